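#' Configure an end-to-end screening-study replication
#'
#' Bundles every stage's settings: the cohort source (a [cohort_config()] to
#' simulate, a fixture directory to read, or an existing `"cohort"`), the
#' detection and FDR thresholds, the fixed false-positive rate, the
#' train/test/validation fractions, the split seed, the outcomes to analyse,
#' and how the prior risk enters combined models (`"covariate"`: its
#' log-odds gets a free coefficient; `"offset"`: fixed coefficient 1).
#'
#' @param cohort Cohort source (see above).
#' @param detection_threshold Detection-fraction cut, strict `>`.
#' @param fdr_threshold Marker-selection FDR gate, strict `<`.
#' @param fpr Fixed false-positive rate for all performance figures.
#' @param fractions Train/test/validation fractions.
#' @param split_seed Seed for [assign_splits()].
#' @param outcomes Outcomes to analyse.
#' @param prior_mode `"covariate"` or `"offset"`.
#' @param prior_terms Maternal characteristics for the prior-risk model.
#' @param adjust_covariates Candidate covariates for MoM adjustment.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            detection_threshold = 0.80,
                            fdr_threshold = 0.15,
                            fpr = 0.10,
                            fractions = c(0.4, 0.3, 0.3),
                            split_seed = 1L,
                            outcomes = c("eo_pe", "lo_pe"),
                            prior_mode = c("covariate", "offset"),
                            prior_terms = c("nulliparous", "weight_kg",
                                            "history_htn", "smoking"),
                            adjust_covariates = c("weight_kg", "smoking",
                                                  "ethnicity")) {
  check_number(detection_threshold, "detection_threshold", lower = 0,
               upper = 1, allow_lower = FALSE, allow_upper = FALSE)
  check_number(fdr_threshold, "fdr_threshold", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  check_number(fpr, "fpr", lower = 0, upper = 1, allow_lower = FALSE)
  structure(
    list(cohort = cohort, detection_threshold = detection_threshold,
         fdr_threshold = fdr_threshold, fpr = fpr, fractions = fractions,
         split_seed = check_count(split_seed, "split_seed"),
         outcomes = match.arg(outcomes, c("eo_pe", "lo_pe"), several.ok = TRUE),
         prior_mode = match.arg(prior_mode),
         prior_terms = prior_terms,
         adjust_covariates = adjust_covariates),
    class = "pipeline_config")
}

#' Run the full screening analysis end to end
#'
#' Executes, in order: cohort simulation (or fixture ingest), the >80%
#' detection filter, half-minimum below-LOD imputation, MAP computation,
#' stratified train/test/validation assignment, gestation-specific median
#' curves on training controls, MoM transformation with covariate
#' adjustment, per-outcome marker pre-selection at FDR < 15%, prior-risk and
#' all candidate combined logistic models on the training set, test-set
#' evaluation at the fixed false-positive rate, best-model selection,
#' validation on held-out subjects, and the growth-restricted
#' (birthweight < 10th centile) subgroup re-evaluation.
#'
#' All stage outputs are pure functions of the config and its two seeds, so
#' re-running the same config reproduces every artifact exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs are also
#'   written as CSV files.
#' @return A list of class `"mom_pipeline"` with the cohort, preprocessing
#'   report, splits, curves, adjustment, MoM table, and per-outcome results
#'   (marker tests, fitted models, the Table-style performance grid, the
#'   selected model and its validation and subgroup rows).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  cohort <- stage("cohort", {
    src <- config$cohort
    if (inherits(src, "cohort_config")) generate_cohort(src)
    else if (is.character(src)) read_cohort(src)
    else if (inherits(src, "cohort")) src
    else abort("unsupported cohort source.")
  })
  subjects <- cohort$subjects

  filtered <- stage("detection_filter",
    apply_detection_filter(cohort$measurements,
                           threshold = config$detection_threshold))
  imputed <- stage("imputation", impute_below_lod(filtered$measurements))
  markers <- stage("map_marker",
    bind_rows(select(imputed, "subject_id", "analyte", "value", "below_lod"),
              map_as_marker(subjects)))

  splits <- stage("splits",
    assign_splits(subjects, config$fractions, config$split_seed))
  train_ids <- splits$subject_id[splits$set == "train"]
  test_ids <- splits$subject_id[splits$set == "test"]
  val_ids <- splits$subject_id[splits$set == "validation"]

  curves <- stage("median_curves",
    fit_median_curves(markers, subjects, train_ids))
  moms_raw <- stage("mom", compute_mom(markers, curves, subjects))
  adjustment <- stage("adjustment",
    fit_adjustment(moms_raw, subjects, train_ids,
                   covariates = config$adjust_covariates))
  moms <- stage("apply_adjustment",
    apply_adjustment(moms_raw, adjustment, subjects))

  mom_wide <- moms %>%
    select("subject_id", "marker", "log10_mom") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "log10_mom")

  results <- purrr::map(
    setNames(config$outcomes, config$outcomes),
    function(oc) stage(paste0("outcome_", oc), {
      run_outcome(oc, config, subjects, splits, moms, mom_wide,
                  train_ids, test_ids, val_ids)
    }))

  run <- structure(
    list(config = config, cohort = cohort, preprocess_report = filtered$report,
         splits = splits, curves = curves, adjustment = adjustment,
         mom_table = moms, results = results),
    class = "mom_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name,
                  conditionMessage(e)), parent = e)
  })
}

run_outcome <- function(outcome, config, subjects, splits, moms, mom_wide,
                        train_ids, test_ids, val_ids) {
  train_moms <- filter(moms, .data$subject_id %in% train_ids)
  tests <- test_markers(train_moms, subjects, outcome,
                        q_threshold = config$fdr_threshold)
  selected <- select_markers(tests, config$fdr_threshold)
  map_selected <- "MAP" %in% selected
  metab_selected <- setdiff(selected, "MAP")

  prior <- fit_prior_risk(
    filter(subjects, .data$subject_id %in% train_ids),
    outcome, terms = config$prior_terms)

  data_for <- function(ids) {
    build_model_data(mom_wide, subjects, prior, outcome, ids)
  }
  train_data <- data_for(train_ids)
  test_data <- data_for(test_ids)
  val_data <- data_for(val_ids)

  offset_mode <- config$prior_mode == "offset"
  candidates <- enumerate_candidate_models(
    metab_selected, include_map = map_selected,
    prior_term = if (offset_mode) NULL else "prior_logodds")

  models <- purrr::map2(candidates$terms, candidates$model_id, function(tm, id) {
    fit_combined_model(train_data, outcome, terms = tm,
                       offset_col = if (offset_mode) "prior_logodds",
                       model_id = id)
  })
  names(models) <- candidates$model_id

  perf <- bind_rows(
    purrr::map(models, function(m) {
      bind_rows(evaluate_model(m, train_data, "train", fpr = config$fpr),
                evaluate_model(m, test_data, "test", fpr = config$fpr))
    }))
  best_id <- select_best_model(filter(perf, .data$dataset == "test"))
  best <- models[[best_id]]
  validation <- validate_model(best, val_data,
                               seen_ids = c(train_ids, test_ids),
                               fpr = config$fpr)
  subgroup <- bind_rows(
    subgroup_performance(best, val_data, ~.data$birthweight_centile < 10,
                         dataset = "validation: birthweight < 10th centile",
                         fpr = config$fpr),
    subgroup_performance(best, val_data, ~.data$birthweight_centile >= 10,
                         dataset = "validation: AGA",
                         fpr = config$fpr))
  list(outcome = outcome, marker_tests = tests, selected = selected,
       prior_model = prior, models = models,
       performance = bind_rows(perf, validation),
       best_model_id = best_id, validation = validation,
       subgroup = subgroup)
}

build_model_data <- function(mom_wide, subjects, prior, outcome, ids) {
  data <- subjects %>%
    filter(.data$subject_id %in% ids,
           .data$group %in% c("control", .env$outcome)) %>%
    mutate(outcome = as.integer(.data$group == .env$outcome),
           dplyr::across(dplyr::all_of(prior$terms_used), as.numeric)) %>%
    select("subject_id", "outcome", "birthweight_centile",
           dplyr::all_of(prior$terms_used))
  data$prior_logodds <- qlogis(predict_risk(prior, data))
  left_join(data, mom_wide, by = "subject_id")
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  w(run$splits, "splits.csv")
  w(run$preprocess_report, "preprocess_report.csv")
  w(select(run$curves, "analyte", "intercept", "slope"), "median_curves.csv")
  w(run$mom_table, "mom_table.csv")
  rep <- report_pipeline(run)
  w(rep$marker_table, "marker_tests.csv")
  w(rep$performance_table, "performance.csv")
  coefs <- bind_rows(purrr::map(run$results, function(res) {
    bind_rows(purrr::map(res$models, tidy), .id = "model_id") %>%
      mutate(outcome = res$outcome)
  }))
  w(coefs, "model_coefficients.csv")
  invisible(out_dir)
}

#' Summarise a pipeline run
#'
#' Produces the study's two headline tables: the per-outcome marker
#' pre-selection table (marker, p-value, FDR q, MoM ratio) and the
#' performance grid (model by dataset, DR at the fixed FPR with its 95% CI,
#' AUC), plus the selected model per outcome. An incomplete run is reported
#' with its missing stages listed.
#'
#' @param run A `"mom_pipeline"` from [run_pipeline()].
#' @return A list with `marker_table`, `performance_table`, `best_models`,
#'   and `missing_stages` (empty for a complete run).
#' @export
report_pipeline <- function(run) {
  needed <- c("cohort", "preprocess_report", "splits", "curves",
              "mom_table", "results")
  missing <- needed[!purrr::map_lgl(needed, ~!is.null(run[[.x]]))]
  if (length(missing) > 0L) {
    return(list(marker_table = tibble(), performance_table = tibble(),
                best_models = character(0), missing_stages = missing))
  }
  marker_table <- bind_rows(purrr::map(run$results, "marker_tests")) %>%
    filter(.data$selected) %>%
    select("outcome", "marker", "p_value", "fdr_q", "momr")
  performance_table <- bind_rows(
    purrr::map(run$results, function(res) {
      bind_rows(res$performance, res$subgroup)
    })) %>%
    select("outcome", "model_id", "dataset", "dr_at_fpr", "dr_low",
           "dr_high", "auc", "n_cases", "n_controls")
  list(marker_table = marker_table,
       performance_table = performance_table,
       best_models = purrr::map_chr(run$results, "best_model_id"),
       missing_stages = character(0))
}

#' @export
print.mom_pipeline <- function(x, ...) {
  rep <- report_pipeline(x)
  cat("<mom_pipeline>\n")
  if (length(rep$missing_stages) > 0L) {
    cat("  incomplete run; missing stages:",
        paste(rep$missing_stages, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat("Selected markers (FDR gate):\n")
  print(rep$marker_table)
  cat("\nBest models:",
      paste(sprintf("%s: %s", names(rep$best_models), rep$best_models),
            collapse = "; "), "\n")
  cat("\nValidation performance:\n")
  print(filter(rep$performance_table, .data$dataset == "validation"))
  invisible(x)
}
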