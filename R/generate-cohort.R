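#' Generate a synthetic case-control screening cohort
#'
#' Draws maternal covariates, blood pressures and a subjects-by-analytes
#' concentration table with the statistical structure a first-trimester
#' multiple-of-median (MoM) screening analysis assumes:
#'
#' * control concentrations at gestational age \eqn{g} are distributed as
#'   \eqn{m(g) \times 10^{N(0,\sigma)}}, where \eqn{\log_{10} m(g)} is linear
#'   in gestational days and \eqn{\sigma} is the analyte's log10 MoM SD;
#' * case concentrations are additionally multiplied by the configured MoM
#'   ratio for their outcome group;
#' * analytes with `lod_quantile > 0` are censored below the corresponding
#'   empirical quantile of the control draw (the limit of detection), with
#'   censored cells stored as `NA` and flagged in `below_lod`;
#' * mean arterial pressure (MAP) is generated analogously on the MoM scale
#'   and decomposed into systolic/diastolic pairs by drawing a pulse pressure
#'   of N(40, 5) mmHg and inverting the MAP identity
#'   \eqn{MAP = DBP + (SBP - DBP)/3}.
#'
#' Identical config and seed give a bit-identical cohort; the caller's RNG
#' state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"cohort"` with elements `subjects` (one row per
#'   pregnancy), `measurements` (long tibble: `subject_id`, `analyte`,
#'   `value`, `below_lod`) and `analytes` (the panel plus the realised
#'   per-analyte `lod`, `NA` when uncensored).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_controls = 40, n_eo = 8, n_lo = 8,
#'                                         seed = 7))
#' dplyr::count(cohort$subjects, group)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created with cohort_config().")
  }
  withr::with_seed(config$seed, {
    subjects <- generate_subjects(config)
    meas <- generate_measurements(subjects, config)
  })
  structure(list(subjects = subjects,
                 measurements = meas$measurements,
                 analytes = meas$analytes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>\n")
  print(count(x$subjects, .data$group))
  cat(sprintf("  %d analytes, %d measurement rows (%d below LOD)\n",
              nrow(x$analytes), nrow(x$measurements),
              sum(x$measurements$below_lod)))
  invisible(x)
}

generate_subjects <- function(config) {
  cov <- config$covariates
  sizes <- c(control = config$n_controls, eo_pe = config$n_eo,
             lo_pe = config$n_lo)
  groups <- rep(names(sizes), times = sizes)
  n <- length(groups)
  ga_lo <- config$ga_sampling_range[1]
  ga_hi <- config$ga_sampling_range[2]

  weight <- pmax(rnorm(n, cov$weight_mean[groups], cov$weight_sd[groups]), 40)
  ga_days <- sample(seq(ga_lo, ga_hi), n, replace = TRUE)
  smoking <- runif(n) < cov$smoking[groups]
  nullip <- runif(n) < cov$nulliparity[groups]
  history <- runif(n) < cov$history[groups]
  ethnicity <- sample(cov$ethnicity_levels, n, replace = TRUE,
                      prob = cov$ethnicity_probs)

  # delivery timing and birthweight centile by outcome group; the centile
  # shift in cases reflects the growth restriction that accompanies PE
  ga_del <- numeric(n)
  centile <- numeric(n)
  for (g in outcome_groups) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng == 0L) next
    ga_del[idx] <- switch(g,
      control = rnorm_trunc(ng, 40, 1.2, 37, 42),
      eo_pe = rnorm_trunc(ng, 31, 1.5, 24, 33.99),
      lo_pe = rnorm_trunc(ng, 37, 1.5, 34, 41.99))
    centile[idx] <- 100 * switch(g,
      control = rbeta(ng, 1.2, 1),
      eo_pe = rbeta(ng, 1, 2.5),
      lo_pe = rbeta(ng, 1, 4.5))
  }

  # MAP on the MoM scale, then decomposed into pressure pairs
  ms <- config$map_spec
  momr <- c(control = 1, eo_pe = ms$momr_eo, lo_pe = ms$momr_lo)
  map <- 10^(log10(ms$median_mmHg) + log10(momr[groups]) +
               rnorm(n, 0, ms$log10_mom_sd))
  pulse <- pmax(rnorm(n, 40, 5), 10)
  dbp <- map - pulse / 3
  sbp <- dbp + pulse

  tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    group = groups,
    ga_sampling_days = as.integer(ga_days),
    weight_kg = unname(weight),
    smoking = unname(smoking),
    nulliparous = unname(nullip),
    history_htn = unname(history),
    ethnicity = ethnicity,
    sbp_mmHg = unname(sbp),
    dbp_mmHg = unname(dbp),
    ga_delivery_weeks = ga_del,
    birthweight_centile = centile
  )
}

# reference points for the panel parameterisation: analyte medians are
# specified at mid-window gestation, weight effects centred at 65.5 kg
ga_reference_days <- 76.5
weight_reference_kg <- 65.5

generate_measurements <- function(subjects, config) {
  panel <- config$analytes
  is_control <- subjects$group == "control"
  n <- nrow(subjects)
  lods <- rep(NA_real_, nrow(panel))

  per_analyte <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    a <- panel[i, ]
    momr <- c(control = 1, eo_pe = a$momr_eo, lo_pe = a$momr_lo)
    log10_conc <- log10(a$median_intercept) +
      a$median_slope * (subjects$ga_sampling_days - ga_reference_days) +
      a$weight_effect * (subjects$weight_kg - weight_reference_kg) +
      log10(momr[subjects$group]) +
      rnorm(n, 0, a$log10_mom_sd)
    conc <- 10^log10_conc
    below <- rep(FALSE, n)
    if (a$lod_quantile > 0) {
      lods[i] <- quantile(conc[is_control], a$lod_quantile,
                          type = 1, names = FALSE)
      below <- conc < lods[i]
    }
    per_analyte[[i]] <- tibble(
      subject_id = subjects$subject_id,
      analyte = a$name,
      value = unname(ifelse(below, NA_real_, conc)),
      below_lod = unname(below)
    )
  }
  list(measurements = bind_rows(per_analyte),
       analytes = mutate(panel, lod = lods))
}
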