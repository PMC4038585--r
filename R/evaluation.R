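#' Detection rate at a fixed false-positive rate
#'
#' The risk cutoff is the empirical \eqn{(1 - FPR)} quantile of the control
#' scores (inverse empirical CDF, i.e. quantile type 1) and subjects are
#' called screen-positive by strict `>`. The detection rate is the fraction
#' of case scores above the cutoff. At `fpr = 1` the threshold is below all
#' controls and the detection rate is 1.
#'
#' @param case_scores,control_scores Numeric risk scores, higher = riskier;
#'   both nonempty.
#' @param fpr Fixed false-positive rate in (0, 1].
#' @return A list with `dr`, `threshold`, and the realised `fpr` (at most the
#'   nominal one).
#' @export
#' @examples
#' dr_at_fpr(c(0.9, 0.8, 0.2), c(0.1, 0.3, 0.2, 0.4), fpr = 0.25)
dr_at_fpr <- function(case_scores, control_scores, fpr = 0.10) {
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    abort("both score vectors must be nonempty.")
  }
  check_number(fpr, "fpr", lower = 0, upper = 1, allow_lower = FALSE)
  threshold <- if (fpr >= 1) {
    -Inf
  } else {
    quantile(control_scores, 1 - fpr, type = 1, names = FALSE)
  }
  list(dr = mean(case_scores > threshold),
       threshold = threshold,
       fpr = mean(control_scores > threshold))
}

#' Wilson score confidence interval for a detection rate
#'
#' @param k Number of detected cases.
#' @param n Number of cases (positive).
#' @param level Confidence level (default 0.95).
#' @return A named vector `c(low, high)`.
#' @export
#' @examples
#' dr_confidence_interval(12, 21)
dr_confidence_interval <- function(k, n, level = 0.95) {
  k <- check_count(k, "k")
  n <- check_count(n, "n")
  if (n == 0L) abort("`n` must be positive.")
  if (k > n) abort("`k` cannot exceed `n`.")
  check_number(level, "level", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Mann-Whitney area under the ROC curve
#'
#' The probability that a random case outscores a random control, with ties
#' counted one half — identical to the trapezoidal area under the empirical
#' ROC curve. Invariant under strictly increasing transforms of the scores.
#'
#' @inheritParams dr_at_fpr
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(3, 1), c(2, 0))
auc <- function(case_scores, control_scores) {
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    abort("both score vectors must be nonempty.")
  }
  n1 <- length(case_scores)
  n0 <- length(control_scores)
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Screening performance of a risk model on one data set
#'
#' Applies [predict_risk()] and summarises the result as the detection rate
#' at the fixed false-positive rate with a Wilson 95% confidence interval,
#' the Mann-Whitney AUC, and the risk threshold used.
#'
#' @param model A `"risk_model"`.
#' @param data Tibble with the model's term columns plus a 0/1 `outcome`
#'   column (or the column named in `outcome_col`).
#' @param dataset Label such as `"train"`, `"test"`, `"validation"`.
#' @param fpr Fixed false-positive rate.
#' @param outcome_col Name of the outcome column.
#' @param level Confidence level of the DR interval.
#' @return A one-row tibble of class `"screening_performance"`.
#' @export
evaluate_model <- function(model, data, dataset = "test", fpr = 0.10,
                           outcome_col = "outcome", level = 0.95) {
  check_cols(data, outcome_col, "data")
  y <- data[[outcome_col]]
  scores <- predict_risk(model, data)
  case_scores <- scores[y == 1]
  control_scores <- scores[y == 0]
  res <- dr_at_fpr(case_scores, control_scores, fpr = fpr)
  k <- sum(case_scores > res$threshold)
  ci <- dr_confidence_interval(k, length(case_scores), level = level)
  out <- tibble(
    model_id = model$model_id,
    outcome = model$outcome,
    dataset = dataset,
    n_cases = length(case_scores),
    n_controls = length(control_scores),
    fpr = fpr,
    dr_at_fpr = res$dr,
    dr_low = unname(ci["low"]),
    dr_high = unname(ci["high"]),
    auc = auc(case_scores, control_scores),
    threshold = res$threshold,
    n_terms = length(model$coefficients)
  )
  structure(out, class = c("screening_performance", class(tibble())))
}

#' Pick the best candidate model from test-set performance
#'
#' The model with the highest test-set detection rate wins; among models
#' whose detection rates tie within `tie_tol` (default exact equality), the
#' one with the fewest terms is preferred — adding a marker that does not
#' improve detection is not rewarded.
#'
#' @param performances A tibble of [evaluate_model()] rows (one per
#'   candidate).
#' @param tie_tol Detection-rate difference treated as a tie.
#' @return The winning `model_id`.
#' @export
select_best_model <- function(performances, tie_tol = 0) {
  check_cols(performances, c("model_id", "dr_at_fpr", "n_terms"),
             "performances")
  if (nrow(performances) == 0L) abort("no candidate performances supplied.")
  best_dr <- max(performances$dr_at_fpr)
  contenders <- performances %>%
    filter(.data$dr_at_fpr >= best_dr - tie_tol) %>%
    arrange(.data$n_terms, dplyr::desc(.data$dr_at_fpr))
  contenders$model_id[1]
}

#' Validate a model on held-out subjects
#'
#' Thin wrapper over [evaluate_model()] that additionally refuses subject
#' overlap between the validation rows and the ids the model was trained or
#' tested on.
#'
#' @inheritParams evaluate_model
#' @param seen_ids Subject ids used in training/testing; overlap with
#'   `data$subject_id` is an error.
#' @return A one-row `"screening_performance"` tibble with
#'   `dataset = "validation"`.
#' @export
validate_model <- function(model, data, seen_ids = character(0), fpr = 0.10,
                           outcome_col = "outcome") {
  if ("subject_id" %in% names(data)) {
    overlap <- intersect(data$subject_id, seen_ids)
    if (length(overlap) > 0L) {
      abort(sprintf("validation subjects overlap earlier splits (e.g. %s).",
                    overlap[1]))
    }
  }
  evaluate_model(model, data, dataset = "validation", fpr = fpr,
                 outcome_col = outcome_col)
}

#' Performance within a case subgroup
#'
#' Re-evaluates detection among the cases satisfying a predicate (by default
#' birthweight below the 10th centile, the growth-restricted subgroup)
#' against all controls. An empty subgroup returns an empty-result row
#' (`n_cases = 0`, measures `NA`) rather than an error.
#'
#' @inheritParams evaluate_model
#' @param predicate A one-sided formula or function of the data returning a
#'   logical per row, e.g. `~ birthweight_centile < 10`.
#' @param dataset Label for the output row.
#' @return A one-row `"screening_performance"` tibble.
#' @export
subgroup_performance <- function(model, data, predicate, dataset = "subgroup",
                                 fpr = 0.10, outcome_col = "outcome") {
  keep <- if (inherits(predicate, "formula")) {
    rlang::eval_tidy(rlang::as_quosure(rlang::f_rhs(predicate),
                                       rlang::f_env(predicate)),
                     data = data)
  } else {
    predicate(data)
  }
  if (!is.logical(keep) || length(keep) != nrow(data)) {
    abort("`predicate` must yield one logical per row.")
  }
  y <- data[[outcome_col]]
  sub <- data[y == 0 | (y == 1 & keep), , drop = FALSE]
  if (sum(sub[[outcome_col]] == 1) == 0L) {
    out <- tibble(model_id = model$model_id, outcome = model$outcome,
                  dataset = dataset, n_cases = 0L,
                  n_controls = sum(y == 0), fpr = fpr,
                  dr_at_fpr = NA_real_, dr_low = NA_real_,
                  dr_high = NA_real_, auc = NA_real_,
                  threshold = NA_real_,
                  n_terms = length(model$coefficients))
    return(structure(out, class = c("screening_performance", class(tibble()))))
  }
  evaluate_model(model, sub, dataset = dataset, fpr = fpr,
                 outcome_col = outcome_col)
}

#' ROC curve for a model on one data set
#'
#' @inheritParams evaluate_model
#' @param mark_fpr Draw the operating point at this false-positive rate.
#' @return A ggplot of the empirical ROC curve.
#' @export
plot_roc <- function(model, data, outcome_col = "outcome", mark_fpr = 0.10) {
  y <- data[[outcome_col]]
  scores <- predict_risk(model, data)
  pts <- roc_points(scores[y == 1], scores[y == 0])
  op <- dr_at_fpr(scores[y == 1], scores[y == 0], fpr = mark_fpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::annotate("point", x = op$fpr, y = op$dr, shape = 4, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "detection rate",
                  title = model$model_id) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param case_scores,control_scores Raw score vectors.
#' @return `roc_points()` returns a tibble of (`fpr`, `tpr`) pairs over all
#'   thresholds.
#' @export
roc_points <- function(case_scores, control_scores) {
  thresholds <- c(Inf, sort(unique(c(case_scores, control_scores)),
                            decreasing = TRUE), -Inf)
  tibble(
    threshold = thresholds,
    fpr = purrr::map_dbl(thresholds, ~mean(control_scores > .x)),
    tpr = purrr::map_dbl(thresholds, ~mean(case_scores > .x))
  )
}
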