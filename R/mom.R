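#' Completed gestational week from gestational age in days
#'
#' Week 8 covers days 56-62, week 13 days 91-97 (half-open 7-day bins).
#'
#' @param ga_days Gestational age in days.
#' @return Integer completed weeks.
#' @export
completed_week <- function(ga_days) as.integer(ga_days %/% 7)

week_midpoint_days <- function(week) 7 * week + 3

#' Fit gestation-specific median curves on training controls
#'
#' For every analyte, the median concentration and subject count are computed
#' per completed gestational week among training-set controls, and
#' \eqn{\log_{10}(\mathrm{median})} is regressed on the week-midpoint
#' gestational day by least squares weighted by the number of women tested in
#' each week. The log scale guarantees a positive predicted median at every
#' gestational age; the weights make sparsely sampled weeks count less.
#'
#' @param measurements Long measurement tibble (after detection filtering and
#'   imputation; all values positive).
#' @param subjects Subject tibble with `ga_sampling_days` and `group`.
#' @param training_ids Subject ids of the training set. Only training-set
#'   controls enter the fit.
#' @return A tibble of class `"mom_curves"`: one row per analyte with
#'   `intercept`, `slope` (log10 concentration per day) and a `weekly`
#'   list-column of the per-week medians and counts used.
#' @export
fit_median_curves <- function(measurements, subjects, training_ids) {
  check_cols(subjects, c("subject_id", "group", "ga_sampling_days"), "subjects")
  check_cols(measurements, c("subject_id", "analyte", "value"), "measurements")
  ctrl_ids <- subjects$subject_id[subjects$group == "control" &
                                    subjects$subject_id %in% training_ids]
  data <- measurements %>%
    filter(.data$subject_id %in% ctrl_ids) %>%
    left_join(select(subjects, "subject_id", "ga_sampling_days"),
              by = "subject_id")
  if (any(is.na(data$value))) {
    abort("measurements contain missing values; impute before curve fitting.")
  }
  if (any(data$value <= 0)) abort("concentrations must be positive.")

  weekly <- data %>%
    mutate(week = completed_week(.data$ga_sampling_days)) %>%
    group_by(.data$analyte, .data$week) %>%
    summarise(median_conc = median(.data$value), n = n(), .groups = "drop")

  curves <- weekly %>%
    tidyr::nest(weekly = c("week", "median_conc", "n")) %>%
    mutate(fit = purrr::map(.data$weekly, fit_one_curve)) %>%
    tidyr::unnest_wider("fit")
  structure(curves, class = c("mom_curves", class(curves)))
}

fit_one_curve <- function(weekly) {
  if (nrow(weekly) < 2L) {
    abort("need medians from at least 2 completed gestational weeks.")
  }
  fit <- lm(log10(median_conc) ~ day,
            data = mutate(weekly, day = week_midpoint_days(week)),
            weights = weekly$n)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

#' Predicted gestation-specific median
#'
#' @param curves A `"mom_curves"` tibble.
#' @param analyte Analyte name (must be present in `curves`).
#' @param ga_days Gestational ages in days.
#' @return Predicted control median concentrations.
#' @export
predict_median <- function(curves, analyte, ga_days) {
  row <- curves[curves$analyte == analyte, ]
  if (nrow(row) != 1L) abort(sprintf("no median curve for analyte %s.", analyte))
  10^(row$intercept + row$slope * ga_days)
}

#' Express measurements as multiples of the gestation-specific median
#'
#' Each concentration is divided by the predicted control median at the
#' subject's gestational age, giving a MoM; MoMs are log10-transformed to
#' provide approximately Normal distributions for downstream t-tests and
#' logistic models.
#'
#' @param measurements Long measurement tibble with positive values.
#' @param curves Median curves from [fit_median_curves()].
#' @param subjects Subject tibble with `ga_sampling_days`.
#' @param ga_range Valid gestational-age window in days; out-of-range
#'   subjects are an error.
#' @return A MoM tibble: `subject_id`, `marker`, `mom`, `log10_mom`.
#' @export
compute_mom <- function(measurements, curves, subjects,
                        ga_range = c(56, 97)) {
  check_cols(measurements, c("subject_id", "analyte", "value"), "measurements")
  data <- measurements %>%
    left_join(select(subjects, "subject_id", "ga_sampling_days"),
              by = "subject_id")
  if (any(is.na(data$ga_sampling_days))) {
    abort("some measurement rows have no matching subject.")
  }
  if (any(data$ga_sampling_days < ga_range[1] |
            data$ga_sampling_days > ga_range[2])) {
    abort("gestational age at sampling outside the supported window.")
  }
  if (any(is.na(data$value)) || any(data$value <= 0)) {
    abort("all values must be positive (impute below-LOD cells first).")
  }
  data %>%
    left_join(select(curves, "analyte", "intercept", "slope"), by = "analyte") %>%
    mutate(
      expected = 10^(.data$intercept + .data$slope * .data$ga_sampling_days),
      mom = .data$value / .data$expected,
      log10_mom = log10(.data$mom)
    ) %>%
    select("subject_id", marker = "analyte", "mom", "log10_mom")
}

#' MoM ratio between cases and controls
#'
#' The effect-size measure of MoM-based screening studies: the median case
#' MoM divided by the median control MoM (optionally the geometric-mean
#' ratio).
#'
#' @param case_moms,control_moms Positive MoM vectors; both nonempty.
#' @param type `"median"` (default) or `"geometric"`.
#' @return The MoM ratio, a positive scalar.
#' @export
#' @examples
#' mom_ratio(c(0.7, 0.8, 0.9), c(0.9, 1.0, 1.1))
mom_ratio <- function(case_moms, control_moms,
                      type = c("median", "geometric")) {
  type <- match.arg(type)
  if (length(case_moms) == 0L || length(control_moms) == 0L) {
    abort("both groups must be nonempty.")
  }
  if (type == "median") {
    median(case_moms) / median(control_moms)
  } else {
    10^(mean(log10(case_moms)) - mean(log10(control_moms)))
  }
}

#' Plot fitted median curves over the weekly medians they were fit to
#'
#' @param object A `"mom_curves"` tibble.
#' @param ... Unused.
#' @return A ggplot: points are weekly medians (sized by the number of women
#'   tested), lines the fitted log-linear curves, one facet per analyte.
#' @method autoplot mom_curves
#' @export
autoplot.mom_curves <- function(object, ...) {
  weekly <- object %>%
    select("analyte", "weekly") %>%
    tidyr::unnest("weekly") %>%
    mutate(day = week_midpoint_days(.data$week))
  grid <- object %>%
    select("analyte", "intercept", "slope") %>%
    tidyr::crossing(day = seq(56, 97, by = 1)) %>%
    mutate(pred = 10^(.data$intercept + .data$slope * .data$day))
  ggplot2::ggplot(weekly, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_conc, size = .data$n),
                        alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$pred),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "gestational age (days)",
                  y = "median concentration",
                  size = "women tested") +
    ggplot2::theme_minimal()
}
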