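#' Student's t-test on log10-MoM values
#'
#' Two-sided two-sample Student's t-test with pooled variance (set
#' `var_equal = FALSE` for the Welch variant).
#'
#' @param case_values,control_values Numeric log10-MoM vectors, each with at
#'   least two values; the pooled variance must be nonzero.
#' @param var_equal Pooled-variance Student test if `TRUE` (default).
#' @return A list with `t` and `p`.
#' @export
t_test_log_mom <- function(case_values, control_values, var_equal = TRUE) {
  if (length(case_values) < 2L || length(control_values) < 2L) {
    abort("each group needs at least two values.")
  }
  if (sd(c(case_values - mean(case_values),
           control_values - mean(control_values))) == 0) {
    abort("degenerate (zero) pooled variance.")
  }
  ht <- t.test(case_values, control_values, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values with monotonicity enforcement; the
#' output is in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.8))
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0) || any(p_values > 1)) {
    abort("all p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-marker case-vs-control testing with FDR control
#'
#' For one outcome group, every marker's log10-MoMs are compared between
#' cases and controls with a Student's t-test; p-values are corrected across
#' the whole tested panel (all retained metabolites plus MAP jointly) by
#' Benjamini-Hochberg, and markers with q strictly below `q_threshold`
#' (default 0.15, i.e. FDR < 15%) are flagged as selected. The MoM ratio is
#' reported as the effect size.
#'
#' @param mom_table MoM tibble (typically restricted to one analysis set,
#'   e.g. training).
#' @param subjects Subject tibble with `group`.
#' @param outcome `"eo_pe"` or `"lo_pe"`; controls are always the comparator.
#' @param q_threshold FDR gate in (0, 1).
#' @param var_equal Passed to [t_test_log_mom()].
#' @return A tibble of class `"marker_tests"`: `marker`, `outcome`,
#'   `t_statistic`, `p_value`, `fdr_q`, `momr`, `selected`, ordered by q.
#' @export
test_markers <- function(mom_table, subjects, outcome, q_threshold = 0.15,
                         var_equal = TRUE) {
  outcome <- check_outcome(outcome)
  check_number(q_threshold, "q_threshold", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  check_cols(mom_table, c("subject_id", "marker", "mom", "log10_mom"),
             "mom_table")
  labels <- subjects %>% select("subject_id", "group")
  data <- mom_table %>%
    left_join(labels, by = "subject_id") %>%
    filter(.data$group %in% c("control", outcome))

  res <- data %>%
    group_by(.data$marker) %>%
    summarise(
      ht = list(t_test_log_mom(.data$log10_mom[.data$group == .env$outcome],
                               .data$log10_mom[.data$group == "control"],
                               var_equal = var_equal)),
      momr = mom_ratio(.data$mom[.data$group == .env$outcome],
                       .data$mom[.data$group == "control"]),
      .groups = "drop"
    ) %>%
    mutate(t_statistic = purrr::map_dbl(.data$ht, "t"),
           p_value = purrr::map_dbl(.data$ht, "p"),
           outcome = .env$outcome,
           fdr_q = bh_fdr(.data$p_value),
           selected = .data$fdr_q < q_threshold) %>%
    select("marker", "outcome", "t_statistic", "p_value", "fdr_q",
           "momr", "selected") %>%
    arrange(.data$fdr_q, .data$p_value)
  structure(res, class = c("marker_tests", class(tibble())))
}

#' Markers passing the FDR gate
#'
#' @param results A `"marker_tests"` tibble from [test_markers()].
#' @param q_threshold FDR gate; strict inequality, so q exactly at the
#'   threshold is not selected.
#' @return Character vector of selected marker names, ordered by ascending q.
#' @export
select_markers <- function(results, q_threshold = 0.15) {
  check_cols(results, c("marker", "fdr_q"), "results")
  results %>%
    filter(.data$fdr_q < q_threshold) %>%
    arrange(.data$fdr_q) %>%
    pull("marker")
}

#' Volcano-style view of marker pre-selection
#'
#' @param object A `"marker_tests"` tibble.
#' @param q_threshold FDR gate drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot of log2 MoM ratio against -log10 q, selected markers
#'   labelled.
#' @method autoplot marker_tests
#' @export
autoplot.marker_tests <- function(object, q_threshold = 0.15, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = log2(.data$momr),
                               y = -log10(.data$fdr_q),
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = 2) +
    ggplot2::geom_text(
      data = dplyr::filter(object, .data$selected),
      ggplot2::aes(label = .data$marker), vjust = -0.8, size = 3,
      show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 MoM ratio (case/control)",
                  y = expression(-log[10] ~ "FDR q"),
                  colour = "selected") +
    ggplot2::theme_minimal()
}
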