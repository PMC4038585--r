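# shared fixture builders; everything is generated in code at test time

# a small panel: the three discriminative amines, MAP handled separately,
# plus a censored and a weight-dependent null analyte
small_panel <- function() {
  dplyr::bind_rows(
    analyte_spec("taurine", "amine", median_intercept = 50,
                 median_slope = 0.002, momr_eo = 0.79),
    analyte_spec("asparagine", "amine", median_intercept = 20,
                 momr_eo = 0.84),
    analyte_spec("glycylglycine", "amine", median_intercept = 80,
                 median_slope = -0.001, momr_lo = 0.72),
    analyte_spec("null_censored", "oxylipin", median_intercept = 5,
                 log10_mom_sd = 0.15, lod_quantile = 0.25),
    analyte_spec("null_weight", "amine", median_intercept = 35,
                 weight_effect = -0.002)
  )
}

small_config <- function(n_controls = 120, n_eo = 30, n_lo = 30, seed = 1,
                         analytes = small_panel(), ...) {
  cohort_config(n_controls = n_controls, n_eo = n_eo, n_lo = n_lo,
                analytes = analytes, seed = seed, ...)
}

# a MoM table drawn directly on the log10-MoM scale (bypasses curve fitting),
# for tests of marker selection where only the MoM distribution matters
simulate_mom_table <- function(n_controls, n_cases, markers, log10_shift,
                               sd = 0.1, outcome = "eo_pe") {
  stopifnot(length(log10_shift) == length(markers))
  n <- n_controls + n_cases
  ids <- sprintf("S%04d", seq_len(n))
  groups <- rep(c("control", outcome), c(n_controls, n_cases))
  mom <- purrr::map2_dfr(markers, log10_shift, function(mk, shift) {
    lm10 <- stats::rnorm(n, 0, sd) + ifelse(groups == outcome, shift, 0)
    tibble::tibble(subject_id = ids, marker = mk,
                   mom = 10^lm10, log10_mom = lm10)
  })
  list(mom = mom,
       subjects = tibble::tibble(subject_id = ids, group = groups))
}

# brute-force oracle for dr_at_fpr: scan every candidate threshold (below
# all controls, and each control value), keep those with FPR <= fpr, use the
# smallest such threshold
brute_force_dr <- function(case_scores, control_scores, fpr) {
  candidates <- sort(unique(c(-Inf, control_scores)))
  ok <- vapply(candidates, function(t) mean(control_scores > t) <= fpr,
               logical(1))
  t_star <- candidates[which(ok)[1]]
  list(dr = mean(case_scores > t_star), threshold = t_star)
}

# brute-force oracle for the Mann-Whitney AUC: enumerate all case/control
# pairs, ties count one half
brute_force_auc <- function(case_scores, control_scores) {
  pairs <- outer(case_scores, control_scores,
                 function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
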