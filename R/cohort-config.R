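#' Configure a synthetic first-trimester case-control cohort
#'
#' Collects everything [generate_cohort()] needs: group sizes, the gestational
#' sampling window, the analyte panel, the mean-arterial-pressure marker spec,
#' and per-group maternal covariate distributions. Defaults reproduce the
#' design of a nested case-control preeclampsia screening study: 500 controls,
#' 68 early-onset (EO-PE) and 99 late-onset (LO-PE) cases sampled at
#' 8+0 to 13+6 weeks of gestation, with covariate rates taken from its
#' baseline table (e.g. nulliparity 46.6% in controls vs 80.9% in EO-PE).
#'
#' @param n_controls,n_eo,n_lo Group sizes (non-negative integers).
#' @param ga_sampling_range Integer gestational-age window at sampling, in
#'   days, within `[56, 97]` (completed weeks 8-13).
#' @param analytes Analyte panel tibble; see [analyte_spec()] and
#'   [default_analyte_panel()].
#' @param map_spec Mean-arterial-pressure marker spec; see [map_marker_spec()].
#' @param covariates Named list of per-group covariate parameters:
#'   `weight_mean`, `weight_sd` (kg), `smoking`, `nulliparity`, `history`
#'   (rates), each a length-3 vector named `control`, `eo_pe`, `lo_pe`, plus
#'   `ethnicity_levels` and `ethnicity_probs`.
#' @param seed Integer seed; the same config and seed give a bit-identical
#'   cohort.
#'
#' @return A list with class `"cohort_config"`.
#' @export
#' @examples
#' cfg <- cohort_config(n_controls = 50, n_eo = 10, n_lo = 10, seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_controls = 500, n_eo = 68, n_lo = 99,
                          ga_sampling_range = c(56L, 97L),
                          analytes = default_analyte_panel(),
                          map_spec = map_marker_spec(),
                          covariates = default_covariate_specs(),
                          seed = 1L) {
  n_controls <- check_count(n_controls, "n_controls")
  n_eo <- check_count(n_eo, "n_eo")
  n_lo <- check_count(n_lo, "n_lo")
  if (length(ga_sampling_range) != 2L ||
      any(ga_sampling_range != trunc(ga_sampling_range)) ||
      ga_sampling_range[1] < 56 || ga_sampling_range[2] > 97 ||
      ga_sampling_range[1] > ga_sampling_range[2]) {
    abort("`ga_sampling_range` must be integer days within [56, 97].")
  }
  validate_analyte_panel(analytes)
  for (nm in c("weight_mean", "weight_sd", "smoking", "nulliparity", "history")) {
    v <- covariates[[nm]]
    if (is.null(v) || length(v) != 3L || any(!is.finite(v))) {
      abort(sprintf("covariate spec `%s` must be a finite length-3 vector.", nm))
    }
  }
  if (any(covariates$weight_sd <= 0)) abort("weight_sd must be positive.")
  seed <- check_count(seed, "seed")
  structure(
    list(n_controls = n_controls, n_eo = n_eo, n_lo = n_lo,
         ga_sampling_range = as.integer(ga_sampling_range),
         analytes = analytes, map_spec = map_spec,
         covariates = covariates, seed = seed),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_covariate_specs <- function() {
  grp <- function(control, eo, lo) c(control = control, eo_pe = eo, lo_pe = lo)
  list(
    weight_mean = grp(65.5, 70.0, 67.5),
    weight_sd = grp(10, 12, 10),
    smoking = grp(0.042, 0.118, 0.061),
    nulliparity = grp(0.466, 0.809, 0.727),
    history = grp(0.008, 0.059, 0.101),
    ethnicity_levels = c("european", "other"),
    ethnicity_probs = c(0.85, 0.15)
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  groups: %d controls, %d EO-PE, %d LO-PE\n",
              x$n_controls, x$n_eo, x$n_lo))
  cat(sprintf("  gestational sampling window: %d-%d days\n",
              x$ga_sampling_range[1], x$ga_sampling_range[2]))
  cat(sprintf("  panel: %d analytes (+ MAP), seed %d\n",
              nrow(x$analytes), x$seed))
  invisible(x)
}
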