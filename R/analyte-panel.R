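#' Define one analyte of a synthetic screening panel
#'
#' An analyte spec describes the control distribution of one serum metabolite:
#' its expected median at the reference gestational age, a log-linear
#' gestational trend, log10 multiple-of-median (MoM) dispersion, case effect
#' sizes expressed as MoM ratios, optional below-limit-of-detection (LOD)
#' censoring, and an optional maternal-weight effect.
#'
#' @param name Analyte name.
#' @param platform `"amine"` or `"oxylipin"`.
#' @param median_intercept Expected control median concentration (arbitrary
#'   units) at the reference gestational age (76.5 days, the middle of the
#'   8+0 to 13+6 week sampling window).
#' @param median_slope Gestational trend of the log10 median, per day.
#' @param log10_mom_sd Standard deviation of log10 MoM in controls; must be
#'   positive.
#' @param momr_eo,momr_lo MoM ratio (case median / control median) in
#'   early-onset and late-onset preeclampsia cases; 1 means no effect.
#' @param lod_quantile Fraction of the control distribution censored below the
#'   limit of detection, in `[0, 1)`.
#' @param weight_effect Slope of log10 MoM per kg of maternal weight
#'   (centred at 65.5 kg); 0 for no weight dependence.
#'
#' @return A one-row tibble.
#' @seealso [default_analyte_panel()], [cohort_config()]
#' @export
#' @examples
#' analyte_spec("taurine", momr_eo = 0.79)
analyte_spec <- function(name,
                         platform = c("amine", "oxylipin"),
                         median_intercept = 50,
                         median_slope = 0,
                         log10_mom_sd = 0.10,
                         momr_eo = 1,
                         momr_lo = 1,
                         lod_quantile = 0,
                         weight_effect = 0) {
  platform <- match.arg(platform)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  check_number(median_intercept, "median_intercept", lower = 0, allow_lower = FALSE)
  check_number(median_slope, "median_slope")
  check_number(log10_mom_sd, "log10_mom_sd", lower = 0, allow_lower = FALSE)
  check_number(momr_eo, "momr_eo", lower = 0, allow_lower = FALSE)
  check_number(momr_lo, "momr_lo", lower = 0, allow_lower = FALSE)
  check_number(lod_quantile, "lod_quantile", lower = 0, upper = 1, allow_upper = FALSE)
  check_number(weight_effect, "weight_effect")
  tibble(
    name = name, platform = platform,
    median_intercept = median_intercept, median_slope = median_slope,
    log10_mom_sd = log10_mom_sd, momr_eo = momr_eo, momr_lo = momr_lo,
    lod_quantile = lod_quantile, weight_effect = weight_effect
  )
}

validate_analyte_panel <- function(panel) {
  check_cols(panel, c("name", "platform", "median_intercept", "median_slope",
                      "log10_mom_sd", "momr_eo", "momr_lo", "lod_quantile",
                      "weight_effect"), "analyte panel")
  if (anyDuplicated(panel$name)) abort("analyte names must be unique.")
  with(panel, {
    if (any(!is.finite(median_intercept)) || any(median_intercept <= 0) ||
        any(!is.finite(log10_mom_sd)) || any(log10_mom_sd <= 0) ||
        any(!is.finite(momr_eo)) || any(momr_eo <= 0) ||
        any(!is.finite(momr_lo)) || any(momr_lo <= 0) ||
        any(!is.finite(lod_quantile)) || any(lod_quantile < 0) ||
        any(lod_quantile >= 1) || any(!is.finite(median_slope)) ||
        any(!is.finite(weight_effect))) {
      abort("analyte panel contains non-finite or out-of-range parameters.")
    }
  })
  invisible(panel)
}

#' Default 104-metabolite synthetic panel
#'
#' A panel of 58 amines and 46 oxylipins mirroring the size of a targeted
#' first-trimester metabolomics screen (105 variables once mean arterial
#' pressure is added as a marker). All analytes are null except the known
#' discriminative ones: taurine (MoM ratio 0.79 in early-onset preeclampsia),
#' asparagine (0.84, early-onset) and glycylglycine (0.72, late-onset). Two
#' oxylipins are censored below the limit of detection in 25% and 30% of
#' controls so the >80% detection filter has something to drop, one amine has
#' 10% censoring to exercise half-minimum imputation, and two amines carry a
#' maternal-weight effect so the covariate-adjustment gate is non-trivial.
#'
#' Dispersion defaults are typical serum-screening values: log10 MoM standard
#' deviation 0.10 for amines and 0.15 for oxylipins.
#'
#' @return A tibble of analyte specs, one row per analyte.
#' @export
default_analyte_panel <- function() {
  amine_names <- c("taurine", "asparagine", "glycylglycine",
                   sprintf("amine_%02d", 4:58))
  oxy_names <- sprintf("oxylipin_%02d", 1:46)
  amines <- tibble(
    name = amine_names, platform = "amine",
    median_intercept = rep(c(50, 20, 80, 35), length.out = 58),
    median_slope = rep(c(0.002, 0, -0.0015, 0.001), length.out = 58),
    log10_mom_sd = 0.10,
    momr_eo = ifelse(amine_names == "taurine", 0.79,
                     ifelse(amine_names == "asparagine", 0.84, 1)),
    momr_lo = ifelse(amine_names == "glycylglycine", 0.72, 1),
    lod_quantile = ifelse(amine_names == "amine_10", 0.10, 0),
    weight_effect = ifelse(amine_names %in% c("amine_05", "amine_06"), -0.002, 0)
  )
  oxylipins <- tibble(
    name = oxy_names, platform = "oxylipin",
    median_intercept = rep(c(5, 2, 12), length.out = 46),
    median_slope = rep(c(0, 0.001, -0.001), length.out = 46),
    log10_mom_sd = 0.15,
    momr_eo = 1, momr_lo = 1,
    lod_quantile = ifelse(oxy_names == "oxylipin_01", 0.25,
                          ifelse(oxy_names == "oxylipin_02", 0.30, 0)),
    weight_effect = 0
  )
  bind_rows(amines, oxylipins)
}

#' Marker spec for mean arterial pressure (MAP)
#'
#' MAP is treated downstream exactly like a serum marker on the MoM scale.
#' The defaults are the effect sizes of a first-trimester preeclampsia
#' cohort: MoM ratio 1.10 in early-onset and 1.07 in late-onset cases, with a
#' log10 MoM standard deviation of 0.04 (blood pressure is far less dispersed
#' than serum metabolites).
#'
#' @param momr_eo,momr_lo MoM ratio in early-/late-onset cases.
#' @param log10_mom_sd Dispersion of log10 MAP-MoM.
#' @param median_mmHg Control median MAP in mmHg.
#' @return A list with the four components above.
#' @export
map_marker_spec <- function(momr_eo = 1.10, momr_lo = 1.07,
                            log10_mom_sd = 0.04, median_mmHg = 85) {
  check_number(momr_eo, "momr_eo", lower = 0, allow_lower = FALSE)
  check_number(momr_lo, "momr_lo", lower = 0, allow_lower = FALSE)
  check_number(log10_mom_sd, "log10_mom_sd", lower = 0, allow_lower = FALSE)
  check_number(median_mmHg, "median_mmHg", lower = 0, allow_lower = FALSE)
  list(momr_eo = momr_eo, momr_lo = momr_lo,
       log10_mom_sd = log10_mom_sd, median_mmHg = median_mmHg)
}
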