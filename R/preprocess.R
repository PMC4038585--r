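#' Mean arterial pressure from a blood-pressure pair
#'
#' MAP is computed as \eqn{DBP + (SBP - DBP)/3}, the diastolic pressure plus a
#' third of the pulse pressure. Vectorised.
#'
#' @param sbp,dbp Systolic and diastolic blood pressure in mmHg; both must be
#'   positive with `dbp <= sbp` elementwise.
#' @return MAP in mmHg.
#' @export
#' @examples
#' compute_map(120, 80)
compute_map <- function(sbp, dbp) {
  if (length(sbp) != length(dbp)) abort("`sbp` and `dbp` must match in length.")
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
      any(dbp <= 0) || any(sbp <= 0)) {
    abort("blood pressures must be positive and finite.")
  }
  if (any(dbp > sbp)) {
    abort("diastolic pressure exceeds systolic pressure for some subjects.")
  }
  dbp + (sbp - dbp) / 3
}

#' Per-analyte detection fractions
#'
#' The detection fraction of an analyte is the share of subjects in which it
#' was measured above the limit of detection.
#'
#' @param measurements Long measurement tibble (`subject_id`, `analyte`,
#'   `value`, `below_lod`).
#' @param analytes Optional character vector restricting the result; an
#'   unknown analyte is an error naming it.
#' @return A tibble with `analyte`, `n_detected`, `n_total`,
#'   `detection_fraction`.
#' @export
detection_fraction <- function(measurements, analytes = NULL) {
  check_cols(measurements, c("subject_id", "analyte", "below_lod"),
             "measurements")
  out <- measurements %>%
    group_by(.data$analyte) %>%
    summarise(n_detected = sum(!.data$below_lod), n_total = n(),
              .groups = "drop") %>%
    mutate(detection_fraction = .data$n_detected / .data$n_total)
  if (!is.null(analytes)) {
    unknown <- setdiff(analytes, out$analyte)
    if (length(unknown) > 0L) {
      abort(sprintf("unknown analyte(s): %s.", paste(unknown, collapse = ", ")))
    }
    out <- filter(out, .data$analyte %in% .env$analytes)
  }
  out
}

#' Drop analytes not detected in more than a threshold share of samples
#'
#' Retains analytes whose detection fraction is strictly greater than
#' `threshold` (default 0.80, the conventional detection cut):
#' an analyte detected in exactly 80% is dropped.
#'
#' @inheritParams detection_fraction
#' @param threshold Detection-fraction cut in (0, 1).
#' @param subjects Optional subject tibble; when given together with
#'   `groups`, detection is counted over those groups only instead of all
#'   samples pooled.
#' @param groups Optional subset of `c("control", "eo_pe", "lo_pe")`.
#' @return A list with `measurements` (retained analytes only) and `report`,
#'   a tibble of all analytes with their detection fractions and a `retained`
#'   flag.
#' @export
apply_detection_filter <- function(measurements, threshold = 0.80,
                                   subjects = NULL, groups = NULL) {
  check_number(threshold, "threshold", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  counted <- measurements
  if (!is.null(groups)) {
    if (is.null(subjects)) abort("`subjects` is required when `groups` is given.")
    keep_ids <- subjects$subject_id[subjects$group %in% groups]
    counted <- filter(measurements, .data$subject_id %in% keep_ids)
  }
  report <- detection_fraction(counted) %>%
    mutate(retained = .data$detection_fraction > threshold)
  retained <- report$analyte[report$retained]
  list(
    measurements = filter(measurements, .data$analyte %in% retained),
    report = report
  )
}

#' Impute below-LOD values as half the lowest detected value
#'
#' Each censored cell of an analyte is replaced by half the lowest detected
#' value of that analyte — a compromise between substituting zero
#' (underestimation) and truncating at the limit of detection
#' (overestimation). Detected values are never altered, the below-LOD mask is
#' cleared, and imputed cells are flagged. Idempotent.
#'
#' @inheritParams detection_fraction
#' @return The measurement tibble with no `NA` values and an added/updated
#'   logical `imputed` column.
#' @export
#' @examples
#' m <- tibble::tibble(subject_id = c("a", "b", "c"), analyte = "x",
#'                     value = c(2, NA, 4), below_lod = c(FALSE, TRUE, FALSE))
#' impute_below_lod(m)
impute_below_lod <- function(measurements) {
  check_cols(measurements, c("subject_id", "analyte", "value", "below_lod"),
             "measurements")
  none_detected <- measurements %>%
    group_by(.data$analyte) %>%
    summarise(any_detected = any(!.data$below_lod), .groups = "drop") %>%
    filter(!.data$any_detected)
  if (nrow(none_detected) > 0L) {
    abort(sprintf(
      "analyte(s) with no detected values, cannot impute: %s.",
      paste(none_detected$analyte, collapse = ", ")))
  }
  measurements %>%
    group_by(.data$analyte) %>%
    mutate(
      .half_min = min(.data$value[!.data$below_lod]) / 2,
      imputed = .data$below_lod |
        (if ("imputed" %in% names(measurements)) .data$imputed else FALSE),
      value = ifelse(.data$below_lod, .data$.half_min, .data$value),
      below_lod = FALSE
    ) %>%
    ungroup() %>%
    select(-".half_min")
}

#' Append mean arterial pressure as a marker row set
#'
#' Computes MAP from the subject table's blood-pressure pair and returns
#' measurement rows (`analyte = "MAP"`) that can be bound to the metabolite
#' table, so MAP flows through MoM normalization, marker testing and
#' modelling exactly like a serum analyte.
#'
#' @param subjects Subject tibble with `sbp_mmHg` and `dbp_mmHg`.
#' @return A long measurement tibble with one MAP row per subject.
#' @export
map_as_marker <- function(subjects) {
  check_cols(subjects, c("subject_id", "sbp_mmHg", "dbp_mmHg"), "subjects")
  tibble(
    subject_id = subjects$subject_id,
    analyte = "MAP",
    value = compute_map(subjects$sbp_mmHg, subjects$dbp_mmHg),
    below_lod = FALSE
  )
}
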