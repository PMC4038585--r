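#' Write and read a cohort as plain-text fixture files
#'
#' A cohort round-trips through three CSV files in `dir`: `subjects.csv` (one
#' row per pregnancy), `measurements.csv` (wide: `subject_id` plus one column
#' per analyte, with an empty cell wherever the value is below the limit of
#' detection) and `analytes.csv` (the panel metadata including realised LODs).
#' `read_cohort(write_cohort(x, dir))` reproduces `x`, including the
#' below-LOD mask.
#'
#' @param cohort A `"cohort"` as returned by [generate_cohort()].
#' @param dir Directory to write to (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   `"cohort"` list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!all(c("subjects", "measurements", "analytes") %in% names(cohort))) {
    abort("`cohort` must have subjects, measurements and analytes components.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  wide <- cohort$measurements %>%
    select("subject_id", "analyte", "value") %>%
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  # keep subject order of the subjects table
  wide <- wide[match(cohort$subjects$subject_id, wide$subject_id), ]
  readr::write_csv(wide, file.path(dir, "measurements.csv"), na = "")
  readr::write_csv(cohort$analytes, file.path(dir, "analytes.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("subjects.csv", "measurements.csv", "analytes.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(sprintf("fixture file(s) not found: %s.",
                  paste(basename(missing), collapse = ", ")))
  }
  subjects <- readr::read_csv(paths[1], show_col_types = FALSE)
  wide <- readr::read_csv(paths[2], show_col_types = FALSE)
  analytes <- readr::read_csv(paths[3], show_col_types = FALSE)
  check_cols(wide, "subject_id", "measurements.csv")

  meas <- wide %>%
    tidyr::pivot_longer(-"subject_id", names_to = "analyte",
                        values_to = "value") %>%
    mutate(below_lod = is.na(.data$value))
  bad <- which(!is.na(meas$value) & meas$value <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "measurements.csv: non-positive concentration for subject %s, analyte %s.",
      meas$subject_id[bad[1]], meas$analyte[bad[1]]))
  }
  # preserve panel ordering of analyte columns
  meas <- arrange(meas, match(.data$analyte, analytes$name),
                  match(.data$subject_id, subjects$subject_id))
  structure(list(subjects = subjects, measurements = meas,
                 analytes = analytes),
            class = "cohort")
}
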