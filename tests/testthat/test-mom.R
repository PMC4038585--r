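make_curve_input <- function(weekly_medians, weeks, n_per_week = 30) {
  # constant concentration within each week so the weekly median is exact
  rows <- purrr::map2_dfr(weekly_medians, weeks, function(m, w) {
    days <- rep(seq(7 * w, 7 * w + 6), length.out = n_per_week)
    tibble::tibble(
      subject_id = sprintf("w%d_%02d", w, seq_len(n_per_week)),
      ga_sampling_days = days, value = m)
  })
  list(
    measurements = tibble::tibble(subject_id = rows$subject_id,
                                  analyte = "x", value = rows$value,
                                  below_lod = FALSE),
    subjects = tibble::tibble(subject_id = rows$subject_id, group = "control",
                              ga_sampling_days = rows$ga_sampling_days)
  )
}

test_that("constant concentrations give a flat median curve", {
  inp <- make_curve_input(c(10, 10, 10), weeks = 8:10)
  curves <- fit_median_curves(inp$measurements, inp$subjects,
                              inp$subjects$subject_id)
  expect_equal(curves$slope, 0, tolerance = 1e-12)
  expect_equal(predict_median(curves, "x", c(56, 77, 97)), rep(10, 3))
})

test_that("the weighted fit recovers an exact log-linear trend", {
  # medians doubling each week lie exactly on a line in log10, so the fitted
  # slope equals log10(2) per week regardless of weights
  inp <- make_curve_input(c(10, 20, 40), weeks = 8:10)
  curves <- fit_median_curves(inp$measurements, inp$subjects,
                              inp$subjects$subject_id)
  expect_equal(curves$slope * 7, log10(2), tolerance = 1e-10)

  # oracle: hand-computed weighted least squares on the three weekly points
  x <- 7 * (8:10) + 3
  y <- log10(c(10, 20, 40))
  w <- rep(30, 3)
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  expect_equal(curves$slope, slope, tolerance = 1e-12)
  expect_equal(curves$intercept, yb - slope * xb, tolerance = 1e-10)
})

test_that("scaling all week weights leaves the curve unchanged", {
  inp <- make_curve_input(c(10, 20, 40), weeks = 8:10, n_per_week = 10)
  inp2 <- make_curve_input(c(10, 20, 40), weeks = 8:10, n_per_week = 20)
  c1 <- fit_median_curves(inp$measurements, inp$subjects,
                          inp$subjects$subject_id)
  c2 <- fit_median_curves(inp2$measurements, inp2$subjects,
                          inp2$subjects$subject_id)
  expect_equal(c1$slope, c2$slope)
  expect_equal(c1$intercept, c2$intercept)
})

test_that("curve fitting demands at least two represented weeks", {
  inp <- make_curve_input(10, weeks = 8)
  expect_error(fit_median_curves(inp$measurements, inp$subjects,
                                 inp$subjects$subject_id),
               "at least 2")
})

test_that("MoM is the value over the gestation-specific expected median", {
  inp <- make_curve_input(c(10, 20, 40), weeks = 8:10)
  curves <- fit_median_curves(inp$measurements, inp$subjects,
                              inp$subjects$subject_id)
  probe <- function(value, ga) {
    m <- tibble::tibble(subject_id = "p", analyte = "x", value = value,
                        below_lod = FALSE)
    s <- tibble::tibble(subject_id = "p", group = "control",
                        ga_sampling_days = ga)
    compute_mom(m, curves, s)$mom
  }
  ga <- 59  # week-8 midpoint, expected median 10
  expect_equal(probe(10, ga), 1.0, tolerance = 1e-10)
  expect_equal(probe(20, ga), 2.0, tolerance = 1e-10)
  expect_equal(probe(7.9, ga), 0.79, tolerance = 1e-10)
  m <- tibble::tibble(subject_id = "p", analyte = "x", value = 10,
                      below_lod = FALSE)
  s <- tibble::tibble(subject_id = "p", group = "control",
                      ga_sampling_days = 120L)
  expect_error(compute_mom(m, curves, s), "window")
})

test_that("control MoM medians sit near 1 in every completed week", {
  cohort <- generate_cohort(small_config(n_controls = 3000, n_eo = 50,
                                         n_lo = 50, seed = 6))
  # all controls serve as the training set: ~500 per completed week, so the
  # weekly-median Monte-Carlo noise (~1% here) sits well inside the 3% band
  train_ids <- cohort$subjects$subject_id
  meas <- impute_below_lod(cohort$measurements)
  curves <- fit_median_curves(meas, cohort$subjects, train_ids)
  moms <- compute_mom(meas, curves, cohort$subjects)
  weekly <- moms |>
    dplyr::filter(subject_id %in% train_ids) |>
    dplyr::semi_join(dplyr::filter(cohort$subjects, group == "control"),
                     by = "subject_id") |>
    dplyr::left_join(cohort$subjects[c("subject_id", "ga_sampling_days")],
                     by = "subject_id") |>
    dplyr::mutate(week = completed_week(ga_sampling_days)) |>
    dplyr::filter(marker == "taurine") |>
    dplyr::group_by(week) |>
    dplyr::summarise(med = median(mom), n = dplyr::n())
  expect_true(all(weekly$n >= 50))
  expect_true(all(abs(weekly$med - 1) < 0.03))
  # log10-MoM of the median control is near zero
  ctrl <- dplyr::semi_join(moms,
                           dplyr::filter(cohort$subjects, group == "control"),
                           by = "subject_id")
  expect_lt(abs(median(ctrl$log10_mom[ctrl$marker == "taurine"])), 0.02)
})

test_that("MoMs are invariant to rescaling an analyte's concentrations", {
  cohort <- generate_cohort(small_config(seed = 7))
  splits <- assign_splits(cohort$subjects, seed = 2)
  train_ids <- splits$subject_id[splits$set == "train"]
  meas <- impute_below_lod(cohort$measurements)
  scaled <- dplyr::mutate(
    meas, value = ifelse(analyte == "taurine", value * 37.5, value))
  mom1 <- compute_mom(meas, fit_median_curves(meas, cohort$subjects, train_ids),
                      cohort$subjects)
  mom2 <- compute_mom(scaled,
                      fit_median_curves(scaled, cohort$subjects, train_ids),
                      cohort$subjects)
  expect_equal(mom1$mom, mom2$mom, tolerance = 1e-10)
})

test_that("mom_ratio is the ratio of group medians", {
  expect_equal(mom_ratio(c(1, 2, 3), c(1, 2, 3)), 1.0)
  x <- stats::runif(101, 0.5, 2)
  expect_equal(mom_ratio(x * 0.72, x), 0.72)
  expect_error(mom_ratio(numeric(0), x), "nonempty")
  # geometric option
  expect_equal(mom_ratio(x * 0.72, x, type = "geometric"), 0.72)
})

test_that("the configured effect size survives the whole MoM pipeline", {
  cohort <- generate_cohort(cohort_config(
    n_controls = 5000, n_eo = 5000, n_lo = 0,
    analytes = analyte_spec("taurine", momr_eo = 0.79), seed = 13))
  splits <- assign_splits(cohort$subjects, seed = 13)
  train_ids <- splits$subject_id[splits$set == "train"]
  curves <- fit_median_curves(cohort$measurements, cohort$subjects, train_ids)
  moms <- compute_mom(cohort$measurements, curves, cohort$subjects)
  grp <- cohort$subjects$group[match(moms$subject_id,
                                     cohort$subjects$subject_id)]
  r <- mom_ratio(moms$mom[grp == "eo_pe"], moms$mom[grp == "control"])
  expect_equal(r, 0.79, tolerance = 0.02 / 0.79)
})
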