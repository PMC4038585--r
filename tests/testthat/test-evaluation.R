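test_that("detection rate at fixed FPR follows the quantile convention", {
  # perfect separation detects everything at any FPR
  res <- dr_at_fpr(c(10, 11, 12), c(1, 2, 3), fpr = 0.10)
  expect_equal(res$dr, 1.0)

  # worked example: threshold is the 9th of 10 ordered controls (0.09);
  # 0.095 and 0.099 exceed it, 0.05 does not
  controls <- seq(0.01, 0.10, by = 0.01)
  cases <- c(0.095, 0.099, 0.05)
  res <- dr_at_fpr(cases, controls, fpr = 0.10)
  oracle <- brute_force_dr(cases, controls, 0.10)
  expect_equal(res$threshold, 0.09)
  expect_equal(res$dr, 2 / 3)
  expect_equal(res$dr, oracle$dr)
  expect_equal(res$threshold, oracle$threshold)

  # exchangeable scores: realised DR is close to the FPR
  withr::with_seed(41, {
    x <- rnorm(20000); y <- rnorm(20000)
  })
  expect_equal(dr_at_fpr(x, y, 0.10)$dr, 0.10, tolerance = 0.1)

  # fpr = 1 places the threshold below all controls
  expect_equal(dr_at_fpr(c(-5, 0), c(1, 2), fpr = 1)$dr, 1.0)
  expect_error(dr_at_fpr(numeric(0), y), "nonempty")
})

test_that("detection rate is monotone in the allowed false-positive rate", {
  withr::with_seed(42, {
    cases <- rnorm(200, 1); controls <- rnorm(300)
  })
  fprs <- c(0.01, 0.05, 0.1, 0.2, 0.5, 1)
  drs <- vapply(fprs, function(f) dr_at_fpr(cases, controls, f)$dr, numeric(1))
  expect_true(all(diff(drs) >= 0))
})

test_that("dr_at_fpr and auc agree with brute force on many tiny score sets", {
  # exhaustive-style property: random small sets (sizes 1..8) drawn from a
  # coarse grid so ties occur often; compare with enumeration oracles
  withr::with_seed(43, {
    for (i in 1:300) {
      n1 <- sample(1:8, 1); n0 <- sample(1:8, 1)
      cases <- sample(seq(0, 1, by = 0.125), n1, replace = TRUE)
      controls <- sample(seq(0, 1, by = 0.125), n0, replace = TRUE)
      fpr <- sample(c(0.05, 0.1, 0.25, 0.5, 0.9), 1)
      res <- dr_at_fpr(cases, controls, fpr)
      oracle <- brute_force_dr(cases, controls, fpr)
      expect_equal(res$dr, oracle$dr)
      expect_equal(res$threshold, oracle$threshold)
      expect_lte(res$fpr, fpr)
      expect_equal(auc(cases, controls), brute_force_auc(cases, controls))
    }
  })
})

test_that("AUC has its closed-form values and invariances", {
  expect_equal(auc(c(3, 1), c(2, 0)), 0.75)  # 3>2, 3>0, 1>0, 1<2
  expect_equal(auc(c(5, 6), c(1, 2)), 1.0)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # invariant under strictly increasing transforms
  withr::with_seed(44, {
    cases <- rnorm(50); controls <- rnorm(70)
  })
  expect_equal(auc(cases, controls), auc(exp(cases), exp(controls)))
  expect_equal(auc(cases, controls), auc(plogis(cases), plogis(controls)))
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(45, {
    cases <- rnorm(80, 0.8); controls <- rnorm(120)
  })
  ours <- auc(cases, controls)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(80, 120)), predictor = c(cases, controls),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the Wilson interval matches its closed form and edge cases", {
  ci <- dr_confidence_interval(12, 21)
  z <- qnorm(0.975); p <- 12 / 21; n <- 21
  low <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  high <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(unname(ci), c(low, high))
  expect_equal(unname(dr_confidence_interval(21, 21))[2], 1.0)
  expect_equal(unname(dr_confidence_interval(0, 21))[1], 0.0)
  expect_error(dr_confidence_interval(5, 0), "positive")
  expect_error(dr_confidence_interval(22, 21), "exceed")
})

eval_fixture <- function(n_cases = 60, n_controls = 200, shift = 1.5,
                         seed = 46) {
  withr::with_seed(seed, {
    tibble::tibble(
      subject_id = sprintf("s%04d", seq_len(n_cases + n_controls)),
      outcome = rep(c(1L, 0L), c(n_cases, n_controls)),
      score = rnorm(n_cases + n_controls) +
        shift * rep(c(1, 0), c(n_cases, n_controls)),
      birthweight_centile = runif(n_cases + n_controls, 0, 100))
  })
}

score_model <- risk_model("eo_pe", intercept = 0, coefficients = c(score = 1))

test_that("evaluate_model summarises DR, CI, AUC and threshold coherently", {
  d <- eval_fixture()
  perf <- evaluate_model(score_model, d, dataset = "test", fpr = 0.10)
  expect_s3_class(perf, "screening_performance")
  expect_true(perf$dr_low <= perf$dr_at_fpr && perf$dr_at_fpr <= perf$dr_high)
  expect_true(perf$auc > 0.5 && perf$auc <= 1)
  scores <- predict_risk(score_model, d)
  direct <- dr_at_fpr(scores[d$outcome == 1], scores[d$outcome == 0], 0.10)
  expect_equal(perf$dr_at_fpr, direct$dr)
  # evaluating twice is deterministic
  expect_equal(perf, evaluate_model(score_model, d, dataset = "test"))
})

test_that("best-model selection prefers parsimony at equal detection", {
  perfs <- tibble::tibble(
    model_id = c("prior", "prior + MAP + taurine",
                 "prior + MAP + taurine + asparagine"),
    dr_at_fpr = c(0.69, 0.88, 0.88),
    n_terms = c(1L, 3L, 4L))
  expect_equal(select_best_model(perfs), "prior + MAP + taurine")
  expect_equal(select_best_model(perfs[1, ]), "prior")
  inc <- tibble::tibble(model_id = c("a", "b", "c"),
                        dr_at_fpr = c(0.1, 0.5, 0.9), n_terms = 1:3)
  expect_equal(select_best_model(inc), "c")
})

test_that("validation refuses subject overlap and matches evaluation", {
  d <- eval_fixture()
  v <- validate_model(score_model, d, seen_ids = character(0))
  expect_equal(v$dataset, "validation")
  expect_equal(v$dr_at_fpr,
               evaluate_model(score_model, d, "validation")$dr_at_fpr)
  expect_error(validate_model(score_model, d, seen_ids = d$subject_id[5]),
               "overlap")
})

test_that("permuted labels drive the validated DR towards the FPR", {
  d <- eval_fixture(n_cases = 2000, n_controls = 2000, shift = 1.5)
  withr::with_seed(47, d$outcome <- sample(d$outcome))
  perf <- evaluate_model(score_model, d, fpr = 0.10)
  expect_equal(perf$dr_at_fpr, 0.10, tolerance = 0.3)
})

test_that("subgroup performance restricts cases and keeps all controls", {
  d <- eval_fixture()
  all_cases <- subgroup_performance(score_model, d, ~rep(TRUE, nrow(d)))
  overall <- evaluate_model(score_model, d, dataset = "subgroup")
  expect_equal(all_cases$dr_at_fpr, overall$dr_at_fpr)
  expect_equal(all_cases$auc, overall$auc)

  none <- subgroup_performance(score_model, d, ~rep(FALSE, nrow(d)))
  expect_equal(none$n_cases, 0L)
  expect_true(is.na(none$dr_at_fpr))

  # centiles independent of scores: subgroup DR close to overall DR
  sub <- subgroup_performance(score_model, d, ~.data$birthweight_centile < 50)
  expect_gt(sub$n_cases, 0)
  expect_equal(sub$dr_at_fpr, overall$dr_at_fpr, tolerance = 0.35)
  expect_equal(sub$n_controls, overall$n_controls)
})

test_that("roc_points trace the empirical curve from (0,0) to (1,1)", {
  d <- eval_fixture(n_cases = 20, n_controls = 30)
  pts <- roc_points(d$score[d$outcome == 1], d$score[d$outcome == 0])
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})
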