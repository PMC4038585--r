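#' Simulate outcomes from a known logistic prediction rule
#'
#' Draws covariates from stated distributions and then a Bernoulli outcome
#' with probability \eqn{\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j)}.
#' Used for coefficient-recovery simulations: outcomes generated from a known
#' rule should let [fit_combined_model()] recover that rule's coefficients.
#'
#' @param model A [risk_model()] (or anything with `intercept` and named
#'   `coefficients`).
#' @param covariate_config Named list with one entry per model term: either a
#'   numeric `c(mean =, sd =)` pair (drawn Normal) or a `function(n)`
#'   returning `n` draws.
#' @param n Number of subjects to simulate.
#' @param seed Integer seed.
#' @return A tibble with one column per covariate plus a 0/1 `outcome`.
#' @export
#' @examples
#' rule <- risk_model("eo_pe", intercept = -2.999,
#'                    coefficients = c(map_mom = 33.491, taurine = -2.490))
#' sim <- generate_from_risk_model(
#'   rule,
#'   list(map_mom = c(mean = 0, sd = 0.2), taurine = c(mean = 0, sd = 0.3)),
#'   n = 1000, seed = 1)
#' mean(sim$outcome)
generate_from_risk_model <- function(model, covariate_config, n, seed = 1L) {
  n <- check_count(n, "n")
  seed <- check_count(seed, "seed")
  terms <- names(model$coefficients)
  missing <- setdiff(terms, names(covariate_config))
  if (length(missing) > 0L) {
    abort(sprintf("covariate_config is missing model term(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  withr::with_seed(seed, {
    covs <- purrr::map(covariate_config, function(spec) {
      if (is.function(spec)) {
        spec(n)
      } else if (is.numeric(spec) && all(c("mean", "sd") %in% names(spec))) {
        rnorm(n, spec[["mean"]], spec[["sd"]])
      } else {
        abort("each covariate_config entry must be c(mean=, sd=) or function(n).")
      }
    })
    data <- if (length(covs) > 0L) as_tibble(covs) else tibble(.rows = n)
    lp <- rep(model$intercept, n)
    for (term in terms) {
      lp <- lp + model$coefficients[[term]] * data[[term]]
    }
    data$outcome <- rbinom(n, 1L, plogis(lp))
  })
  data
}
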