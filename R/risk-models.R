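#' Construct a logistic risk model from explicit coefficients
#'
#' A risk model is an intercept plus named term coefficients on the log-odds
#' scale; predicted risk is \eqn{\mathrm{logit}^{-1}} of the linear
#' predictor. [fit_prior_risk()] and [fit_combined_model()] return the same
#' structure, so a published prediction rule can be written down directly and
#' evaluated, simulated from, or compared with a refit.
#'
#' @param outcome `"eo_pe"` or `"lo_pe"`.
#' @param intercept Intercept on the log-odds scale.
#' @param coefficients Named numeric vector of term coefficients (may be
#'   empty).
#' @param offset Optional name of a column added to the linear predictor with
#'   coefficient fixed at 1 (used for "prior risk as offset" models).
#' @param fit Optional underlying `glm` fit.
#' @param n_cases,n_controls Training counts (metadata).
#' @param model_id Optional label.
#' @return An object of class `"risk_model"`.
#' @export
#' @examples
#' eo_rule <- risk_model("eo_pe", intercept = -2.999,
#'                       coefficients = c(MAP = 33.491, taurine = -2.490))
#' predict_risk(eo_rule, tibble::tibble(MAP = 0, taurine = 0))
risk_model <- function(outcome, intercept, coefficients = numeric(0),
                       offset = NULL, fit = NULL,
                       n_cases = NA_integer_, n_controls = NA_integer_,
                       model_id = NULL) {
  outcome <- check_outcome(outcome)
  check_number(intercept, "intercept")
  if (length(coefficients) > 0L &&
      (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))) {
    abort("`coefficients` must be a named numeric vector.")
  }
  if (any(!is.finite(coefficients))) abort("coefficients must be finite.")
  structure(
    list(outcome = outcome, intercept = intercept,
         coefficients = coefficients, offset = offset, fit = fit,
         n_cases = n_cases, n_controls = n_controls,
         model_id = model_id %||%
           if (length(coefficients) > 0L) {
             paste(names(coefficients), collapse = " + ")
           } else "intercept-only"),
    class = "risk_model")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.risk_model <- function(x, ...) {
  terms <- if (length(x$coefficients) > 0L) {
    paste(sprintf("%+.4g x %s", x$coefficients, names(x$coefficients)),
          collapse = " ")
  } else ""
  cat(sprintf("<risk_model: %s> logit(risk) = %.4g %s\n",
              x$outcome, x$intercept, terms))
  if (!is.null(x$offset)) cat(sprintf("  + offset(%s)\n", x$offset))
  invisible(x)
}

#' Fit the prior-risk logistic model from maternal characteristics
#'
#' Maximum-likelihood logistic regression of case status on maternal
#' characteristics alone (by default nulliparity, weight, history of
#' hypertensive pregnancy disorders and smoking), fitted on the designated
#' training subjects only. This is the pregnancy's baseline risk before any
#' marker information.
#'
#' @param subjects Subject tibble restricted to the training set (controls
#'   plus the outcome group's cases; other groups are ignored).
#' @param outcome `"eo_pe"` or `"lo_pe"`.
#' @param terms Characteristic columns to use; a characteristic constant in
#'   the training data (e.g. a rare history with no carriers in a small
#'   split) is dropped with a warning.
#' @return A `"risk_model"` whose extra `prior` component holds each training
#'   subject's prior risk and prior log-odds.
#' @export
fit_prior_risk <- function(subjects, outcome,
                           terms = c("nulliparous", "weight_kg",
                                     "history_htn", "smoking")) {
  outcome <- check_outcome(outcome)
  check_cols(subjects, c("subject_id", "group", terms), "subjects")
  data <- subjects %>%
    filter(.data$group %in% c("control", .env$outcome)) %>%
    mutate(.case = as.integer(.data$group == .env$outcome),
           dplyr::across(dplyr::all_of(terms), as.numeric))
  n_cases <- sum(data$.case)
  n_controls <- sum(1L - data$.case)
  if (n_cases < 10L || n_controls < 10L) {
    abort("need at least 10 cases and 10 controls in the training set.")
  }
  constant <- terms[purrr::map_lgl(terms, ~length(unique(data[[.x]])) < 2L)]
  if (length(constant) > 0L) {
    warn(sprintf("characteristic(s) constant in the training set, dropped: %s.",
                 paste(constant, collapse = ", ")))
    terms <- setdiff(terms, constant)
    if (length(terms) == 0L) abort("no non-constant characteristics left.")
  }
  fit <- glm(stats::reformulate(terms, response = ".case"),
             family = binomial(), data = data,
             control = list(epsilon = 1e-8, maxit = 100))
  check_glm_fit(fit, data$.case)
  cf <- coef(fit)
  model <- risk_model(outcome, intercept = unname(cf[1]),
                      coefficients = cf[-1], fit = fit,
                      n_cases = n_cases, n_controls = n_controls,
                      model_id = "prior")
  model$terms_used <- terms
  model$prior <- tibble(subject_id = data$subject_id,
                        prior_risk = unname(stats::fitted(fit)),
                        prior_logodds = unname(qlogis(stats::fitted(fit))))
  model
}

check_glm_fit <- function(fit, y) {
  if (!fit$converged) {
    abort("logistic fit did not converge within 100 iterations.")
  }
  if (any(is.na(coef(fit)))) {
    abort(sprintf("degenerate (collinear) design: coefficient(s) %s not estimable.",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  probs <- stats::fitted(fit)
  if (all(probs[y == 1] > 1 - 1e-8) && all(probs[y == 0] < 1e-8)) {
    abort("complete separation: case status is perfectly predicted.")
  }
  invisible(fit)
}

#' Fit a combined logistic risk model on training data
#'
#' Plain maximum-likelihood logistic regression of the binary outcome on the
#' given term columns (typically the prior log-odds plus log10-MoM values of
#' selected markers). No regularization; convergence tolerance 1e-8 with at
#' most 100 iterations; a rank-deficient design or non-convergence is an
#' error.
#'
#' @param data Tibble holding one column per term plus the outcome column.
#' @param outcome `"eo_pe"` or `"lo_pe"` (label stored on the model).
#' @param terms Term column names entering with free coefficients.
#' @param outcome_col Name of the 0/1 outcome column (default `"outcome"`).
#' @param offset_col Optional column added to the linear predictor with a
#'   fixed coefficient of 1.
#' @param model_id Optional label.
#' @return A `"risk_model"`.
#' @export
fit_combined_model <- function(data, outcome, terms,
                               outcome_col = "outcome", offset_col = NULL,
                               model_id = NULL) {
  outcome <- check_outcome(outcome)
  check_cols(data, c(terms, outcome_col, offset_col), "data")
  y <- data[[outcome_col]]
  if (!all(y %in% c(0, 1))) abort("outcome column must be 0/1.")
  rhs <- if (length(terms) > 0L) terms else "1"
  fml <- stats::reformulate(rhs, response = outcome_col)
  fit <- glm(fml, family = binomial(), data = data,
             offset = if (!is.null(offset_col)) data[[offset_col]],
             control = list(epsilon = 1e-8, maxit = 100))
  check_glm_fit(fit, y)
  cf <- coef(fit)
  risk_model(outcome, intercept = unname(cf[1]),
             coefficients = cf[-1], offset = offset_col, fit = fit,
             n_cases = sum(y == 1), n_controls = sum(y == 0),
             model_id = model_id %||% paste(c(terms, offset_col), collapse = " + "))
}

#' Predicted risk from a logistic model
#'
#' @param model A `"risk_model"`.
#' @param newdata Tibble with one column per model term (and the offset
#'   column, if any); a missing term is an error naming it.
#' @return Predicted probabilities in (0, 1).
#' @export
predict_risk <- function(model, newdata) {
  if (!inherits(model, "risk_model")) abort("`model` must be a risk_model.")
  needed <- c(names(model$coefficients), model$offset)
  missing <- setdiff(needed, names(newdata))
  if (length(missing) > 0L) {
    abort(sprintf("newdata is missing model term(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  lp <- rep(model$intercept, nrow(newdata))
  for (term in names(model$coefficients)) {
    lp <- lp + model$coefficients[[term]] * newdata[[term]]
  }
  if (!is.null(model$offset)) lp <- lp + newdata[[model$offset]]
  plogis(lp)
}

#' Enumerate candidate term sets for combined models
#'
#' All subsets of MAP and the selected markers, each combined with the prior
#' risk, including the prior-risk-only model — the candidate list a
#' best-model search over the test set ranges over.
#'
#' @param selected_markers Character vector of FDR-selected marker names
#'   (without MAP).
#' @param include_map Offer MAP as a candidate term (default `TRUE`).
#' @param prior_term Name of the prior-risk term (`"prior_logodds"`), present
#'   in every candidate; set to `NULL` to drop it.
#' @return A tibble with `model_id` and a `terms` list-column.
#' @export
#' @examples
#' enumerate_candidate_models(c("taurine", "asparagine"))
enumerate_candidate_models <- function(selected_markers, include_map = TRUE,
                                       prior_term = "prior_logodds") {
  pool <- c(if (include_map) "MAP", setdiff(selected_markers, "MAP"))
  subsets <- list(character(0))
  for (mk in pool) {
    subsets <- c(subsets, purrr::map(subsets, ~c(.x, mk)))
  }
  tibble(
    model_id = purrr::map_chr(subsets, ~paste(c("prior", .x), collapse = " + ")),
    terms = purrr::map(subsets, ~c(prior_term, .x))
  )
}

#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    model_id = x$model_id,
    n_terms = length(x$coefficients),
    n_cases = x$n_cases,
    n_controls = x$n_controls,
    deviance = if (!is.null(x$fit)) x$fit$deviance else NA_real_,
    aic = if (!is.null(x$fit)) x$fit$aic else NA_real_
  )
}
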