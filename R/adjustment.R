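#' Fit covariate adjustments for log10-MoM values
#'
#' Standard Cuckle-Wald practice: among training-set controls, each candidate
#' maternal covariate is tested for association with a marker's log10-MoM
#' (regression-slope t-test for numeric covariates such as weight; Student's
#' t-test / one-way ANOVA for binary or categorical covariates such as
#' smoking and ethnicity). Covariates significant at `alpha` are then fitted
#' jointly by least squares, and that fitted effect is later subtracted on
#' the log10-MoM scale. Gestational age is not a candidate here: the median
#' curve already removes it, and re-adjusting would double-correct.
#'
#' @param mom_table MoM tibble from [compute_mom()].
#' @param subjects Subject tibble carrying the covariate columns.
#' @param training_ids Training-set subject ids; only training controls are
#'   used for testing and fitting.
#' @param covariates Candidate covariate column names (default weight,
#'   smoking, ethnicity). A covariate constant among training controls is
#'   skipped with a warning.
#' @param alpha Two-sided significance gate (default 0.05).
#' @return A tibble of class `"mom_adjustment"`: per marker, the gate
#'   outcomes (`gates` list-column), the applied covariates, and the joint
#'   least-squares fit with its centring constant.
#' @export
fit_adjustment <- function(mom_table, subjects, training_ids,
                           covariates = c("weight_kg", "smoking", "ethnicity"),
                           alpha = 0.05) {
  check_cols(mom_table, c("subject_id", "marker", "log10_mom"), "mom_table")
  check_cols(subjects, c("subject_id", "group"), "subjects")
  if (length(covariates) > 0L) check_cols(subjects, covariates, "subjects")
  check_number(alpha, "alpha", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)

  ctrl <- subjects %>%
    filter(.data$group == "control", .data$subject_id %in% training_ids)
  usable <- character(0)
  for (cv in covariates) {
    vals <- ctrl[[cv]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      warn(sprintf("covariate `%s` is constant among training controls; skipped.", cv))
    } else {
      usable <- c(usable, cv)
    }
  }

  markers <- unique(mom_table$marker)
  rows <- purrr::map(markers, function(mk) {
    data <- mom_table %>%
      filter(.data$marker == mk) %>%
      semi_join(ctrl, by = "subject_id") %>%
      left_join(ctrl, by = "subject_id")
    gates <- purrr::map_dfr(usable, function(cv) {
      tibble(covariate = cv,
             p_value = covariate_gate_p(data$log10_mom, data[[cv]]))
    })
    if (nrow(gates) > 0L) gates$significant <- gates$p_value < alpha
    applied <- if (nrow(gates) > 0L) gates$covariate[gates$significant] else character(0)
    if (length(applied) > 0L) {
      fml <- stats::reformulate(applied, response = "log10_mom")
      fit <- lm(fml, data = data)
      center <- mean(predict(fit))
    } else {
      fit <- NULL
      center <- 0
    }
    tibble(marker = mk, gates = list(gates),
           covariates = list(applied), fit = list(fit), center = center)
  })
  structure(bind_rows(rows), class = c("mom_adjustment", class(tibble())))
}

# association p-value of one covariate with log10-MoM among training controls
covariate_gate_p <- function(log10_mom, covariate) {
  if (is.numeric(covariate)) {
    fit <- lm(log10_mom ~ covariate)
    summary(fit)$coefficients["covariate", "Pr(>|t|)"]
  } else {
    f <- factor(covariate)
    if (nlevels(f) == 2L) {
      t.test(log10_mom ~ f, var.equal = TRUE)$p.value
    } else {
      stats::anova(lm(log10_mom ~ f))[["Pr(>F)"]][1]
    }
  }
}

#' Apply a fitted covariate adjustment to a MoM table
#'
#' Adjusted log10-MoM = raw log10-MoM minus the fitted covariate effect,
#' centred so that a training control with average covariates is unchanged
#' (equivalently, MoM is divided by the expected MoM given the covariates).
#' Markers with no significant covariates pass through unchanged.
#'
#' @param mom_table MoM tibble from [compute_mom()].
#' @param adjustment A `"mom_adjustment"` from [fit_adjustment()].
#' @param subjects Subject tibble carrying covariate values for every subject
#'   in `mom_table`; a missing value is an error identifying the subject.
#' @return The MoM table with `log10_mom` and `mom` adjusted.
#' @export
apply_adjustment <- function(mom_table, adjustment, subjects) {
  if (!inherits(adjustment, "mom_adjustment")) {
    abort("`adjustment` must come from fit_adjustment().")
  }
  active <- adjustment[purrr::map_int(adjustment$covariates, length) > 0L, ]
  if (nrow(active) == 0L) return(mom_table)

  out <- mom_table
  for (i in seq_len(nrow(active))) {
    mk <- active$marker[i]
    fit <- active$fit[[i]]
    covs <- active$covariates[[i]]
    idx <- which(out$marker == mk)
    if (length(idx) == 0L) next
    newdata <- tibble(subject_id = out$subject_id[idx]) %>%
      left_join(select(subjects, "subject_id", dplyr::all_of(covs)),
                by = "subject_id")
    incomplete <- !complete.cases(newdata[covs])
    if (any(incomplete)) {
      abort(sprintf("missing covariate value(s) for subject %s (marker %s).",
                    newdata$subject_id[which(incomplete)[1]], mk))
    }
    effect <- predict(fit, newdata = newdata) - active$center[i]
    out$log10_mom[idx] <- out$log10_mom[idx] - effect
    out$mom[idx] <- 10^out$log10_mom[idx]
  }
  out
}
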