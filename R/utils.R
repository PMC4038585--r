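# internal validation helpers

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 0 || x != trunc(x)) {
    abort(sprintf("`%s` must be a single non-negative integer.", name))
  }
  invisible(as.integer(x))
}

check_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# round-half-up, unlike base round() which rounds half to even
round_half_up <- function(x) floor(x + 0.5)

# inverse-CDF truncated normal draw on [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, p_lo, p_hi), mean, sd)
}

outcome_groups <- c("control", "eo_pe", "lo_pe")

check_outcome <- function(outcome) {
  if (!is.character(outcome) || length(outcome) != 1L ||
      !outcome %in% c("eo_pe", "lo_pe")) {
    abort('`outcome` must be "eo_pe" or "lo_pe".')
  }
  outcome
}
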