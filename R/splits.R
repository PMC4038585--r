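#' Train/test/validation sizes for one outcome group
#'
#' Sizes follow a 40/30/30 design with round-half-up on the training and test
#' counts and the validation set as the remainder — the rule that reproduces
#' the printed assignment of a 500/68/99 cohort exactly: 200/150/150 controls,
#' 27/20/21 early-onset and 40/30/29 late-onset cases.
#'
#' @param n Group size (at least 3).
#' @param fractions Length-3 fractions summing to 1 (train, test, validation).
#' @return Named integer vector `c(train, test, validation)`.
#' @export
#' @examples
#' split_sizes(68)
split_sizes <- function(n, fractions = c(0.4, 0.3, 0.3)) {
  n <- check_count(n, "n")
  if (n < 3L) abort("`n` must be at least 3 to populate all three sets.")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions <= 0)) {
    abort("`fractions` must be three positive numbers summing to 1.")
  }
  n_train <- as.integer(round_half_up(fractions[1] * n))
  n_test <- as.integer(round_half_up(fractions[2] * n))
  n_val <- n - n_train - n_test
  sizes <- c(train = n_train, test = n_test, validation = n_val)
  if (any(sizes < 1L)) {
    abort(sprintf("group of %d gives an empty set under these fractions.", n))
  }
  sizes
}

#' Randomly assign subjects to training, test and validation sets
#'
#' Within each outcome group, a seeded random permutation is cut at the
#' [split_sizes()] boundaries, so the partition is stratified by outcome
#' group, exhaustive and disjoint, and identical for identical seeds.
#'
#' @param subjects Subject tibble with `subject_id` and `group`.
#' @param fractions Passed to [split_sizes()].
#' @param seed Integer seed.
#' @return A tibble `subject_id`, `group`, `set` (factor
#'   train/test/validation).
#' @export
assign_splits <- function(subjects, fractions = c(0.4, 0.3, 0.3), seed = 1L) {
  check_cols(subjects, c("subject_id", "group"), "subjects")
  seed <- check_count(seed, "seed")
  withr::with_seed(seed, {
    out <- subjects %>%
      select("subject_id", "group") %>%
      group_by(.data$group) %>%
      mutate(.ord = sample.int(n())) %>%
      mutate(set = {
        sizes <- split_sizes(n(), fractions)
        cut(.data$.ord,
            breaks = c(0, cumsum(sizes)),
            labels = c("train", "test", "validation"))
      }) %>%
      ungroup() %>%
      select(-".ord")
  })
  out
}
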