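# run the generator + full MoM normalization and return the empirical
# case/control MoM ratio for one marker
momr_recovery <- function(analytes, outcome, marker, seed,
                          n_per_group = 5000, map_spec = map_marker_spec()) {
  cfg <- cohort_config(
    n_controls = n_per_group,
    n_eo = if (outcome == "eo_pe") n_per_group else 0,
    n_lo = if (outcome == "lo_pe") n_per_group else 0,
    analytes = analytes, map_spec = map_spec, seed = seed)
  cohort <- generate_cohort(cfg)
  meas <- dplyr::bind_rows(cohort$measurements, map_as_marker(cohort$subjects))
  splits <- assign_splits(cohort$subjects, seed = seed)
  train_ids <- splits$subject_id[splits$set == "train"]
  curves <- fit_median_curves(meas, cohort$subjects, train_ids)
  moms <- compute_mom(meas, curves, cohort$subjects)
  grp <- cohort$subjects$group[match(moms$subject_id,
                                     cohort$subjects$subject_id)]
  mk <- moms$marker == marker
  mom_ratio(moms$mom[mk & grp == outcome], moms$mom[mk & grp == "control"])
}
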