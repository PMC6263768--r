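# Seeded simulation ensembles at the reference geometry, shared by the
# statistical property tests. Computed once per test run and cached.

ensemble_cache <- new.env(parent = emptyenv())

ensemble_seg <- function() segmentation_params(L = 100, delta_l = 10)

# 20 breathing targets in moderate clutter/noise: identification decision,
# enhanced-matrix peak, and paired AaT vs NON SNCR per seed.
breathing_ensemble <- function(n = 20L) {
  key <- paste0("breathing_", n)
  if (is.null(ensemble_cache[[key]])) {
    ensemble_cache[[key]] <- lapply(seq_len(n), function(s) {
      eb <- generate_fixture("breathing_cluttered", seed = s)
      dec <- identify_target(eb, ensemble_seg(), seed = s)
      emN <- run_enhancement(eb, pipe = pipeline_params("NON"))
      list(decision = dec$decision,
           peak = dec$enhanced_peak,
           range_bin = diff(dec$enhanced$range_axis[1:2]),
           freq_bin = diff(dec$enhanced$freq_axis[1:2]),
           sncr_aat = power_range_plot(dec$enhanced)$sncr,
           sncr_non = power_range_plot(emN)$sncr)
    })
  }
  ensemble_cache[[key]]
}

# 20 clutter-only scenes (no target): identification decision per seed.
clutter_ensemble <- function(n = 20L) {
  key <- paste0("clutter_", n)
  if (is.null(ensemble_cache[[key]])) {
    ensemble_cache[[key]] <- vapply(seq_len(n), function(s) {
      ec <- generate_fixture("clutter_only", seed = 100L + s)
      identify_target(ec, ensemble_seg(), seed = s)$decision
    }, character(1))
  }
  ensemble_cache[[key]]
}
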