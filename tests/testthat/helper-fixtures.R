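# Shared fixtures: compact cohort configurations and hand-built segments.

tiny_config <- function(...) {
  args <- utils::modifyList(list(n_patients = 6L, frac_la = 0.5, eeg = FALSE,
                                 sua_rate_base = 4), list(...))
  do.call(cohort_config, args)
}

# A small cohort cached per test run (generation is seeded and cheap).
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function(seed = 101L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(tiny_config(), seed = seed)
  }
  .fixture_env[[key]]
}

# Segment with a perfectly regular train at `fr` Hz.
regular_segment <- function(id = "seg1", fr = 10, duration = 1,
                            snr = 8, ...) {
  spike_segment(id, seq(0, duration - 1 / fr, by = 1 / fr), duration,
                snr = snr, structure_imaging = "STN", ...)
}

# Ten segments: 2 short, 3 low-SNR, 1 outside both nuclei, 4 clean.
filter_fixture <- function() {
  mk <- function(id, duration = 10, snr = 8, structure = "STN", single = TRUE) {
    spike_segment(id, c(0.1, 0.2, 0.4), duration, snr = snr,
                  is_single_unit = single, structure_imaging = structure)
  }
  list(mk("short1", duration = 2), mk("short2", duration = 1.5),
       mk("low1", snr = 1), mk("low2", snr = 2.5), mk("low3", snr = 2.9),
       mk("out1", structure = "other"),
       mk("ok1"), mk("ok2", structure = "SNr"), mk("ok3"), mk("ok4"))
}
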