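# Synthetic cohort generator: determinism, configuration contracts, spike
# train / RMS / EEG calibration, and the dose-response structure.

test_that("cohort generation is deterministic for a fixed seed", {
  c1 <- generate_cohort(tiny_config(), seed = 5)
  c2 <- generate_cohort(tiny_config(), seed = 5)
  expect_identical(c1$segments, c2$segments)
  expect_identical(c1$rms, c2$rms)
  expect_identical(c1$spike_times, c2$spike_times)
  expect_identical(c1$electrodes, c2$electrodes)
  c3 <- generate_cohort(tiny_config(), seed = 6)
  expect_false(identical(c1$segments, c3$segments))
})

test_that("frac_la = 1 labels every patient LA with absent doses", {
  co <- generate_cohort(tiny_config(frac_la = 1), seed = 2)
  expect_true(all(co$patients$group == "LA"))
  expect_true(all(is.na(co$hemispheres$propofol_rate)))
  expect_true(all(co$trajectories$condition == "LA"))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(frac_la = 1.2), "frac_la",
               class = "mertopo_config_error")
  expect_error(cohort_config(propofol_range = c(0, 8)), "propofol_range",
               class = "mertopo_config_error")
  expect_error(cohort_config(propofol_sd = -1), "propofol_sd",
               class = "mertopo_config_error")
  expect_error(cohort_config(burst_weight = 1.5), "burst_weight",
               class = "mertopo_config_error")
})

test_that("paper-scale GA doses average near the configured mean", {
  co <- generate_cohort(cohort_config(eeg = FALSE), seed = 1)
  expect_equal(sum(co$patients$group == "LA"), 11)
  expect_equal(sum(co$patients$group == "GA"), 14)
  doses <- co$hemispheres$propofol_rate[co$hemispheres$condition != "LA"]
  expect_true(all(doses >= 1 & doses <= 7.5))
  expect_lt(abs(mean(doses) - 3.9), 0.5)
})

test_that("generated feature targets match the configured distributions", {
  set.seed(77)
  b <- mertopo:::rshiftlnorm(2e4, 11.98, 9.53)
  expect_true(all(b >= 1))
  expect_equal(mean(b), 11.98, tolerance = 0.05)
  expect_equal(sd(b), 9.53, tolerance = 0.05)
  f <- mertopo:::rtruncnorm(2e4, 21.07, 14.37, lo = 0.5, match_mean = TRUE)
  expect_true(all(f > 0.5))
  expect_equal(mean(f), 21.07, tolerance = 0.05)

  # cohort-level: per-condition depth means recover the configured targets
  co <- generate_cohort(cohort_config(eeg = FALSE), seed = 3)
  fp <- co$config$feature_params
  for (cond in c("LA", "GA_high")) {
    tgt <- fp$depth_mean[fp$condition == cond]
    got <- mean(co$segments$depth_to_target[co$segments$condition == cond])
    expect_lt(abs(got - tgt), 0.45)
  }
})

test_that("spike trains are calibrated in rate and burstiness", {
  st <- generate_spike_train(60, 20, 10, seed = 7)
  expect_true(all(diff(st) > 0) && all(st >= 0 & st <= 60))
  expect_identical(st, generate_spike_train(60, 20, 10, seed = 7))

  # bi = 1: single-component train, extracted BI stays near 1
  st1 <- generate_spike_train(60, 20, 1, seed = 4)
  bi1 <- burst_index(interspike_intervals(st1), seed = 1)
  expect_lte(as.numeric(bi1), 1.5)

  # median extracted BI over independent seeds within 25% of the target
  bis <- vapply(1:50, function(s) {
    as.numeric(burst_index(interspike_intervals(
      generate_spike_train(60, 20, 10, seed = s)), seed = s))
  }, numeric(1))
  expect_lt(abs(median(bis) - 10) / 10, 0.25)

  # firing-rate calibration across seeds and burst levels
  for (bi in c(1, 4, 12)) {
    frs <- vapply(1:30, function(s) {
      firing_rate(interspike_intervals(
        generate_spike_train(60, 20, bi, seed = s + 100)))
    }, numeric(1))
    expect_lt(abs(median(frs) - 20) / 20, 0.15)
  }
  expect_error(generate_spike_train(3, 1, 2, seed = 1),
               class = "mertopo_generation_error")
})

test_that("RMS profiles show an STN plateau with dose-dependent suppression", {
  atlas <- atlas_geometry()
  geom <- trajectory_geometry(c(0, 0, 0), c(0, 0, -1))
  p_la <- generate_rms_profile(geom, atlas, NA, seed = 5)
  stn_in <- p_la$depths < p_la$stn_entry - 0.5 & p_la$depths > p_la$stn_exit + 0.5
  above <- p_la$depths > p_la$stn_entry + 1
  expect_gt(mean(p_la$rms[stn_in]), mean(p_la$rms[above]))

  p_hi <- generate_rms_profile(geom, atlas, 7.5, seed = 5)
  expect_true(all(p_hi$rms[stn_in] < p_la$rms[stn_in]))

  expect_equal(mertopo:::dose_suppression(3.0), 1)
  expect_equal(mertopo:::dose_suppression(NA), 1)
  doses <- seq(0.5, 7.5, by = 0.5)
  supp <- vapply(doses, mertopo:::dose_suppression, numeric(1))
  expect_true(all(diff(supp) <= 0))
})

test_that("EEG generation hits the target spectral edge and is seeded", {
  r20 <- generate_eeg(20, 60, 4, 250, seed = 3)
  s20 <- sedation_for_mer(r20)$sef95
  expect_true(s20 >= 19 && s20 <= 21)
  r8 <- generate_eeg(8, 60, 4, 250, seed = 3)
  s8 <- sedation_for_mer(r8)$sef95
  expect_true(s8 >= 7 && s8 <= 9)
  expect_identical(r20$channels, generate_eeg(20, 60, 4, 250, seed = 3)$channels)
  expect_error(generate_eeg(29, 60, 4, 250, seed = 1),
               class = "mertopo_generation_error")
})

test_that("dose monotonicity holds for SEF95 targets and burst index per condition", {
  co <- generate_cohort(cohort_config(eeg = FALSE), seed = 9)
  p <- co$patients
  ga <- !is.na(p$propofol_rate)
  # SEF95 declines with dose (up to the configured noise): check the trend
  fit <- lm(sef95_target ~ propofol_rate, data = p[ga, ])
  expect_lt(coef(fit)[2], 0)
  expect_gt(mean(p$sef95_target[!ga]), mean(p$sef95_target[ga]))
  # burst index higher under GA than LA
  expect_gt(mean(co$segments$target_bi[co$segments$condition != "LA"]),
            mean(co$segments$target_bi[co$segments$condition == "LA"]))
})

test_that("cohort writes and reads back as delimited text", {
  co <- generate_cohort(tiny_config(eeg = TRUE, eeg_duration = 40,
                                    n_patients = 2L), seed = 12)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "patients.tsv", "trajectories.tsv", "segments.tsv", "rms.tsv",
    "electrodes.tsv", "manifest.json")))))
  segs <- read_segments(dir)
  expect_length(segs, nrow(co$segments))
  j <- which(co$segments$segment_id == segs[[1]]$segment_id)
  expect_equal(segs[[1]]$spike_times, co$spike_times[[co$segments$segment_id[j]]],
               tolerance = 1e-8)
  rec <- read_eeg(file.path(dir, "eeg", paste0(co$patients$patient_id[1], ".csv")))
  expect_equal(rec$fs, co$config$eeg_fs)
})
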