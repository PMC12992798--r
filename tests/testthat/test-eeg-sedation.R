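# SEF95 sedation indexing: epoching, artifact rejection, normalized PSD,
# spectral edge computation, and the generator round trip.

sine_record <- function(freq = 10, amp = 20, duration = 60, fs = 250,
                        n_ch = 2) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  eeg_record(replicate(n_ch, amp * sin(2 * pi * freq * t)), fs = fs)
}

test_that("epoching cuts non-overlapping 2-s windows and drops partials", {
  rec <- eeg_record(matrix(rnorm(2500), ncol = 1), fs = 250)
  ep <- epoch_eeg(rec)                     # 10 s -> 5 epochs of 500 samples
  expect_equal(dim(ep), c(500, 5))
  rec2 <- eeg_record(matrix(rnorm(2375), ncol = 1), fs = 250)
  expect_equal(ncol(epoch_eeg(rec2)), 4)   # 9.5 s -> 4 epochs
  rec3 <- eeg_record(matrix(rnorm(500), ncol = 1), fs = 250)
  expect_equal(ncol(epoch_eeg(rec3)), 1)   # exactly one epoch
  rec4 <- eeg_record(matrix(rnorm(400), ncol = 1), fs = 250)
  expect_error(epoch_eeg(rec4), class = "mertopo_insufficient_data")
})

test_that("artifact rejection drops large-amplitude epochs only", {
  rec <- sine_record(amp = 20, duration = 10)
  ep <- epoch_eeg(rec)
  r <- reject_artifacts(ep)
  expect_equal(r$rejected_count, 0)
  ep2 <- ep
  ep2[100, 2] <- 500
  r2 <- reject_artifacts(ep2)
  expect_equal(r2$rejected_count, 1)
  expect_equal(ncol(r2$retained), ncol(ep) - 1)
  r3 <- reject_artifacts(ep[, 0, drop = FALSE])
  expect_equal(r3$rejected_count, 0)
})

test_that("normalized PSD is flat for white noise, concentrated for a sine, sums to 1", {
  set.seed(2)
  rec <- eeg_record(matrix(rnorm(250 * 240), ncol = 1), fs = 250)  # 240 s
  psd <- normalized_psd(epoch_eeg(rec))
  expect_equal(sum(psd$power), 1)
  expect_lt(max(psd$power) / min(psd$power), 3)

  psd_sine <- normalized_psd(epoch_eeg(sine_record(freq = 10)))
  near <- abs(psd_sine$freq - 10) <= 1
  expect_gte(sum(psd_sine$power[near]), 0.95)

  expect_error(normalized_psd(epoch_eeg(sine_record(duration = 10))),
               class = "mertopo_insufficient_data")
})

test_that("SEF95 matches closed forms", {
  flat <- psd_from_values(seq(1, 30, by = 0.5), rep(1, 59), band = c(0.5, 30))
  expect_equal(sef95(flat), 0.5 + 0.95 * 29.5)

  point <- psd_from_values(12, 1, band = c(0.5, 30))
  expect_equal(sef95(point), 12)

  f <- seq(0.5005, 30, by = 0.001)
  inv2 <- psd_from_values(f, f^-2, band = c(0.5, 30))
  # closed form: F solving (2 - 1/F) / (2 - 1/30) = 0.95
  expect_equal(sef95(inv2), 1 / (2 - 0.95 * (2 - 1 / 30)), tolerance = 0.005)
})

test_that("SEF95 is monotone under shifting power downward and amplitude-invariant", {
  f <- seq(1, 30, by = 0.5)
  p_hi <- psd_from_values(f, dnorm(f, 20, 3), band = c(0.5, 30))
  p_lo <- psd_from_values(f, dnorm(f, 8, 3), band = c(0.5, 30))
  expect_lt(sef95(p_lo), sef95(p_hi))

  rec <- generate_eeg(15, 60, 2, 250, seed = 9)
  s1 <- sedation_for_mer(rec)$sef95
  rec_scaled <- eeg_record(rec$channels * 0.2, rec$fs)
  expect_equal(sedation_for_mer(rec_scaled)$sef95, s1)
})

test_that("sedation_for_mer restricts to the MER window and validates it", {
  rec <- generate_eeg(20, 120, 2, 250, seed = 4)
  expect_error(sedation_for_mer(rec, window = c(100, 130)),
               class = "mertopo_config_error")
  s_a <- sedation_for_mer(rec, window = c(0, 55))$sef95
  s_b <- sedation_for_mer(rec, window = c(60, 115))$sef95
  expect_lt(abs(s_a - s_b), 1)  # stationary record: windows agree
  full <- sedation_for_mer(rec)
  expect_true(full$sef95 > 19 && full$sef95 < 21)
})

test_that("EEG text round trip preserves the record", {
  rec <- generate_eeg(12, 40, 3, 250, seed = 6)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "p.csv")
  writeLines(sprintf("# fs=%g", rec$fs), path)
  suppressWarnings(utils::write.table(
    round(rec$channels, 4), path, sep = ",", quote = FALSE, row.names = FALSE,
    col.names = c("ch1", "ch2", "ch3"), append = TRUE))
  back <- read_eeg(path)
  expect_equal(back$fs, 250)
  expect_equal(dim(back$channels), dim(rec$channels))
  expect_equal(sedation_for_mer(back)$sef95, sedation_for_mer(rec)$sef95,
               tolerance = 0.01)
})
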