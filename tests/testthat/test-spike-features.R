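# Single-unit feature extraction: ISIs, firing rate, burst index (EM on log
# ISIs), robust CV, SNR estimation, inclusion filters.

test_that("interspike intervals follow the difference rule and reject bad input", {
  expect_equal(interspike_intervals(c(0.0, 0.1, 0.3)), c(0.1, 0.2))
  expect_error(interspike_intervals(c(0.1)), class = "mertopo_insufficient_data")
  expect_error(spike_segment("d", c(0.1, 0.1, 0.3), 1),
               class = "mertopo_config_error")
  seg <- regular_segment(fr = 10, duration = 1)
  expect_equal(interspike_intervals(seg), rep(0.1, 9))
})

test_that("firing rate is the inverse mean ISI", {
  expect_equal(firing_rate(rep(0.1, 9)), 10)
  expect_equal(firing_rate(0.5), 2)
  expect_equal(firing_rate(c(0.1, 0.3)), 5)
  expect_error(firing_rate(numeric(0)), class = "mertopo_insufficient_data")
})

test_that("robust CV is unscaled MAD over median", {
  expect_equal(coefficient_of_variation(rep(0.01, 50)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
})

test_that("robust CV of exponential ISIs matches the closed form", {
  # MAD of Exp(1) solves sinh(m) = 1/2; CV = asinh(0.5) / ln 2
  set.seed(1)
  isi <- rexp(1e6)
  expect_equal(coefficient_of_variation(isi), asinh(0.5) / log(2),
               tolerance = 0.01)
})

test_that("burst index recovers a two-point ISI mixture exactly", {
  isi <- rep(c(0.005, 0.05), each = 500)
  bi <- burst_index(isi)
  expect_false(attr(bi, "degenerate"))
  expect_equal(as.numeric(bi), 10, tolerance = 0.01)
  # seed-independent for well-separated point masses
  for (s in c(2, 17, 99)) {
    expect_equal(as.numeric(burst_index(isi, seed = s)), 10, tolerance = 0.01)
  }
})

test_that("burst index collapses to 1 on unimodal ISIs and needs enough data", {
  bi <- burst_index(rep(0.01, 100))
  expect_true(attr(bi, "degenerate"))
  expect_equal(as.numeric(bi), 1)
  expect_error(burst_index(rep(c(0.005, 0.05), 10)),
               class = "mertopo_insufficient_data")
})

test_that("burst index recovers the generating geometric-mean ratio", {
  set.seed(42)
  n <- 2000
  comp <- runif(n) < 0.5
  isi <- exp(ifelse(comp, rnorm(n, log(0.004), 0.2), rnorm(n, log(0.06), 0.2)))
  bi <- burst_index(isi, seed = 3)
  expect_equal(as.numeric(bi), 15, tolerance = 0.10)
})

test_that("burst index is invariant to ISI scaling, FR and CV covary correctly", {
  set.seed(5)
  isi <- exp(ifelse(runif(500) < 0.5, rnorm(500, log(0.005), 0.3),
                    rnorm(500, log(0.04), 0.3)))
  for (c0 in c(0.5, 3, 10)) {
    expect_equal(as.numeric(burst_index(isi * c0, seed = 1)),
                 as.numeric(burst_index(isi, seed = 1)), tolerance = 1e-6)
    expect_equal(firing_rate(isi * c0), firing_rate(isi) / c0)
    expect_equal(coefficient_of_variation(isi * c0),
                 coefficient_of_variation(isi))
  }
})

test_that("EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  n <- 1500
  comp <- runif(n) < 0.5
  isi <- exp(ifelse(comp, rnorm(n, log(0.005), 0.3), rnorm(n, log(0.05), 0.3)))
  bi <- burst_index(isi, seed = 2)
  mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the calling frame
  fit <- mclust::Mclust(log(isi), G = 2, modelNames = "V", verbose = FALSE)
  bi_ref <- unname(exp(abs(diff(fit$parameters$mean))))
  expect_equal(as.numeric(bi), bi_ref, tolerance = 0.02)
})

test_that("SNR estimate matches the construction and respects the cap", {
  set.seed(3)
  trace <- rnorm(20000, sd = 2)
  idx <- seq(500, 19500, by = 250)
  trace[idx] <- 6
  snr <- estimate_snr(trace, idx)
  expect_equal(snr, 3, tolerance = 0.1)
  expect_equal(estimate_snr(rep(0, 1000), c(100, 200)), 1e6)
  expect_true(is.na(estimate_snr(trace, integer(0))))
})

test_that("quality filter applies the inclusion rules with first-rule tallies", {
  qf <- quality_filter(filter_fixture())
  expect_length(qf$retained, 4)
  expect_equal(qf$excluded, c(short = 2L, snr = 3L, anatomy = 1L))

  # all-pass fixture: empty tally
  ok <- filter_fixture()[7:10]
  qf2 <- quality_filter(ok)
  expect_length(qf2$retained, 4)
  expect_length(qf2$excluded, 0)

  # a segment failing short AND low-SNR counts under 'short' only
  both <- spike_segment("b", c(0.1, 0.5), 2, snr = 1,
                        structure_imaging = "STN")
  qf3 <- quality_filter(list(both))
  expect_equal(qf3$excluded, c(short = 1L))
})

test_that("extracted features recover generator targets per condition", {
  # paper-scale cohort; extraction is compared cell-wise to the drawn targets
  co <- small_cohort()
  feats <- extract_unit_features(cohort_segments(co), seed = 7)
  m <- merge(feats, co$segments[, c("segment_id", "target_fr", "target_bi")],
             by = "segment_id")
  expect_gt(nrow(m), 50)
  expect_equal(mean(m$fr), mean(m$target_fr), tolerance = 0.05)
  ok <- !is.na(m$bi) & m$target_bi > 1.5  # near-degenerate targets collapse to 1
  expect_equal(mean(m$bi[ok]), mean(m$target_bi[ok]), tolerance = 0.1)
})
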