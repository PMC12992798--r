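# Single-unit feature extraction: firing rate, burst index (two-component
# Gaussian mixture on log interspike intervals), robust coefficient of
# variation, signal-to-noise estimation, and the study inclusion filters.

#' Construct a spike segment record
#'
#' One MER segment: a sorted spike-time vector plus the metadata needed by the
#' inclusion filters and the spatial mapping (depth along the trajectory,
#' duration, SNR, single-unit flag, structure labels).
#'
#' @param segment_id Identifier.
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing, within `[0, duration]`.
#' @param duration Segment duration in seconds (> 0).
#' @param depth_to_target Signed depth in mm; positive = dorsal of the planned
#'   target (the ventral STN border).
#' @param snr Signal-to-noise ratio (>= 0).
#' @param is_single_unit Logical; `FALSE` marks multi-unit activity.
#' @param structure_imaging,structure_intraop Structure labels
#'   (`"STN"`, `"SNr"`, `"other"`; intraop may be `"unlabelled"`).
#' @param patient_id,hemisphere,trajectory_id Optional provenance fields.
#' @return An object of class `spike_segment`.
#' @export
spike_segment <- function(segment_id, spike_times, duration,
                          depth_to_target = NA_real_, snr = NA_real_,
                          is_single_unit = TRUE,
                          structure_imaging = "unlabelled",
                          structure_intraop = "unlabelled",
                          patient_id = NA_character_,
                          hemisphere = NA_character_,
                          trajectory_id = NA_character_) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop_config("'duration' must be a single positive number")
  }
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && (any(spike_times < 0) || any(spike_times > duration))) {
    stop_config("spike times must lie within [0, duration]")
  }
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0)) {
    stop_config("spike times must be strictly increasing")
  }
  if (!is.na(snr) && snr < 0) stop_config("'snr' must be >= 0")
  structure(list(
    segment_id = segment_id, spike_times = spike_times, duration = duration,
    depth_to_target = depth_to_target, snr = snr,
    is_single_unit = isTRUE(is_single_unit),
    structure_imaging = structure_imaging,
    structure_intraop = structure_intraop,
    patient_id = patient_id, hemisphere = hemisphere,
    trajectory_id = trajectory_id
  ), class = "spike_segment")
}

#' @export
print.spike_segment <- function(x, ...) {
  cat(sprintf("<spike_segment %s: %d spikes / %.1f s, depth %.2f mm, snr %.1f, %s>\n",
              x$segment_id, length(x$spike_times), x$duration,
              x$depth_to_target, x$snr, x$structure_imaging))
  invisible(x)
}

#' Interspike intervals of a segment
#'
#' @param segment A `spike_segment`, or a numeric vector of sorted spike times.
#' @return Numeric vector of ISIs in seconds (length `n_spikes - 1`).
#' @export
interspike_intervals <- function(segment) {
  t <- if (inherits(segment, "spike_segment")) segment$spike_times else as.numeric(segment)
  if (length(t) < 2L) stop_insufficient("need at least 2 spikes to form ISIs")
  isi <- diff(t)
  if (any(isi <= 0)) stop_config("spike times must be strictly increasing")
  isi
}

#' Firing rate as the inverse of the mean interspike interval
#'
#' @param isi Numeric vector of ISIs in seconds.
#' @return Firing rate in Hz.
#' @export
firing_rate <- function(isi) {
  if (length(isi) < 1L) stop_insufficient("need at least 1 ISI")
  1 / mean(isi)
}

#' Robust coefficient of variation of the ISI distribution
#'
#' Median absolute deviation (unscaled, no normal-consistency constant)
#' divided by the median.
#'
#' @param isi Numeric vector of ISIs in seconds.
#' @return Unitless, >= 0.
#' @export
coefficient_of_variation <- function(isi) {
  if (length(isi) < 1L) stop_insufficient("need at least 1 ISI")
  med <- median(isi)
  median(abs(isi - med)) / med
}

#' Burst index from a two-component Gaussian mixture on log ISIs
#'
#' Fits a two-component Gaussian mixture to the natural-log ISI distribution by
#' expectation-maximization and returns the ratio of the component means. On
#' the default `"geometric"` scale this is `exp(mu_long - mu_short)`, the ratio
#' of the component geometric-mean ISIs, and is >= 1 by construction. The fit
#' collapses to a degenerate single component (BI reported as 1, flag set) when
#' the component means are closer than `collapse_eps` log-units or a component
#' weight falls below `w_min`.
#'
#' @param isi Numeric vector of ISIs in seconds; at least `min_isi` required.
#' @param seed Seed for the EM restarts.
#' @param min_isi Minimum number of ISIs for a reliable fit (default 30).
#' @param n_restarts EM restarts around the quantile-based initialization.
#' @param var_floor Variance floor in squared log-units.
#' @param w_min Component weight floor; smaller weights mark a collapsed fit.
#' @param collapse_eps Mean-separation tolerance (log-units) below which the
#'   fit is degenerate.
#' @param ratio_scale `"geometric"` (ratio of geometric-mean ISIs, default) or
#'   `"linear"` (ratio of the component arithmetic-mean ISIs,
#'   `exp(mu + s^2/2)` under log-normality).
#' @return Numeric burst index (>= 1) with attributes `degenerate` (logical)
#'   and `fit` (component means/sds/weights in log space).
#' @export
burst_index <- function(isi, seed = 1L, min_isi = 30L, n_restarts = 10L,
                        var_floor = 1e-4, w_min = 0.05, collapse_eps = 0.05,
                        ratio_scale = c("geometric", "linear")) {
  ratio_scale <- match.arg(ratio_scale)
  if (length(isi) < min_isi) {
    stop_insufficient(sprintf("need at least %d ISIs for the burst index", min_isi))
  }
  if (any(isi <= 0)) stop_config("ISIs must be positive")
  x <- log(isi)
  fit <- with_seed(seed, em_gmm2(x, n_restarts = n_restarts, var_floor = var_floor))
  lo <- which.min(fit$mu); hi <- which.max(fit$mu)
  sep <- fit$mu[hi] - fit$mu[lo]
  degenerate <- sep < collapse_eps || min(fit$w) < w_min
  bi <- if (degenerate) {
    1
  } else if (ratio_scale == "geometric") {
    exp(sep)
  } else {
    exp(fit$mu[hi] + fit$s2[hi] / 2) / exp(fit$mu[lo] + fit$s2[lo] / 2)
  }
  structure(bi, degenerate = degenerate,
            fit = list(mu = fit$mu[c(lo, hi)], s2 = fit$s2[c(lo, hi)],
                       w = fit$w[c(lo, hi)], loglik = fit$loglik))
}

# Two-component 1-D Gaussian mixture by EM. Initialization at the 25th/75th
# percentiles; restarts jitter the initial means. Variance floor guards
# point-mass components.
em_gmm2 <- function(x, n_restarts = 10L, var_floor = 1e-4,
                    tol = 1e-8, max_iter = 200L) {
  n <- length(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  jit_sd <- max(sd(x) / 4, sqrt(var_floor))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- if (r == 1L) q else q + rnorm(2L, 0, jit_sd)
    s2 <- rep(max(var(x) / 4, var_floor), 2L)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], sqrt(s2[1]))
      d2 <- w[2] * dnorm(x, mu[2], sqrt(s2[2]))
      tot <- d1 + d2
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      g <- d1 / tot
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
      n1 <- sum(g); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu[1] <- sum(g * x) / n1
      mu[2] <- sum((1 - g) * x) / n2
      s2[1] <- max(sum(g * (x - mu[1])^2) / n1, var_floor)
      s2[2] <- max(sum((1 - g) * (x - mu[2])^2) / n2, var_floor)
      w <- c(n1, n2) / n
    }
    if (is.null(best) || ll_old > best$loglik) {
      best <- list(mu = mu, s2 = s2, w = w, loglik = ll_old)
    }
  }
  best
}

#' Signal-to-noise ratio of a raw trace with known spike positions
#'
#' Mean absolute spike-peak amplitude divided by a robust noise SD (median
#' absolute deviation of the spike-free trace divided by 0.6745). Samples
#' within `exclude_halfwidth` of a spike index are excluded from the noise
#' estimate. Noiseless traces are capped at `cap`.
#'
#' @param raw_trace Numeric sample vector.
#' @param spike_indices Integer sample positions of spike peaks.
#' @param exclude_halfwidth Samples excluded around each spike (default 30).
#' @param cap Upper bound returned for (near-)noiseless traces.
#' @return SNR (unitless), or `NA` when there are no spikes.
#' @export
estimate_snr <- function(raw_trace, spike_indices, exclude_halfwidth = 30L,
                         cap = 1e6) {
  if (!length(raw_trace)) stop_config("empty trace")
  if (!length(spike_indices)) return(NA_real_)
  spike_indices <- as.integer(spike_indices)
  if (any(spike_indices < 1L) || any(spike_indices > length(raw_trace))) {
    stop_config("spike indices outside the trace")
  }
  amp <- mean(abs(raw_trace[spike_indices]))
  excl <- unique(unlist(lapply(spike_indices, function(i) {
    max(1L, i - exclude_halfwidth):min(length(raw_trace), i + exclude_halfwidth)
  })))
  noise <- raw_trace[-excl]
  if (!length(noise)) return(cap)
  sigma <- median(abs(noise - median(noise))) / 0.6745
  if (sigma <= 0) return(cap)
  min(amp / sigma, cap)
}

#' Apply the study inclusion filters to spike segments
#'
#' Retains segments with duration >= `min_duration` s, SNR >= `min_snr`,
#' isolated single-unit activity, and an imaging-defined location inside the
#' STN or the SNr. Each excluded segment is tallied once under the first
#' failing rule, in that order (`short`, `snr`, `anatomy`); multi-unit
#' activity counts under `snr`, matching how such recordings are screened
#' together with low-SNR ones.
#'
#' @param segments List of `spike_segment` objects.
#' @param min_duration Minimum duration in seconds (default 3).
#' @param min_snr Minimum SNR (default 3).
#' @return List with `retained` (segments) and `excluded` (named integer tally).
#' @export
quality_filter <- function(segments, min_duration = 3, min_snr = 3) {
  tally <- c(short = 0L, snr = 0L, anatomy = 0L)
  keep <- logical(length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (s$duration < min_duration) {
      tally["short"] <- tally["short"] + 1L
    } else if ((!is.na(s$snr) && s$snr < min_snr) || !s$is_single_unit) {
      tally["snr"] <- tally["snr"] + 1L
    } else if (!s$structure_imaging %in% c("STN", "SNr")) {
      tally["anatomy"] <- tally["anatomy"] + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  list(retained = segments[keep], excluded = tally[tally > 0L])
}

#' Extract unit features from one segment
#'
#' Convenience wrapper computing firing rate, burst index (with degeneracy
#' flag), and robust CV for a segment; BI is `NA` (flagged) when the segment
#' has fewer than `min_isi` ISIs.
#'
#' @param segment A `spike_segment`.
#' @param seed Seed forwarded to [burst_index()].
#' @param ... Further arguments to [burst_index()].
#' @return A one-row data frame (`unit_features`): `segment_id`, `fr`, `bi`,
#'   `bi_degenerate`, `cv`, `n_spikes`, `n_isi`.
#' @export
unit_features <- function(segment, seed = 1L, ...) {
  isi <- interspike_intervals(segment)
  bi <- tryCatch(burst_index(isi, seed = seed, ...),
                 mertopo_insufficient_data = function(e) NA_real_)
  data.frame(
    segment_id = segment$segment_id,
    fr = firing_rate(isi),
    bi = as.numeric(bi),
    bi_degenerate = isTRUE(attr(bi, "degenerate")),
    cv = coefficient_of_variation(isi),
    n_spikes = length(segment$spike_times),
    n_isi = length(isi),
    stringsAsFactors = FALSE
  )
}

#' Read spike segments from a cohort directory
#'
#' Reads `segments.tsv` plus the per-segment sidecar spike-time files
#' (seconds, one per line) written by [write_cohort()].
#'
#' @param dir Cohort directory.
#' @return List of `spike_segment` objects.
#' @export
read_segments <- function(dir) {
  path <- file.path(dir, "segments.tsv")
  if (!file.exists(path)) stop_config(sprintf("missing %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    st <- scan(file.path(dir, "spikes", paste0(r$segment_id, ".txt")),
               what = numeric(), quiet = TRUE)
    spike_segment(r$segment_id, st, r$duration,
                  depth_to_target = r$depth_to_target, snr = r$snr,
                  is_single_unit = r$is_single_unit,
                  structure_imaging = r$structure_imaging,
                  structure_intraop = r$structure_intraop,
                  patient_id = r$patient_id, hemisphere = r$hemisphere,
                  trajectory_id = r$trajectory_id)
  })
}

#' Extract features for every retained segment of a cohort
#'
#' Applies [quality_filter()] then [unit_features()] per retained segment.
#'
#' @param segments List of `spike_segment` objects.
#' @param seed Base seed; each segment gets a derived seed.
#' @param filter Apply the quality filter first (default `TRUE`).
#' @return Data frame of unit features with segment metadata columns bound on,
#'   plus attribute `excluded` (the filter tally).
#' @export
extract_unit_features <- function(segments, seed = 1L, filter = TRUE) {
  excluded <- c()
  if (filter) {
    qf <- quality_filter(segments)
    segments <- qf$retained
    excluded <- qf$excluded
  }
  rows <- with_seed(seed, lapply(segments, function(s) {
    f <- tryCatch(unit_features(s, seed = child_seed()),
                  mertopo_insufficient_data = function(e) NULL)
    if (is.null(f)) return(NULL)  # segment too sparse to analyze
    f$depth_to_target <- s$depth_to_target
    f$structure_imaging <- s$structure_imaging
    f$trajectory_id <- s$trajectory_id
    f$patient_id <- s$patient_id
    f
  }))
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}
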