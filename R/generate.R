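# Synthetic cohort generator: seeded patients, hemispheres, Ben-Gun
# trajectories, bursty spike trains, depth-indexed RMS profiles, frontal EEG
# and final-electrode models, with the statistical structure of a
# dose-stratified STN-DBS surgical cohort.

#' Default per-condition / per-structure feature parameters
#'
#' Means and SDs of firing rate (Hz), burst index, and single-unit depth
#' (mm-to-target) per anesthesia condition, with the burst index split by
#' structure. The cell means are chosen so the condition and structure
#' marginals, weighted by typical cell sizes, recover the group summaries a
#' dose-stratified cohort of this kind exhibits; cell SDs keep the
#' condition-level coefficient of variation.
#'
#' @return Data frame keyed by `condition` (one row each for LA, GA_low,
#'   GA_high).
#' @export
default_feature_params <- function() {
  data.frame(
    condition   = c("LA", "GA_low", "GA_high"),
    fr_mean     = c(28.47, 21.07, 21.07),
    fr_sd       = c(14.00, 14.37, 14.37),
    bi_mean_stn = c(6.21, 13.19, 13.19),
    bi_sd_stn   = c(5.09, 10.49, 10.49),
    bi_mean_snr = c(2.00, 8.98, 8.98),
    bi_sd_snr   = c(1.64, 7.14, 7.14),
    depth_mean  = c(2.32, 2.39, -0.07),
    depth_sd    = c(3.01, 2.94, 2.38),
    stringsAsFactors = FALSE
  )
}

#' Cohort configuration
#'
#' All tunable parameters of the synthetic cohort generator. Defaults emulate
#' a 25-patient STN-DBS cohort (11 awake / 14 under propofol, doses
#' 1.0-7.5 mg/kg/h averaging 3.9 +/- 1.8) with about six microelectrode
#' trajectories per patient.
#'
#' @param n_patients Number of patients.
#' @param frac_la Fraction of patients operated under local anesthesia.
#' @param propofol_mean,propofol_sd GA propofol dose distribution (mg/kg/h),
#'   truncated to `propofol_range`; the location is adjusted so the truncated
#'   mean equals `propofol_mean`.
#' @param propofol_range Allowed dose range, within (0, 20].
#' @param dose_threshold Dose partition boundary (mg/kg/h, default 4;
#'   inclusive on the low side).
#' @param trajectories_per_hemisphere Ben-Gun trajectories per hemisphere
#'   (1-3 use the built-in central/posterolateral/anteromedial offsets).
#' @param target_jitter_sd Per-hemisphere SD (mm) of the planned-target
#'   placement relative to the atlas (anatomical variability + brain shift).
#' @param implantation_offset_sd SD (mm) of the intra-operative final-depth
#'   adjustment (clamped to +/- 2 mm; negative = implanted deeper).
#' @param feature_params Data frame as [default_feature_params()].
#' @param bi_distance_rho Named vector (`LA`, `GA`): within-condition Gaussian
#'   copula coefficient coupling each unit's burst-index quantile to its
#'   sweetspot distance. The STN/SNr composition gradient already induces a
#'   negative cohort-level correlation on its own; the defaults are
#'   calibrated so the *observed* Spearman correlation between burst index
#'   and sweetspot distance in a default cohort is about -0.28 under LA and
#'   -0.11 under GA.
#' @param sua_rate_base,sua_dose_decay Expected single units per trajectory:
#'   `base * exp(-decay * dose)` (dose 0 under LA).
#' @param frac_outside Fraction of units placed unconditionally over the
#'   recording range rather than inside the nuclei (emulating recordings
#'   whose anatomical location falls outside both STN and SNr).
#' @param duration_mean,duration_sd Segment duration distribution (s),
#'   truncated at 3.2 s for regular segments.
#' @param snr_mean,snr_sd Retained-segment SNR distribution (truncated at 3).
#' @param frac_short,frac_lowsnr,frac_multi Fractions of injected
#'   quality-filter failures (short, low-SNR, multi-unit).
#' @param isi_sigma Common log-space SD of the two ISI mixture components.
#' @param burst_weight Mixture weight of the intra-burst (short-ISI) component.
#' @param depth_range Recording depth range (mm-to-target) units may occupy.
#' @param sef95_intercept,sef95_slope,sef95_sd SEF95 (Hz) dose-response:
#'   `intercept + slope * dose + noise`, dose 0 under LA; clamped to
#'   `[3, 27]` Hz.
#' @param eeg Generate EEG records (default `TRUE`).
#' @param eeg_fs,eeg_channels,eeg_duration,eeg_rms EEG sampling rate (Hz),
#'   channel count, duration (s) and per-channel RMS amplitude (microvolts).
#' @param rms_step Depth step (mm) of the RMS profile grid (10 to -5 mm).
#' @param rms_plateau Multiplicative STN elevation of background RMS (LA).
#' @param rms_snr_elev Additive SNr elevation (fraction of baseline).
#' @param rms_noise_sd Log-space SD of the multiplicative RMS noise.
#' @param suppression_slope Per-(mg/kg/h) decline of the STN plateau factor
#'   above `dose_threshold` (factor 1 at or below the threshold).
#' @param site_duration_mean,site_duration_sd RMS site duration distribution
#'   (s), truncated at 8 s.
#' @param electrode_zdev Named list of `c(mean, sd)` z-deviations (mm) of the
#'   final-electrode center from the sweetspot per condition.
#' @param electrode_xy_sd Lateral SD (mm) of electrode-center placement.
#' @param contact_offsets Contact offsets (mm) along the lead relative to its
#'   center.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 25L, frac_la = 11 / 25,
                          propofol_mean = 3.9, propofol_sd = 1.8,
                          propofol_range = c(1.0, 7.5), dose_threshold = 4,
                          trajectories_per_hemisphere = 3L,
                          target_jitter_sd = 0.7,
                          implantation_offset_sd = 0.75,
                          feature_params = default_feature_params(),
                          bi_distance_rho = c(LA = -0.04, GA = 0.10),
                          sua_rate_base = 5.2, sua_dose_decay = 0.08,
                          frac_outside = 0.04,
                          duration_mean = 10, duration_sd = 4,
                          snr_mean = 8.01, snr_sd = 3.02,
                          frac_short = 0.045, frac_lowsnr = 0.05,
                          frac_multi = 0.025,
                          isi_sigma = 0.3, burst_weight = 0.5,
                          depth_range = c(-4.5, 9.5),
                          sef95_intercept = 23, sef95_slope = -2.0,
                          sef95_sd = 1.5,
                          eeg = TRUE, eeg_fs = 250, eeg_channels = 4L,
                          eeg_duration = 60, eeg_rms = 20,
                          rms_step = 0.5, rms_plateau = 2.2,
                          rms_snr_elev = 0.3, rms_noise_sd = 0.12,
                          suppression_slope = 0.12,
                          site_duration_mean = 15, site_duration_sd = 4,
                          electrode_zdev = list(LA = c(-0.39, 0.91),
                                                GA_high = c(-1.55, 0.93),
                                                GA_low = c(-0.16, 1.22)),
                          electrode_xy_sd = 0.8,
                          contact_offsets = c(-3, -1, 1, 3)) {
  cfg <- as.list(environment())
  if (n_patients < 1) stop_config("invalid config field 'n_patients'")
  if (frac_la < 0 || frac_la > 1) stop_config("invalid config field 'frac_la'")
  if (propofol_sd < 0) stop_config("invalid config field 'propofol_sd'")
  if (propofol_range[1] <= 0 || propofol_range[2] > 20 ||
      propofol_range[1] >= propofol_range[2]) {
    stop_config("invalid config field 'propofol_range' (must be within (0, 20])")
  }
  sds <- c(duration_sd, snr_sd, sef95_sd, target_jitter_sd,
           implantation_offset_sd, rms_noise_sd, site_duration_sd,
           feature_params$fr_sd, feature_params$bi_sd_stn,
           feature_params$bi_sd_snr, feature_params$depth_sd)
  if (any(sds < 0)) stop_config("invalid config field: all SDs must be >= 0")
  if (isi_sigma <= 0) stop_config("invalid config field 'isi_sigma'")
  if (burst_weight <= 0 || burst_weight >= 1) {
    stop_config("invalid config field 'burst_weight'")
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config: %d patients (%.0f%% LA), propofol %.1f +/- %.1f [%g, %g] mg/kg/h>\n",
              x$n_patients, 100 * x$frac_la, x$propofol_mean, x$propofol_sd,
              x$propofol_range[1], x$propofol_range[2]))
  invisible(x)
}

# STN-plateau suppression factor: 1 at or below the dose threshold, linear
# decline above it, floored.
dose_suppression <- function(dose, threshold = 4, slope = 0.12, floor = 0.2) {
  if (is.na(dose) || dose <= threshold) return(1)
  max(floor, 1 - slope * (dose - threshold))
}

#' Generate a bursty spike train as a two-regime renewal process
#'
#' Interspike intervals are drawn from a two-component lognormal mixture with
#' common log-space SD `sigma`: an intra-burst (short-ISI) component and an
#' inter-burst component whose geometric means are `target_bi` apart, with
#' the location solved so the overall mean ISI equals `1 / target_fr`.
#'
#' @param duration Train duration in seconds (>= 3).
#' @param target_fr Target firing rate, Hz (> 0).
#' @param target_bi Target burst index (>= 1); 1 gives a single-component
#'   renewal train.
#' @param seed RNG seed.
#' @param sigma Common component SD in natural-log space.
#' @param burst_weight Weight of the short-ISI component.
#' @return Sorted spike times (s) within `[0, duration]`.
#' @export
generate_spike_train <- function(duration, target_fr, target_bi, seed = 1L,
                                 sigma = 0.3, burst_weight = 0.5) {
  if (duration < 3) stop_config("'duration' must be >= 3 s")
  if (target_fr <= 0) stop_config("'target_fr' must be > 0")
  if (target_bi < 1) stop_config("'target_bi' must be >= 1")
  if (target_fr * duration < 10) {
    stop_generation("infeasible train: target_fr * duration < 10 expected spikes")
  }
  w <- burst_weight
  mu_s <- -log(target_fr) - sigma^2 / 2 - log(w + (1 - w) * target_bi)
  mu_l <- mu_s + log(target_bi)
  with_seed(seed, {
    n_draw <- ceiling(target_fr * duration * 1.6 + 50)
    comp <- runif(n_draw) < w
    isi <- numeric(n_draw)
    isi[comp] <- rlnorm(sum(comp), mu_s, sigma)
    isi[!comp] <- rlnorm(sum(!comp), mu_l, sigma)
    t <- cumsum(isi)
    t <- t[t <= duration]
    if (length(t) < 2L) stop_generation("degenerate train: fewer than 2 spikes")
    t
  })
}

#' Generate a depth-indexed RMS profile along a trajectory
#'
#' Baseline background RMS outside the nuclei, an elevated plateau inside the
#' STN scaled by a dose-dependent suppression factor (1 at or below the dose
#' threshold, declining above it), a milder SNr elevation, logistic border
#' blurring (the dorsal edge blurs further with dose), and multiplicative
#' lognormal noise. A random per-trajectory gain emulates uncalibrated
#' amplifier units, which the NRMS normalization removes.
#'
#' @param geometry A `trajectory_geometry`.
#' @param atlas An `atlas_geometry`.
#' @param propofol_dose Dose in mg/kg/h, or `NA` under local anesthesia.
#' @param seed RNG seed.
#' @param depths Depth grid, mm-to-target, dorsal to ventral.
#' @param dose_threshold,suppression_slope See [cohort_config()].
#' @param plateau,snr_elev,noise_sd Profile shape parameters.
#' @param site_duration_mean,site_duration_sd Site duration distribution (s).
#' @param trajectory_id Identifier for the resulting profile.
#' @return A `trajectory_profile` (un-normalized) with the imaging-defined
#'   STN borders filled in when the trajectory intersects the STN.
#' @export
generate_rms_profile <- function(geometry, atlas, propofol_dose = NA_real_,
                                 seed = 1L, depths = seq(10, -5, by = -0.5),
                                 dose_threshold = 4, suppression_slope = 0.12,
                                 plateau = 2.2, snr_elev = 0.3,
                                 noise_sd = 0.12,
                                 site_duration_mean = 15,
                                 site_duration_sd = 4,
                                 trajectory_id = "traj") {
  span_stn <- stn_span(geometry, atlas, "stn")
  span_snr <- stn_span(geometry, atlas, "snr")
  supp <- dose_suppression(propofol_dose, dose_threshold, suppression_slope)
  w_ventral <- 0.25
  w_dorsal <- 0.25 + if (is.na(propofol_dose)) 0 else
    0.25 * max(0, propofol_dose - dose_threshold)
  inside <- function(d, span, wd, wv) {
    if (is.null(span)) return(rep(0, length(d)))
    plogis((span[1] - d) / wd) * plogis((d - span[2]) / wv)
  }
  shape <- 1 + (plateau - 1) * supp * inside(depths, span_stn, w_dorsal, w_ventral) +
    snr_elev * inside(depths, span_snr, 0.25, 0.25)
  with_seed(seed, {
    gain <- runif(1, 5, 15)
    noise <- exp(rnorm(length(depths), 0, noise_sd))
    durations <- rtruncnorm(length(depths), site_duration_mean,
                            site_duration_sd, lo = 8)
    trajectory_profile(
      trajectory_id, depths, gain * shape * noise, durations,
      condition = if (is.na(propofol_dose)) "LA" else "GA",
      propofol_rate = propofol_dose,
      stn_entry = if (is.null(span_stn)) NA_real_ else span_stn[1],
      stn_exit = if (is.null(span_stn)) NA_real_ else span_stn[2])
  })
}

#' Generate a multichannel EEG record with a target SEF95
#'
#' Colored-noise channels whose band-limited spectrum follows an
#' exponential-decay profile `S(f) = exp(-f / tau)`, with the decay rate
#' solved numerically so the 95% spectral edge of the analysis band equals
#' `target_sef95`. Channels are independent and scaled to `rms_uv` microvolts
#' RMS.
#'
#' @param target_sef95 Target SEF95 in Hz; must lie strictly between the low
#'   band edge and the flat-spectrum limit `lo + 0.95 * (hi - lo)`.
#' @param duration Record duration in seconds (>= 30).
#' @param n_channels Number of channels (default 4).
#' @param fs Sampling rate, Hz (default 250).
#' @param seed RNG seed.
#' @param band Analysis band, Hz.
#' @param rms_uv Per-channel RMS amplitude in microvolts.
#' @return An `eeg_record`.
#' @export
generate_eeg <- function(target_sef95, duration = 60, n_channels = 4L,
                         fs = 250, seed = 1L, band = c(0.5, 30),
                         rms_uv = 20) {
  if (duration < 30) stop_config("'duration' must be >= 30 s")
  if (target_sef95 <= band[1] || target_sef95 >= fs / 2) {
    stop_config("target SEF95 must lie in (band_low, fs/2)")
  }
  lo <- band[1]; hi <- band[2]
  if (target_sef95 >= lo + 0.95 * (hi - lo)) {
    stop_generation("target SEF95 unreachable within the analysis band")
  }
  # (1 - exp(-(F-lo)/tau)) / (1 - exp(-(hi-lo)/tau)) = 0.95, solved for tau
  g <- function(log_tau) {
    tau <- exp(log_tau)
    (1 - exp(-(target_sef95 - lo) / tau)) / (1 - exp(-(hi - lo) / tau)) - 0.95
  }
  tau <- exp(uniroot(g, c(log(1e-3), log(1e5)))$root)
  n <- round(duration * fs)
  f_fold <- pmin((0:(n - 1)) * fs / n, fs - (0:(n - 1)) * fs / n)
  amp <- sqrt(exp(-f_fold / tau))
  amp[1] <- 0  # no DC
  ch <- with_seed(seed, {
    vapply(seq_len(n_channels), function(k) {
      white <- rnorm(n)
      x <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / n
      x * rms_uv / sqrt(mean(x^2))
    }, numeric(n))
  })
  eeg_record(ch, fs = fs)
}

#' Generate a full synthetic cohort
#'
#' Builds patients, hemispheres (propofol dose drawn per hemisphere under
#' GA), Ben-Gun trajectories with jittered targets, single-unit segments with
#' bursty spike trains (features drawn per condition and structure, burst
#' index coupled to sweetspot distance through a Gaussian copula),
#' depth-indexed RMS profiles, frontal EEG records with dose-dependent SEF95,
#' and final-electrode models. Deterministic for a fixed `(config, seed)`.
#'
#' @param config A `cohort_config`.
#' @param seed Integer seed.
#' @param atlas An `atlas_geometry`.
#' @return An object of class `mer_cohort`: data frames `patients`,
#'   `hemispheres`, `trajectories`, `segments`, `rms` (long), `electrodes`
#'   (long); named lists `spike_times` and `eeg`; plus `config`, `atlas`,
#'   `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            atlas = atlas_geometry()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, generate_cohort_impl(config, atlas, seed))
}

generate_cohort_impl <- function(cfg, atlas, seed) {
  ben_gun <- list(c(0, 0), c(1.41, -1.41), c(-1.41, 1.41))
  fp <- cfg$feature_params
  n_la <- round(cfg$n_patients * cfg$frac_la)

  patients <- data.frame(
    patient_id = sprintf("P%02d", seq_len(cfg$n_patients)),
    group = c(rep("LA", n_la), rep("GA", cfg$n_patients - n_la)),
    stringsAsFactors = FALSE)

  hemis <- list(); trajs <- list(); segs <- list(); rms_rows <- list()
  electrodes <- list(); spike_times <- list()
  geometries <- list()

  for (i in seq_len(cfg$n_patients)) {
    pid <- patients$patient_id[i]
    grp <- patients$group[i]
    for (side in c("left", "right")) {
      hid <- paste0(pid, "_", substr(side, 1, 1))
      dose <- if (grp == "LA") NA_real_ else
        rtruncnorm(1, cfg$propofol_mean, cfg$propofol_sd,
                   cfg$propofol_range[1], cfg$propofol_range[2],
                   match_mean = TRUE)
      cond <- if (grp == "LA") "LA" else
        if (dose > cfg$dose_threshold) "GA_high" else "GA_low"
      jit <- rnorm(3, 0, cfg$target_jitter_sd)
      hemis[[hid]] <- data.frame(
        hemisphere_id = hid, patient_id = pid, side = side,
        propofol_rate = dose, condition = cond, stringsAsFactors = FALSE)

      for (k in seq_len(cfg$trajectories_per_hemisphere)) {
        tid <- paste0(hid, "_t", k)
        off <- ben_gun[[(k - 1L) %% length(ben_gun) + 1L]]
        offim <- max(-2, min(2, rnorm(1, 0, cfg$implantation_offset_sd)))
        geom <- trajectory_geometry(
          target_point = c(jit[1] + off[1], jit[2] + off[2], jit[3]),
          direction = c(0, 0, -1), implantation_offset = offim)
        geometries[[tid]] <- geom
        span <- stn_span(geom, atlas, "stn")
        span_snr <- stn_span(geom, atlas, "snr")
        trajs[[tid]] <- data.frame(
          trajectory_id = tid, hemisphere_id = hid, patient_id = pid,
          condition = cond, propofol_rate = dose,
          target_x = geom$target_point[1], target_y = geom$target_point[2],
          target_z = geom$target_point[3],
          dir_x = 0, dir_y = 0, dir_z = -1,
          implantation_offset = offim,
          stn_entry = if (is.null(span)) NA_real_ else span[1],
          stn_exit = if (is.null(span)) NA_real_ else span[2],
          stringsAsFactors = FALSE)

        # RMS profile
        prof <- generate_rms_profile(
          geom, atlas, propofol_dose = dose, seed = child_seed(),
          depths = seq(10, -5, by = -cfg$rms_step),
          dose_threshold = cfg$dose_threshold,
          suppression_slope = cfg$suppression_slope,
          plateau = cfg$rms_plateau, snr_elev = cfg$rms_snr_elev,
          noise_sd = cfg$rms_noise_sd,
          site_duration_mean = cfg$site_duration_mean,
          site_duration_sd = cfg$site_duration_sd, trajectory_id = tid)
        rms_rows[[tid]] <- data.frame(
          trajectory_id = tid, depth = prof$depths, rms = prof$rms,
          duration = prof$durations, stringsAsFactors = FALSE)

        # Single units on this trajectory
        dose0 <- if (is.na(dose)) 0 else dose
        n_units <- rpois(1, cfg$sua_rate_base * exp(-cfg$sua_dose_decay * dose0))
        if (n_units > 0L) {
          p <- fp[fp$condition == cond, ]
          # Units live where cells are: depths are drawn conditional on the
          # trajectory's STN+SNr extent (the printed depth statistics
          # describe units retained inside the nuclei), with a small
          # unconditioned fraction landing outside both.
          hi <- if (!is.null(span)) span[1] else
            if (!is.null(span_snr)) span_snr[1] else cfg$depth_range[2]
          lo <- if (!is.null(span_snr)) span_snr[2] else
            if (!is.null(span)) span[2] else cfg$depth_range[1]
          lo <- max(lo, cfg$depth_range[1]); hi <- min(hi, cfg$depth_range[2])
          n_out <- rbinom(1, n_units, cfg$frac_outside)
          depth <- c(rtruncnorm(n_units - n_out, p$depth_mean, p$depth_sd,
                                lo, hi, match_mean = TRUE),
                     runif(n_out, cfg$depth_range[1], cfg$depth_range[2]))
          # cells sit on the recording line at the mechanical depth itself;
          # the implantation offset only matters for reconstruction
          xyz <- t(vapply(depth,
                          function(d) locate_mer_site(geom, d,
                                                      implantation_offset = 0),
                          numeric(3)))
          segs[[tid]] <- data.frame(
            segment_id = paste0(tid, "_u", seq_len(n_units)),
            trajectory_id = tid, hemisphere_id = hid, patient_id = pid,
            condition = cond, propofol_rate = dose,
            depth_to_target = depth,
            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
            stringsAsFactors = FALSE)
        }
      }

      # Final electrode (central trajectory line through this hemisphere)
      zd <- cfg$electrode_zdev[[cond]]
      center <- atlas$sweetspot + c(rnorm(2, 0, cfg$electrode_xy_sd),
                                    rnorm(1, zd[1], zd[2]))
      contacts <- t(vapply(cfg$contact_offsets,
                           function(o) center + c(0, 0, o), numeric(3)))
      electrodes[[hid]] <- data.frame(
        hemisphere_id = hid, patient_id = pid, condition = cond,
        propofol_rate = dose, contact = seq_along(cfg$contact_offsets),
        x = contacts[, 1], y = contacts[, 2], z = contacts[, 3],
        stringsAsFactors = FALSE)
    }
  }

  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL

  # Structure labels from the atlas geometry
  segments$structure_imaging <- vapply(seq_len(nrow(segments)), function(j) {
    classify_structure(c(segments$x[j], segments$y[j], segments$z[j]), atlas)
  }, character(1))
  flip <- runif(nrow(segments))
  segments$structure_intraop <- ifelse(
    flip < 0.07, c(STN = "SNr", SNr = "STN", other = "other")[segments$structure_imaging],
    ifelse(flip < 0.15, "unlabelled", segments$structure_imaging))

  # Sweetspot distances and copula-coupled burst-index targets
  segments$distance_to_sweetspot <- sqrt(
    (segments$x - atlas$sweetspot[1])^2 + (segments$y - atlas$sweetspot[2])^2 +
      (segments$z - atlas$sweetspot[3])^2)
  segments$target_fr <- NA_real_
  segments$target_bi <- NA_real_
  for (cond in unique(segments$condition)) {
    sel <- which(segments$condition == cond)
    p <- fp[fp$condition == cond, ]
    segments$target_fr[sel] <- rtruncnorm(length(sel), p$fr_mean, p$fr_sd,
                                          lo = 0.5, match_mean = TRUE)
    rho <- unname(cfg$bi_distance_rho[[if (cond == "LA") "LA" else "GA"]])
    z_dist <- qnorm(rank(segments$distance_to_sweetspot[sel],
                         ties.method = "random") / (length(sel) + 1))
    z_bi <- rho * z_dist + sqrt(1 - rho^2) * rnorm(length(sel))
    u <- pnorm(z_bi)
    is_snr <- segments$structure_imaging[sel] %in% c("SNr", "other")
    segments$target_bi[sel] <- ifelse(
      is_snr,
      qshiftlnorm(u, p$bi_mean_snr, p$bi_sd_snr),
      qshiftlnorm(u, p$bi_mean_stn, p$bi_sd_stn))
  }

  # Segment quality metadata + spike trains
  n_seg <- nrow(segments)
  segments$duration <- rtruncnorm(n_seg, cfg$duration_mean, cfg$duration_sd,
                                  lo = 3.2)
  segments$snr <- rtruncnorm(n_seg, cfg$snr_mean, cfg$snr_sd, lo = 3)
  segments$is_single_unit <- TRUE
  u <- runif(n_seg)
  short_ix <- u < cfg$frac_short
  low_ix <- !short_ix & u < cfg$frac_short + cfg$frac_lowsnr
  multi_ix <- !short_ix & !low_ix &
    u < cfg$frac_short + cfg$frac_lowsnr + cfg$frac_multi
  segments$duration[short_ix] <- runif(sum(short_ix), 1, 2.9)
  segments$snr[low_ix] <- runif(sum(low_ix), 1, 2.9)
  segments$is_single_unit[multi_ix] <- FALSE

  spike_times <- vector("list", n_seg)
  names(spike_times) <- segments$segment_id
  for (j in seq_len(n_seg)) {
    dur <- max(segments$duration[j], 3)
    # keep the train feasible: at least ~10 expected spikes per segment
    fr_used <- max(segments$target_fr[j], 10.5 / dur)
    spike_times[[j]] <- tryCatch(
      generate_spike_train(dur, fr_used,
                           max(segments$target_bi[j], 1), seed = child_seed(),
                           sigma = cfg$isi_sigma,
                           burst_weight = cfg$burst_weight),
      mertopo_generation_error = function(e) numeric(0))
    spike_times[[j]] <- spike_times[[j]][spike_times[[j]] <= segments$duration[j]]
  }

  hemispheres <- do.call(rbind, hemis); rownames(hemispheres) <- NULL
  trajectories <- do.call(rbind, trajs); rownames(trajectories) <- NULL

  # EEG per patient: SEF95 follows the (mean hemisphere) dose
  eeg <- list()
  patients$propofol_rate <- vapply(patients$patient_id, function(pid) {
    mean(hemispheres$propofol_rate[hemispheres$patient_id == pid])
  }, numeric(1))
  patients$sef95_target <- pmax(3, pmin(27,
    cfg$sef95_intercept +
      cfg$sef95_slope * ifelse(is.na(patients$propofol_rate), 0,
                               patients$propofol_rate) +
      rnorm(cfg$n_patients, 0, cfg$sef95_sd)))
  if (isTRUE(cfg$eeg)) {
    for (i in seq_len(cfg$n_patients)) {
      eeg[[patients$patient_id[i]]] <- generate_eeg(
        patients$sef95_target[i], duration = cfg$eeg_duration,
        n_channels = cfg$eeg_channels, fs = cfg$eeg_fs, seed = child_seed(),
        rms_uv = cfg$eeg_rms)
    }
  }

  structure(list(
    patients = patients, hemispheres = hemispheres,
    trajectories = trajectories, segments = segments,
    spike_times = spike_times,
    rms = do.call(rbind, c(rms_rows, list(make.row.names = FALSE))),
    electrodes = do.call(rbind, c(electrodes, list(make.row.names = FALSE))),
    eeg = eeg, geometries = geometries,
    config = cfg, atlas = atlas, seed = seed
  ), class = "mer_cohort")
}

#' @export
print.mer_cohort <- function(x, ...) {
  cat(sprintf(paste0("<mer_cohort: %d patients (%d LA / %d GA), %d trajectories, ",
                     "%d segments, seed %d>\n"),
              nrow(x$patients), sum(x$patients$group == "LA"),
              sum(x$patients$group == "GA"), nrow(x$trajectories),
              nrow(x$segments), x$seed))
  invisible(x)
}

#' Turn a cohort's segment table into spike_segment objects
#'
#' @param cohort An `mer_cohort`.
#' @return List of `spike_segment` objects.
#' @export
cohort_segments <- function(cohort) {
  s <- cohort$segments
  lapply(seq_len(nrow(s)), function(j) {
    spike_segment(s$segment_id[j], cohort$spike_times[[s$segment_id[j]]],
                  s$duration[j], depth_to_target = s$depth_to_target[j],
                  snr = s$snr[j], is_single_unit = s$is_single_unit[j],
                  structure_imaging = s$structure_imaging[j],
                  structure_intraop = s$structure_intraop[j],
                  patient_id = s$patient_id[j],
                  trajectory_id = s$trajectory_id[j])
  })
}

#' Build trajectory_profile objects from a cohort's RMS table
#'
#' @param cohort An `mer_cohort`.
#' @return Named list of `trajectory_profile` objects.
#' @export
cohort_profiles <- function(cohort) {
  tr <- cohort$trajectories
  out <- list()
  for (i in seq_len(nrow(tr))) {
    tid <- tr$trajectory_id[i]
    r <- cohort$rms[cohort$rms$trajectory_id == tid, ]
    out[[tid]] <- trajectory_profile(
      tid, r$depth, r$rms, r$duration,
      condition = if (tr$condition[i] == "LA") "LA" else "GA",
      propofol_rate = tr$propofol_rate[i],
      stn_entry = tr$stn_entry[i], stn_exit = tr$stn_exit[i])
  }
  out
}

#' Write a cohort as a directory of delimited-text tables
#'
#' `patients.tsv`, `hemispheres.tsv`, `trajectories.tsv`, `segments.tsv` (one
#' row per segment, spike times in `spikes/<segment_id>.txt` sidecars of
#' seconds, one per line), `rms.tsv`, `electrodes.tsv`, `eeg/<patient>.csv`
#' (header line `# fs=<Hz>`), and `manifest.json` with the config and seed.
#'
#' @param cohort An `mer_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$patients, "patients.tsv")
  wt(cohort$hemispheres, "hemispheres.tsv")
  wt(cohort$trajectories, "trajectories.tsv")
  wt(cohort$segments, "segments.tsv")
  wt(cohort$rms, "rms.tsv")
  wt(cohort$electrodes, "electrodes.tsv")
  dir.create(file.path(dir, "spikes"), showWarnings = FALSE)
  for (sid in names(cohort$spike_times)) {
    writeLines(format(cohort$spike_times[[sid]], digits = 10, trim = TRUE),
               file.path(dir, "spikes", paste0(sid, ".txt")))
  }
  if (length(cohort$eeg)) {
    dir.create(file.path(dir, "eeg"), showWarnings = FALSE)
    for (pid in names(cohort$eeg)) {
      rec <- cohort$eeg[[pid]]
      path <- file.path(dir, "eeg", paste0(pid, ".csv"))
      writeLines(sprintf("# fs=%g", rec$fs), path)
      suppressWarnings(utils::write.table(
        round(rec$channels, 4), path, sep = ",", quote = FALSE,
        row.names = FALSE, col.names = paste0("ch", seq_len(ncol(rec$channels))),
        append = TRUE))
    }
  }
  manifest <- list(seed = cohort$seed,
                   atlas = unclass(cohort$atlas),
                   config = cohort$config[!vapply(cohort$config, is.function,
                                                  logical(1))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
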