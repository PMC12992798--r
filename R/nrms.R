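# Normalized root-mean-square background-activity profiles along
# microelectrode trajectories, dose grouping, and common-grid resampling.

#' Root mean square of a sample vector
#'
#' @param samples Numeric vector (non-empty).
#' @return `sqrt(mean(samples^2))`.
#' @export
rms <- function(samples) {
  if (!length(samples)) stop_config("empty sample vector")
  sqrt(mean(samples^2))
}

#' Construct a trajectory background-activity profile
#'
#' Depth-indexed RMS values for one microelectrode pass, with the propofol
#' condition and (optionally) the imaging-defined STN entry/exit depths.
#' Depths are mm-to-target, listed dorsal to ventral (strictly decreasing).
#'
#' @param trajectory_id Identifier.
#' @param depths Strictly monotone (decreasing) depth vector, mm-to-target.
#' @param rms_values Non-negative RMS value per depth.
#' @param durations Recording duration (s) per depth.
#' @param condition `"LA"` or `"GA"` (dose-based grouping refines GA).
#' @param propofol_rate Propofol infusion rate in mg/kg/h, or `NA` for LA.
#' @param stn_entry,stn_exit Imaging-defined STN border depths (entry dorsal,
#'   so `stn_entry > stn_exit`), or `NA`.
#' @return An object of class `trajectory_profile`.
#' @export
trajectory_profile <- function(trajectory_id, depths, rms_values, durations,
                               condition = c("LA", "GA"),
                               propofol_rate = NA_real_,
                               stn_entry = NA_real_, stn_exit = NA_real_) {
  condition <- match.arg(condition)
  depths <- as.numeric(depths)
  if (length(depths) > 1L && !all(diff(depths) < 0)) {
    stop_config("depths must be strictly decreasing (dorsal to ventral)")
  }
  if (length(rms_values) != length(depths) || length(durations) != length(depths)) {
    stop_config("rms_values and durations must match depths in length")
  }
  if (any(rms_values < 0)) stop_config("rms values must be >= 0")
  if (!is.na(stn_entry) && !is.na(stn_exit) && stn_entry <= stn_exit) {
    stop_config("stn_entry must be dorsal of (greater than) stn_exit")
  }
  structure(list(
    trajectory_id = trajectory_id, depths = depths,
    rms = as.numeric(rms_values), durations = as.numeric(durations),
    nrms = NULL, condition = condition, propofol_rate = propofol_rate,
    stn_entry = stn_entry, stn_exit = stn_exit, aligned = FALSE
  ), class = "trajectory_profile")
}

#' @export
print.trajectory_profile <- function(x, ...) {
  cat(sprintf("<trajectory_profile %s: %d depths [%.1f, %.1f] mm, %s%s%s>\n",
              x$trajectory_id, length(x$depths),
              max(x$depths), min(x$depths), x$condition,
              if (!is.na(x$propofol_rate)) sprintf(" %.1f mg/kg/h", x$propofol_rate) else "",
              if (!is.null(x$nrms)) ", normalized" else ""))
  invisible(x)
}

#' Normalize a trajectory's RMS profile
#'
#' Scales the RMS values by the median of the first `n_ref` qualifying
#' recording sites, where a site qualifies when its duration is at least
#' `min_site_duration` seconds and sites are taken in dorsal-to-ventral
#' recording order. When fewer than `n_ref` sites qualify, at least `n_min`
#' are required; below that the trajectory is not normalizable.
#'
#' @param profile A `trajectory_profile`.
#' @param n_ref Number of reference sites (default 5).
#' @param n_min Minimum acceptable number of qualifying sites (default 3).
#' @param min_site_duration Minimum site duration in seconds (default 10).
#' @return The profile with `nrms` filled in.
#' @export
normalize_trajectory <- function(profile, n_ref = 5L, n_min = 3L,
                                 min_site_duration = 10) {
  qual <- which(profile$durations >= min_site_duration)
  if (length(qual) < n_min) {
    stop_insufficient(sprintf(
      "trajectory %s: only %d sites with duration >= %g s (need >= %d); not normalizable",
      profile$trajectory_id, length(qual), min_site_duration, n_min))
  }
  ref <- qual[seq_len(min(n_ref, length(qual)))]
  profile$nrms <- profile$rms / median(profile$rms[ref])
  profile
}

#' Partition trajectory profiles by anesthesia condition and propofol dose
#'
#' @param profiles List of `trajectory_profile` objects.
#' @param dose_threshold Dose boundary in mg/kg/h; doses strictly above it are
#'   `GA_high`, doses at or below it `GA_low` (the boundary is inclusive on
#'   the low side). Default 4.
#' @return Named list of profile lists: `LA`, `GA_high`, `GA_low`.
#' @export
group_by_dose <- function(profiles, dose_threshold = 4) {
  grp <- vapply(profiles, function(p) {
    if (p$condition == "LA") return("LA")
    if (is.na(p$propofol_rate)) {
      stop_config(sprintf("GA trajectory %s has no propofol dose", p$trajectory_id))
    }
    if (p$propofol_rate > dose_threshold) "GA_high" else "GA_low"
  }, character(1))
  list(LA = profiles[grp == "LA"],
       GA_high = profiles[grp == "GA_high"],
       GA_low = profiles[grp == "GA_low"])
}

#' Resample NRMS profiles onto a common depth grid
#'
#' Nearest-depth assignment within a half-grid-step tolerance; grid cells
#' with no recording within tolerance are missing (`NA`), not zero.
#'
#' @param profiles List of normalized `trajectory_profile` objects.
#' @param grid Common depth grid (mm-to-target, decreasing).
#' @param tol Matching tolerance in mm (default half the grid step).
#' @param value `"nrms"` (default) or `"rms"`.
#' @return Matrix (profiles x grid), with the grid as column names.
#' @export
resample_profiles <- function(profiles, grid = seq(8, -3, by = -0.5),
                              tol = NULL, value = c("nrms", "rms")) {
  value <- match.arg(value)
  if (is.null(tol)) tol <- abs(diff(grid[1:2])) / 2
  out <- matrix(NA_real_, nrow = length(profiles), ncol = length(grid),
                dimnames = list(NULL, format(grid)))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    v <- p[[value]]
    if (is.null(v)) stop_config("profile has no nrms; run normalize_trajectory first")
    for (j in seq_along(grid)) {
      d <- abs(p$depths - grid[j])
      k <- which.min(d)
      if (length(k) && d[k] <= tol) out[i, j] <- v[k]
    }
  }
  out
}
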