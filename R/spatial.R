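# Spatial mapping: ellipsoid atlas geometry, trajectory/line intersections,
# depth alignment, structure classification, and sweetspot distances.
#
# Coordinate convention: right-handed mm frame, z dorsal-positive.
# Depth-to-target d is positive dorsal of the planned target (the ventral STN
# border): position(d) = target_point - d * direction, where `direction` is
# the unit dorsal-to-ventral advance vector (so -direction points dorsally).

#' Ellipsoid atlas geometry for the STN, SNr and DBS sweetspot
#'
#' A parametric stand-in for an imaging-derived atlas: axis-aligned (or
#' rotated) ellipsoids for the subthalamic nucleus and substantia nigra pars
#' reticulata, plus a configurable sweetspot point in the dorsolateral STN.
#' Defaults place the STN so a vertical central trajectory traverses about
#' 4.5 mm of nucleus, exiting at the planned target (depth 0), with the SNr
#' ventral to it. The frame is synthetic; no anatomical accuracy is claimed.
#'
#' @param stn_center,stn_axes STN ellipsoid center (xyz, mm) and semi-axes.
#' @param snr_center,snr_axes SNr ellipsoid center and semi-axes.
#' @param sweetspot Sweetspot coordinates (xyz, mm).
#' @param stn_rotation,snr_rotation Optional 3x3 rotation matrices mapping
#'   world coordinates into each ellipsoid's principal frame.
#' @return An object of class `atlas_geometry`.
#' @export
atlas_geometry <- function(stn_center = c(0, 0, 2.4),
                           stn_axes = c(4.5, 3.5, 2.4),
                           snr_center = c(0, 0, -3),
                           snr_axes = c(4.5, 3.5, 3),
                           sweetspot = c(1.5, 0.8, 3.2),
                           stn_rotation = NULL, snr_rotation = NULL) {
  chk <- function(ax, nm) if (any(ax <= 0)) stop_config(sprintf("%s semi-axes must be > 0", nm))
  chk(stn_axes, "STN"); chk(snr_axes, "SNr")
  structure(list(
    stn = list(center = stn_center, axes = stn_axes, rotation = stn_rotation),
    snr = list(center = snr_center, axes = snr_axes, rotation = snr_rotation),
    sweetspot = sweetspot
  ), class = "atlas_geometry")
}

#' @export
print.atlas_geometry <- function(x, ...) {
  cat(sprintf("<atlas_geometry: STN c(%s) axes(%s); SNr c(%s) axes(%s); sweetspot (%s)>\n",
              paste(x$stn$center, collapse = ","), paste(x$stn$axes, collapse = ","),
              paste(x$snr$center, collapse = ","), paste(x$snr$axes, collapse = ","),
              paste(x$sweetspot, collapse = ",")))
  invisible(x)
}

#' Trajectory geometry for one microelectrode pass
#'
#' @param target_point Planned target (ventral STN border) at depth 0, xyz mm.
#' @param direction Unit advance vector, dorsal to ventral.
#' @param implantation_offset Intra-operative adjustment of the final
#'   implantation depth in mm; negative = implanted deeper than planned.
#' @return An object of class `trajectory_geometry`.
#' @export
trajectory_geometry <- function(target_point = c(0, 0, 0),
                                direction = c(0, 0, -1),
                                implantation_offset = 0) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) direction <- direction / nrm
  structure(list(target_point = as.numeric(target_point),
                 direction = as.numeric(direction),
                 implantation_offset = implantation_offset),
            class = "trajectory_geometry")
}

# World point -> normalized ellipsoid coordinates (unit ball frame).
ellipsoid_coords <- function(p, ell) {
  u <- p - ell$center
  if (!is.null(ell$rotation)) u <- as.numeric(ell$rotation %*% u)
  u / ell$axes
}

in_ellipsoid <- function(p, ell) sum(ellipsoid_coords(p, ell)^2) <= 1

#' Depth span of a trajectory through the STN ellipsoid
#'
#' Solves the line-ellipsoid intersection and returns the two crossing depths
#' as `c(entry, exit)` in mm-to-target, entry dorsal (larger). Tangent or
#' zero-length intersections count as no intersection.
#'
#' @param geometry A `trajectory_geometry`.
#' @param atlas An `atlas_geometry`.
#' @param nucleus `"stn"` (default) or `"snr"`.
#' @return `c(entry, exit)` or `NULL` when the trajectory misses the nucleus.
#' @export
stn_span <- function(geometry, atlas, nucleus = c("stn", "snr")) {
  nucleus <- match.arg(nucleus)
  ell <- atlas[[nucleus]]
  # position(d) = target - d * dir; in ellipsoid frame: a + d * b
  R <- ell$rotation
  tp <- geometry$target_point - ell$center
  dr <- -geometry$direction
  if (!is.null(R)) { tp <- as.numeric(R %*% tp); dr <- as.numeric(R %*% dr) }
  a <- tp / ell$axes
  b <- dr / ell$axes
  A <- sum(b^2); B <- 2 * sum(a * b); C <- sum(a^2) - 1
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(NULL)
  d1 <- (-B - sqrt(disc)) / (2 * A)
  d2 <- (-B + sqrt(disc)) / (2 * A)
  span <- c(entry = max(d1, d2), exit = min(d1, d2))
  if (span[1] - span[2] <= 1e-9) return(NULL)
  span
}

#' Align trajectory depths to a common STN-midpoint reference
#'
#' The reference midpoint is half the mean imaging-defined STN length across
#' trajectories (the exit anchored at depth 0); each trajectory is shifted by
#' the difference between the reference and its own STN midpoint. Spans and
#' all supplied depth vectors shift together.
#'
#' @param spans List of `c(entry, exit)` spans (all non-`NULL`).
#' @return List with `reference_midpoint`, `mean_length`, `shifts` (one per
#'   trajectory), and `spans` (shifted).
#' @export
align_depths <- function(spans) {
  if (!length(spans)) stop_insufficient("no trajectories with a valid STN span")
  if (any(vapply(spans, is.null, logical(1)))) {
    stop_config("all spans must be non-NULL; exclude trajectories first")
  }
  lens <- vapply(spans, function(s) s[1] - s[2], numeric(1))
  mids <- vapply(spans, function(s) (s[1] + s[2]) / 2, numeric(1))
  ref <- mean(lens) / 2
  shifts <- ref - mids
  shifted <- Map(function(s, sh) s + sh, spans, shifts)
  list(reference_midpoint = ref, mean_length = mean(lens),
       shifts = shifts, spans = shifted)
}

#' Apply depth-alignment shifts to trajectory profiles
#'
#' Computes spans (from supplied geometry or stored `stn_entry`/`stn_exit`),
#' aligns them with [align_depths()], and shifts each profile's depth grid and
#' borders accordingly.
#'
#' @param profiles List of `trajectory_profile` objects with `stn_entry` and
#'   `stn_exit` set.
#' @return List with `profiles` (shifted, `aligned = TRUE`) and `reference_midpoint`.
#' @export
align_profiles <- function(profiles) {
  spans <- lapply(profiles, function(p) {
    if (is.na(p$stn_entry) || is.na(p$stn_exit)) {
      stop_config(sprintf("trajectory %s has no STN span", p$trajectory_id))
    }
    c(p$stn_entry, p$stn_exit)
  })
  al <- align_depths(spans)
  for (i in seq_along(profiles)) {
    sh <- al$shifts[i]
    profiles[[i]]$depths <- profiles[[i]]$depths + sh
    profiles[[i]]$stn_entry <- profiles[[i]]$stn_entry + sh
    profiles[[i]]$stn_exit <- profiles[[i]]$stn_exit + sh
    profiles[[i]]$aligned <- TRUE
  }
  list(profiles = profiles, reference_midpoint = al$reference_midpoint,
       mean_length = al$mean_length, shifts = al$shifts)
}

#' Exclude trajectories without a usable STN traversal
#'
#' Drops trajectories with (a) no imaging-defined STN intersection or (b) an
#' STN entry-to-exit length shorter than `min_length` mm (a traversal of
#' exactly `min_length` is kept).
#'
#' @param spans List of spans (`c(entry, exit)` or `NULL`).
#' @param min_length Minimum STN chord length in mm (default 3).
#' @return List with `keep` (logical vector) and `excluded` (tally by reason:
#'   `no_stn`, `short_span`).
#' @export
exclude_trajectories <- function(spans, min_length = 3) {
  keep <- logical(length(spans))
  tally <- c(no_stn = 0L, short_span = 0L)
  for (i in seq_along(spans)) {
    s <- spans[[i]]
    if (is.null(s)) {
      tally["no_stn"] <- tally["no_stn"] + 1L
    } else if (s[1] - s[2] < min_length) {
      tally["short_span"] <- tally["short_span"] + 1L
    } else keep[i] <- TRUE
  }
  list(keep = keep, excluded = tally)
}

#' Classify a point against the atlas
#'
#' Inside-ellipsoid test; a point inside both nuclei is labelled `"STN"`
#' (STN precedence).
#'
#' @param xyz Point (xyz, mm).
#' @param atlas An `atlas_geometry`.
#' @return `"STN"`, `"SNr"` or `"other"`.
#' @export
classify_structure <- function(xyz, atlas) {
  if (in_ellipsoid(xyz, atlas$stn)) return("STN")
  if (in_ellipsoid(xyz, atlas$snr)) return("SNr")
  "other"
}

#' Locate an MER site along the final-electrode trajectory
#'
#' Projects a recording depth back along the trajectory, correcting for the
#' intra-operative implantation-depth adjustment: the recorded depth is taken
#' relative to the planned target, so the site sits at
#' `position(depth_to_target + implantation_offset)` on the final-electrode
#' line (offset negative = implanted deeper).
#'
#' @param geometry A `trajectory_geometry`.
#' @param depth_to_target Recorded depth (mm, positive dorsal).
#' @param implantation_offset Override of the geometry's offset.
#' @return xyz coordinates (mm).
#' @export
locate_mer_site <- function(geometry, depth_to_target,
                            implantation_offset = NULL) {
  off <- implantation_offset %||% geometry$implantation_offset
  d <- depth_to_target + off
  geometry$target_point - d * geometry$direction
}

#' Euclidean distance to the DBS sweetspot
#'
#' @param xyz Point (xyz, mm).
#' @param sweetspot Sweetspot coordinates (xyz, mm).
#' @return Distance in mm.
#' @export
sweetspot_distance <- function(xyz, sweetspot) {
  sqrt(sum((as.numeric(xyz) - as.numeric(sweetspot))^2))
}

#' Center of a final electrode and its deviation from the sweetspot
#'
#' The electrode center is the arithmetic mean of all contact positions; the
#' z-deviation is `center_z - sweetspot_z` (negative = implanted ventral of,
#' i.e. deeper than, the sweetspot).
#'
#' @param contacts Matrix of contact positions (contacts x 3) or a single xyz.
#' @param sweetspot Sweetspot coordinates.
#' @return List with `center`, `distance`, `z_deviation`.
#' @export
electrode_center <- function(contacts, sweetspot) {
  contacts <- matrix(as.numeric(contacts), ncol = 3)
  if (!nrow(contacts)) stop_config("need at least one contact")
  center <- colMeans(contacts)
  list(center = center,
       distance = sweetspot_distance(center, sweetspot),
       z_deviation = center[3] - sweetspot[3])
}

#' Normalized depth of the first single unit below the dorsal STN border
#'
#' Among single units with at least `min_neighbors` other units within
#' `window` mm along the trajectory (screening out sparse zona-incerta-like
#' activity), takes the most dorsal one and returns its distance from the STN
#' entry normalized by the STN traversal length:
#' `(entry - depth) / (entry - exit)`. Values below 0 (unit dorsal of entry)
#' or above 1 (unit ventral of exit) are returned unclipped, with attribute
#' `out_of_span = TRUE`.
#'
#' @param span STN span `c(entry, exit)` (mm-to-target).
#' @param sua_depths Depths of the trajectory's isolated single units.
#' @param window Proximity window in mm (default 2).
#' @param min_neighbors Minimum number of other units within the window
#'   (default 2).
#' @return Normalized fraction, or `NA` when no unit qualifies.
#' @export
first_sua_normalized_distance <- function(span, sua_depths, window = 2,
                                          min_neighbors = 2L) {
  if (is.null(span)) stop_config("trajectory has no STN span")
  if (!length(sua_depths)) return(NA_real_)
  qual <- vapply(seq_along(sua_depths), function(i) {
    sum(abs(sua_depths[-i] - sua_depths[i]) <= window) >= min_neighbors
  }, logical(1))
  if (!any(qual)) return(NA_real_)
  first <- max(sua_depths[qual])  # most dorsal qualifying unit
  frac <- (span[1] - first) / (span[1] - span[2])
  structure(frac, out_of_span = frac < 0 || frac > 1)
}
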