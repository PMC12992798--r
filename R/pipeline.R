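# End-to-end orchestration: generation -> feature extraction -> NRMS ->
# sedation -> spatial mapping -> group statistics -> report, plus
# directory-based stage functions mirroring the same flow over TSV tables.

#' Extract unit features for a cohort with segment metadata attached
#'
#' @param cohort An `mer_cohort`.
#' @param seed Base seed for the burst-index fits.
#' @return Data frame of unit features merged with condition, dose and
#'   sweetspot distance; attribute `excluded` carries the filter tally.
#' @keywords internal
pipeline_features <- function(cohort, seed = 1L) {
  feats <- extract_unit_features(cohort_segments(cohort), seed = seed)
  meta <- cohort$segments[, c("segment_id", "condition", "propofol_rate",
                              "distance_to_sweetspot", "x", "y", "z")]
  out <- merge(feats, meta, by = "segment_id", sort = FALSE)
  attr(out, "excluded") <- attr(feats, "excluded")
  out
}

#' NRMS stage: normalize, exclude, align and grid the cohort's profiles
#'
#' @param cohort An `mer_cohort`.
#' @param grid Common aligned depth grid.
#' @return List: `groups` (matrices per condition), `reference_midpoint`,
#'   `excluded` (trajectory tally), `n_not_normalizable`.
#' @keywords internal
pipeline_nrms <- function(cohort, grid = seq(8, -3, by = -0.5)) {
  profiles <- cohort_profiles(cohort)
  spans <- lapply(profiles, function(p) {
    if (is.na(p$stn_entry)) NULL else c(p$stn_entry, p$stn_exit)
  })
  excl <- exclude_trajectories(spans)
  profiles <- profiles[excl$keep]
  normed <- list(); n_bad <- 0L
  for (p in profiles) {
    np <- tryCatch(normalize_trajectory(p),
                   mertopo_insufficient_data = function(e) NULL)
    if (is.null(np)) n_bad <- n_bad + 1L else normed[[np$trajectory_id]] <- np
  }
  if (!length(normed)) stop_insufficient("no normalizable trajectories")
  al <- align_profiles(unname(normed))
  groups <- group_by_dose(al$profiles, cohort$config$dose_threshold)
  mats <- lapply(groups, function(g) {
    if (length(g)) resample_profiles(g, grid) else
      matrix(NA_real_, 0, length(grid))
  })
  list(groups = mats, profiles = al$profiles,
       reference_midpoint = al$reference_midpoint, grid = grid,
       excluded = excl$excluded, n_not_normalizable = n_bad)
}

#' Sedation stage: SEF95 per patient
#'
#' @param cohort An `mer_cohort`.
#' @return Data frame `patient_id`, `sef95`, `n_epochs_used`,
#'   `n_epochs_rejected`, `propofol_rate`, or `NULL` when the cohort has no
#'   EEG records.
#' @keywords internal
pipeline_sedation <- function(cohort) {
  if (!length(cohort$eeg)) return(NULL)
  rows <- lapply(names(cohort$eeg), function(pid) {
    si <- sedation_for_mer(cohort$eeg[[pid]])
    data.frame(patient_id = pid, sef95 = si$sef95,
               n_epochs_used = si$n_epochs_used,
               n_epochs_rejected = si$n_epochs_rejected,
               propofol_rate = cohort$patients$propofol_rate[
                 cohort$patients$patient_id == pid],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spatial stage: first-SUA border distances and electrode summaries
#'
#' @param cohort An `mer_cohort`.
#' @param features Feature table from [pipeline_features()].
#' @return List of data frames `first_sua` (per kept trajectory) and
#'   `electrodes` (per hemisphere center/distance/z-deviation).
#' @keywords internal
pipeline_spatial <- function(cohort, features) {
  tr <- cohort$trajectories
  first_rows <- list()
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$stn_entry[i]) || tr$stn_entry[i] - tr$stn_exit[i] < 3) next
    depths <- features$depth_to_target[features$trajectory_id == tr$trajectory_id[i]]
    frac <- first_sua_normalized_distance(c(tr$stn_entry[i], tr$stn_exit[i]),
                                          depths)
    first_rows[[tr$trajectory_id[i]]] <- data.frame(
      trajectory_id = tr$trajectory_id[i], patient_id = tr$patient_id[i],
      condition = tr$condition[i], first_sua_fraction = as.numeric(frac),
      stringsAsFactors = FALSE)
  }
  el <- cohort$electrodes
  el_rows <- lapply(split(el, el$hemisphere_id), function(e) {
    ec <- electrode_center(as.matrix(e[, c("x", "y", "z")]),
                           cohort$atlas$sweetspot)
    data.frame(hemisphere_id = e$hemisphere_id[1], condition = e$condition[1],
               center_x = ec$center[1], center_y = ec$center[2],
               center_z = ec$center[3], distance = ec$distance,
               z_deviation = ec$z_deviation, stringsAsFactors = FALSE)
  })
  list(first_sua = do.call(rbind, c(first_rows, list(make.row.names = FALSE))),
       electrodes = do.call(rbind, c(el_rows, list(make.row.names = FALSE))))
}

skip_block <- function(reason) list(skipped = reason)

# Every enabled analysis yields a result or an explicit skip reason; a block
# that cannot be computed (e.g. an empty dose stratum in a small cohort)
# must not abort the remaining analyses.
safe_block <- function(expr) {
  tryCatch(expr, mertopo_error = function(e) skip_block(conditionMessage(e)))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes generation, feature extraction, NRMS profiling, EEG sedation
#' indexing, spatial mapping and the group-statistics layer, returning an
#' analysis report whose blocks mirror the study's six result analyses:
#' `fig2b` (NRMS cluster tests), `fig2d` (single-unit depth ANOVA), `fig2e`
#' (MANOVA on coordinates), `fig3` (two-way feature ANOVAs), `fig4b`/`fig4c`
#' (SEF95 correlations), `fig5` (burst-index vs sweetspot distance), and
#' `fig6cd` (final-electrode placement ANOVAs).
#'
#' @param config A `cohort_config` (set `eeg = FALSE` to skip the EEG stage;
#'   the SEF95 blocks then carry a skip reason).
#' @param seed Integer seed controlling every random stage.
#' @param atlas An `atlas_geometry`.
#' @param n_perm Permutations for the NRMS cluster tests.
#' @param grid Aligned depth grid for the NRMS comparison.
#' @param out_dir Optional directory; when given, the report (JSON) and the
#'   stage tables (TSV) are written there.
#' @return An `analysis_report`: the blocks above plus `counts`, `nrms`
#'   summaries and `provenance`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         atlas = atlas_geometry(), n_perm = 2000L,
                         grid = seq(8, -3, by = -0.5), out_dir = NULL) {
  cohort <- generate_cohort(config, seed = seed, atlas = atlas)
  feats <- pipeline_features(cohort, seed = seed + 1L)
  nr <- pipeline_nrms(cohort, grid = grid)
  sed <- pipeline_sedation(cohort)
  sp <- pipeline_spatial(cohort, feats)
  blocks <- compute_stats_blocks(feats, nr, sed, sp, seed = seed + 2L,
                                 n_perm = n_perm)
  report <- structure(c(blocks, list(
    counts = list(
      n_patients = nrow(cohort$patients),
      n_trajectories = nrow(cohort$trajectories),
      n_segments = nrow(cohort$segments),
      n_units_retained = nrow(feats),
      excluded_segments = as.list(attr(feats, "excluded")),
      excluded_trajectories = as.list(nr$excluded),
      trajectories_not_normalizable = nr$n_not_normalizable),
    nrms = list(reference_midpoint = nr$reference_midpoint,
                group_sizes = vapply(nr$groups, nrow, integer(1))),
    provenance = list(seed = seed, package_version =
                        as.character(utils::packageVersion("mertopo")),
                      config_checksum = config_checksum(config))
  )), class = "analysis_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    utils::write.table(feats, file.path(out_dir, "unit_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Cheap deterministic checksum of a config (provenance only).
config_checksum <- function(config) {
  txt <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997L)) %% 1e9
}

compute_stats_blocks <- function(feats, nr, sed, sp, seed = 1L,
                                 n_perm = 2000L) {
  anesthesia <- ifelse(feats$condition == "LA", "LA", "GA")

  fig2b <- list(
    la_vs_ga_high = cluster_or_skip(nr$groups$LA, nr$groups$GA_high,
                                    nr$grid, n_perm, seed),
    la_vs_ga_low = cluster_or_skip(nr$groups$LA, nr$groups$GA_low,
                                   nr$grid, n_perm, seed + 1L))

  fig2d <- safe_block(list(
    anova = anova_oneway(feats$depth_to_target, feats$condition),
    group_means = tapply(feats$depth_to_target, feats$condition, mean),
    posthoc = posthoc_ttests(feats$depth_to_target, feats$condition, m = 3L)))

  fig2e <- safe_block(
    manova_groups(as.matrix(feats[, c("x", "y", "z")]), feats$condition))

  fig3 <- lapply(c(fr = "fr", bi = "bi", cv = "cv"), function(v) safe_block({
    ok <- !is.na(feats[[v]])  # short segments have no stable burst index
    res <- anova_twoway(feats[[v]][ok], feats$structure_imaging[ok],
                        anesthesia[ok])
    names(res) <- c("structure", "anesthesia", "interaction")
    res$group_means <- tapply(feats[[v]][ok],
                              list(feats$structure_imaging[ok], anesthesia[ok]),
                              mean)
    res
  }))

  if (is.null(sed)) {
    fig4b <- skip_block("no EEG records in cohort")
    fig4c <- skip_block("no EEG records in cohort")
  } else {
    sua <- merge(sp$first_sua, sed[, c("patient_id", "sef95")], by = "patient_id")
    sua <- sua[!is.na(sua$first_sua_fraction), ]
    fig4b <- if (nrow(sua) >= 4L) {
      safe_block(spearman_cor(sua$sef95, sua$first_sua_fraction,
                              n_comparisons = 4L))
    } else skip_block("fewer than 4 trajectories with a qualifying first unit")
    fu <- merge(feats, sed[, c("patient_id", "sef95")], by = "patient_id")
    fig4c <- lapply(c(fr = "fr", bi = "bi", cv = "cv"), function(v) safe_block({
      ok <- !is.na(fu[[v]])
      spearman_cor(fu$sef95[ok], fu[[v]][ok], n_comparisons = 4L)
    }))
  }

  fig5 <- lapply(c(LA = "LA", GA = "GA"), function(g) safe_block({
    sel <- anesthesia == g & !is.na(feats$bi)
    spearman_cor(feats$bi[sel], feats$distance_to_sweetspot[sel],
                 n_comparisons = 2L)
  }))

  fig6cd <- safe_block(list(
    distance = anova_oneway(sp$electrodes$distance, sp$electrodes$condition),
    z_deviation = anova_oneway(sp$electrodes$z_deviation,
                               sp$electrodes$condition),
    posthoc_z = posthoc_ttests(sp$electrodes$z_deviation,
                               sp$electrodes$condition, m = 3L),
    group_z = tapply(sp$electrodes$z_deviation, sp$electrodes$condition, mean)))

  list(fig2b = fig2b, fig2d = fig2d, fig2e = fig2e, fig3 = fig3,
       fig4b = fig4b, fig4c = fig4c, fig5 = fig5, fig6cd = fig6cd)
}

cluster_or_skip <- function(A, B, grid, n_perm, seed) {
  if (nrow(A) < 2L || nrow(B) < 2L) {
    return(skip_block("fewer than 2 trajectories in a group"))
  }
  cluster_permutation_test(A, B, grid, n_perm = n_perm, seed = seed)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  units retained: %d of %d segments\n",
              x$counts$n_units_retained, x$counts$n_segments))
  for (b in c("fig2b", "fig2d", "fig2e", "fig3", "fig4b", "fig4c",
              "fig5", "fig6cd")) {
    blk <- x[[b]]
    cat(sprintf("  %s: %s\n", b,
                if (!is.null(blk$skipped)) paste("skipped -", blk$skipped)
                else "computed"))
  }
  invisible(x)
}

# Strip heavy members for JSON serialization.
report_to_json <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "cluster_result")) {
      return(list(clusters = x$clusters, n_permutations = x$n_permutations,
                  alpha = x$alpha))
    }
    if (inherits(x, "test_summary")) return(unclass(x))
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  simplify(unclass(report))
}

# ---- Directory-based stages (subcommand semantics) -------------------------

stage_path <- function(dir, name) {
  p <- file.path(dir, name)
  if (!file.exists(p)) {
    stop_config(sprintf("missing upstream table %s; run the producing stage first", name))
  }
  p
}

#' Pipeline stage: simulate a cohort into a run directory
#'
#' @param dir Run directory.
#' @param config A `cohort_config`.
#' @param seed Integer seed.
#' @param atlas An `atlas_geometry`.
#' @return The cohort, invisibly.
#' @export
stage_simulate <- function(dir, config = cohort_config(), seed = 1L,
                           atlas = atlas_geometry()) {
  cohort <- generate_cohort(config, seed = seed, atlas = atlas)
  write_cohort(cohort, dir)
  invisible(cohort)
}

#' Pipeline stage: extract unit features from a run directory
#'
#' Reads `segments.tsv` (+ spike sidecars) and writes `unit_features.tsv`.
#'
#' @param dir Run directory.
#' @param seed Base seed for the burst-index fits.
#' @return The feature data frame, invisibly.
#' @export
stage_features <- function(dir, seed = 1L) {
  stage_path(dir, "segments.tsv")
  segs <- read_segments(dir)
  feats <- extract_unit_features(segs, seed = seed)
  utils::write.table(feats, file.path(dir, "unit_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(feats)
}

#' Pipeline stage: NRMS normalization and alignment over a run directory
#'
#' Reads `trajectories.tsv` and `rms.tsv`, writes `nrms.tsv` (long format
#' with aligned depths).
#'
#' @param dir Run directory.
#' @return The long NRMS data frame, invisibly.
#' @export
stage_nrms <- function(dir) {
  tr <- utils::read.delim(stage_path(dir, "trajectories.tsv"))
  rm <- utils::read.delim(stage_path(dir, "rms.tsv"))
  profiles <- list()
  for (i in seq_len(nrow(tr))) {
    r <- rm[rm$trajectory_id == tr$trajectory_id[i], ]
    profiles[[i]] <- trajectory_profile(
      tr$trajectory_id[i], r$depth, r$rms, r$duration,
      condition = if (tr$condition[i] == "LA") "LA" else "GA",
      propofol_rate = tr$propofol_rate[i],
      stn_entry = tr$stn_entry[i], stn_exit = tr$stn_exit[i])
  }
  spans <- lapply(profiles, function(p) {
    if (is.na(p$stn_entry)) NULL else c(p$stn_entry, p$stn_exit)
  })
  keep <- exclude_trajectories(spans)$keep
  normed <- Filter(Negate(is.null), lapply(profiles[keep], function(p) {
    tryCatch(normalize_trajectory(p), mertopo_insufficient_data = function(e) NULL)
  }))
  al <- align_profiles(normed)
  rows <- lapply(al$profiles, function(p) {
    data.frame(trajectory_id = p$trajectory_id, condition = p$condition,
               propofol_rate = p$propofol_rate, depth_aligned = p$depths,
               nrms = p$nrms, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(out, file.path(dir, "nrms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Pipeline stage: SEF95 sedation indices over a run directory
#'
#' Reads `eeg/<patient>.csv` and `patients.tsv`, writes `sedation.tsv`.
#'
#' @param dir Run directory.
#' @return The sedation data frame, invisibly.
#' @export
stage_sedation <- function(dir) {
  pats <- utils::read.delim(stage_path(dir, "patients.tsv"))
  eeg_dir <- file.path(dir, "eeg")
  if (!dir.exists(eeg_dir)) stop_config("missing upstream table eeg/; run simulate with eeg enabled")
  rows <- lapply(seq_len(nrow(pats)), function(i) {
    path <- file.path(eeg_dir, paste0(pats$patient_id[i], ".csv"))
    si <- sedation_for_mer(read_eeg(path))
    data.frame(patient_id = pats$patient_id[i], sef95 = si$sef95,
               n_epochs_used = si$n_epochs_used,
               n_epochs_rejected = si$n_epochs_rejected,
               propofol_rate = pats$propofol_rate[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(dir, "sedation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Pipeline stage: spatial mapping over a run directory
#'
#' Reads `segments.tsv`, `trajectories.tsv`, `electrodes.tsv` and the
#' manifest's atlas, writes `mer_sites.tsv` and `electrode_summary.tsv`.
#'
#' @param dir Run directory.
#' @return List of the two data frames, invisibly.
#' @export
stage_map <- function(dir) {
  segs <- utils::read.delim(stage_path(dir, "segments.tsv"))
  el <- utils::read.delim(stage_path(dir, "electrodes.tsv"))
  manifest <- jsonlite::read_json(stage_path(dir, "manifest.json"))
  sweetspot <- as.numeric(unlist(manifest$atlas$sweetspot))
  sites <- segs[, c("segment_id", "trajectory_id", "condition",
                    "depth_to_target", "x", "y", "z", "structure_imaging")]
  sites$distance_to_sweetspot <- sqrt((sites$x - sweetspot[1])^2 +
                                        (sites$y - sweetspot[2])^2 +
                                        (sites$z - sweetspot[3])^2)
  utils::write.table(sites, file.path(dir, "mer_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  el_rows <- lapply(split(el, el$hemisphere_id), function(e) {
    ec <- electrode_center(as.matrix(e[, c("x", "y", "z")]), sweetspot)
    data.frame(hemisphere_id = e$hemisphere_id[1], condition = e$condition[1],
               center_x = ec$center[1], center_y = ec$center[2],
               center_z = ec$center[3], distance = ec$distance,
               z_deviation = ec$z_deviation, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, c(el_rows, list(make.row.names = FALSE)))
  utils::write.table(summary, file.path(dir, "electrode_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(mer_sites = sites, electrode_summary = summary))
}

#' Pipeline stage: group statistics over a run directory
#'
#' Reads the upstream stage tables (`unit_features.tsv`, `mer_sites.tsv`,
#' `nrms.tsv`, `electrode_summary.tsv`, optionally `sedation.tsv`) and
#' writes `stats_report.json` and `clusters.tsv`.
#'
#' @param dir Run directory.
#' @param seed Seed for the permutation tests.
#' @param n_perm Number of permutations.
#' @param grid Aligned depth grid.
#' @return The stats block list, invisibly.
#' @export
stage_stats <- function(dir, seed = 1L, n_perm = 2000L,
                        grid = seq(8, -3, by = -0.5)) {
  feats <- utils::read.delim(stage_path(dir, "unit_features.tsv"))
  sites <- utils::read.delim(stage_path(dir, "mer_sites.tsv"))
  nrms <- utils::read.delim(stage_path(dir, "nrms.tsv"))
  eltab <- utils::read.delim(stage_path(dir, "electrode_summary.tsv"))
  sed <- if (file.exists(file.path(dir, "sedation.tsv"))) {
    utils::read.delim(file.path(dir, "sedation.tsv"))
  } else NULL
  tr <- utils::read.delim(stage_path(dir, "trajectories.tsv"))

  feats <- merge(feats, sites[, c("segment_id", "condition", "x", "y", "z",
                                  "distance_to_sweetspot")], by = "segment_id")
  dose_thr <- 4
  nrms$group <- ifelse(nrms$condition == "LA", "LA",
                       ifelse(nrms$propofol_rate > dose_thr, "GA_high", "GA_low"))
  to_mat <- function(sub) {
    ids <- unique(sub$trajectory_id)
    m <- matrix(NA_real_, length(ids), length(grid))
    for (i in seq_along(ids)) {
      s <- sub[sub$trajectory_id == ids[i], ]
      for (j in seq_along(grid)) {
        d <- abs(s$depth_aligned - grid[j])
        k <- which.min(d)
        if (length(k) && d[k] <= abs(grid[2] - grid[1]) / 2) m[i, j] <- s$nrms[k]
      }
    }
    m
  }
  nr <- list(groups = lapply(split(nrms, nrms$group), to_mat), grid = grid)
  for (g in c("LA", "GA_high", "GA_low")) {
    if (is.null(nr$groups[[g]])) nr$groups[[g]] <- matrix(NA_real_, 0, length(grid))
  }

  first_rows <- list()
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$stn_entry[i]) || tr$stn_entry[i] - tr$stn_exit[i] < 3) next
    depths <- feats$depth_to_target[feats$trajectory_id == tr$trajectory_id[i]]
    frac <- first_sua_normalized_distance(c(tr$stn_entry[i], tr$stn_exit[i]),
                                          depths)
    first_rows[[tr$trajectory_id[i]]] <- data.frame(
      trajectory_id = tr$trajectory_id[i], patient_id = tr$patient_id[i],
      condition = tr$condition[i], first_sua_fraction = as.numeric(frac),
      stringsAsFactors = FALSE)
  }
  sp <- list(first_sua = do.call(rbind, c(first_rows, list(make.row.names = FALSE))),
             electrodes = eltab)

  blocks <- compute_stats_blocks(feats, nr, sed, sp, seed = seed,
                                 n_perm = n_perm)
  jsonlite::write_json(report_to_json(blocks),
                       file.path(dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cl <- blocks$fig2b$la_vs_ga_high
  if (inherits(cl, "cluster_result") && nrow(cl$clusters)) {
    utils::write.table(cl$clusters, file.path(dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(data.frame(depth_start = numeric(0)),
                       file.path(dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(blocks)
}

#' Pipeline stage: assemble the final report for a run directory
#'
#' Combines `stats_report.json` with the stage tallies into `report.json`;
#' running it twice produces identical output.
#'
#' @param dir Run directory.
#' @return The report list, invisibly.
#' @export
stage_report <- function(dir) {
  stats <- jsonlite::read_json(stage_path(dir, "stats_report.json"))
  feats <- utils::read.delim(stage_path(dir, "unit_features.tsv"))
  segs <- utils::read.delim(stage_path(dir, "segments.tsv"))
  manifest <- jsonlite::read_json(stage_path(dir, "manifest.json"))
  report <- list(stats = stats,
                 counts = list(n_segments = nrow(segs),
                               n_units_retained = nrow(feats)),
                 provenance = list(seed = manifest$seed))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
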