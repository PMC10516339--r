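#' Extract parcel-mean timecourses from a 4D image and a label atlas
#'
#' For every labeled parcel, averages the timecourse over the voxels inside
#' the parcel whose series is not identically zero (mask-excluded voxels in
#' preprocessed BOLD are all-zero). A parcel with no eligible voxel yields an
#' all-`NA` column and is reported in the `dropped_regions` attribute rather
#' than raising an error, since atlas parcels can fall outside a subject's
#' field of view.
#'
#' @param bold 4D array or NIfTI image (x, y, z, time).
#' @param atlas 3D integer array or NIfTI image on the same grid; 0 is
#'   background, parcels are labeled `1..K`.
#' @param region_ids parcels to extract; defaults to every positive label in
#'   the atlas, ascending.
#' @return volumes x regions matrix with `region_ids` and `dropped_regions`
#'   attributes; columns named `r<id>`.
#' @export
extract_parcel_timecourses <- function(bold, atlas, region_ids = NULL) {
  bold <- unclass(as.array(bold))
  atlas <- unclass(as.array(atlas))
  db <- dim(bold)
  da <- dim(atlas)
  # NIfTI readers may drop or add trailing singleton dimensions
  if (length(da) == 4L && da[4] == 1L) da <- da[1:3]
  if (length(da) < 3L) da <- c(da, rep(1L, 3L - length(da)))
  dim(atlas) <- da
  if (length(db) != 4L)
    stop("bold must be 4D (x, y, z, time); got dim ",
         paste(db, collapse = "x"))
  if (length(da) != 3L || !all(db[1:3] == da))
    stop("bold grid ", paste(db[1:3], collapse = "x"),
         " does not match atlas grid ", paste(da, collapse = "x"))
  labels <- sort(unique(as.integer(atlas[atlas > 0])))
  if (length(labels) == 0L) stop("atlas contains no nonzero labels")
  if (is.null(region_ids)) region_ids <- labels
  region_ids <- as.integer(region_ids)

  nt <- db[4]
  nvox <- prod(db[1:3])
  dim(bold) <- c(nvox, nt)           # voxels x time
  lab_vec <- as.integer(atlas)

  out <- matrix(NA_real_, nt, length(region_ids))
  colnames(out) <- paste0("r", region_ids)
  dropped <- integer(0)
  for (j in seq_along(region_ids)) {
    vox <- which(lab_vec == region_ids[j])
    if (length(vox)) {
      sub <- bold[vox, , drop = FALSE]
      eligible <- rowSums(sub != 0) > 0L
      sub <- sub[eligible, , drop = FALSE]
    } else sub <- matrix(0, 0L, nt)
    if (nrow(sub) == 0L) {
      dropped <- c(dropped, region_ids[j])
    } else {
      out[, j] <- colMeans(sub)
    }
  }
  attr(out, "region_ids") <- region_ids
  attr(out, "dropped_regions") <- dropped
  out
}

#' Trim initial volumes, drop post-stimulus volumes, and concatenate runs
#'
#' Per run, keeps volumes `(trim, end_volume]` (so the first `trim` volumes
#' and everything after the stimulus ends are discarded) and stacks the
#' retained blocks in run order. The output row count is
#' `sum(end_volume - trim)` over retained runs.
#'
#' @param runs list of volumes x regions matrices (one per retained run), in
#'   run order.
#' @param trim initial volumes to discard per run (default 21).
#' @param end_volume last stimulus volume per run; scalar or one per run.
#'   Defaults to each run's full length.
#' @return single concatenated volumes x regions matrix.
#' @export
trim_and_concatenate <- function(runs, trim = 21L, end_volume = NULL) {
  if (!is.list(runs) || length(runs) == 0L)
    stop("runs must be a non-empty list of matrices (empty retained-run set?)")
  trim <- as.integer(trim)
  stopifnot(trim >= 0L)
  lens <- vapply(runs, nrow, integer(1))
  if (is.null(end_volume)) end_volume <- lens
  end_volume <- as.integer(rep_len(end_volume, length(runs)))
  if (any(end_volume > lens))
    stop("end_volume exceeds run length for run(s) ",
         paste(which(end_volume > lens), collapse = ", "))
  if (any(lens <= trim) || any(end_volume <= trim))
    stop("run(s) ", paste(which(lens <= trim | end_volume <= trim),
                          collapse = ", "),
         " are not longer than the trim of ", trim, " volumes")
  blocks <- lapply(seq_along(runs), function(r)
    runs[[r]][(trim + 1L):end_volume[r], , drop = FALSE])
  do.call(rbind, blocks)
}

#' Per-dyad region-wise and summary neural similarity
#'
#' Correlates each region's timecourse between the two partners
#' (volume-for-volume, after both have been trimmed and concatenated over
#' the same retained runs) and summarizes the resulting region profile as
#' the unweighted mean (whole-brain similarity) and a parcel-size-weighted
#' mean. Regions where either partner's series is constant have an undefined
#' correlation; they are set to `NA`, excluded from both means, and counted.
#'
#' @param a,b concatenated volumes x regions matrices for the two partners;
#'   identical row and column counts, same region ordering.
#' @param parcel_sizes optional voxel counts per region for the weighted
#'   mean; equal sizes reproduce the unweighted mean.
#' @param dyad_id optional identifier carried into the result.
#' @return object of class `similarity_profile`: list with `dyad_id`,
#'   `region_r` (named per-region correlations), `whole_brain`, `weighted`,
#'   `n_regions_used`, `n_regions_dropped`.
#' @export
pairwise_similarity <- function(a, b, parcel_sizes = NULL, dyad_id = NA_character_) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("row count mismatch: ", nrow(a), " vs ", nrow(b),
         " volumes; partners must be aligned on the same retained volumes")
  if (ncol(a) != ncol(b))
    stop("region count mismatch: ", ncol(a), " vs ", ncol(b))
  k <- ncol(a)
  if (is.null(parcel_sizes)) parcel_sizes <- rep(1, k)
  if (length(parcel_sizes) != k)
    stop("parcel_sizes must have one entry per region")

  ac <- scale(a, center = TRUE, scale = FALSE)
  bc <- scale(b, center = TRUE, scale = FALSE)
  sa <- sqrt(colSums(ac^2))
  sb <- sqrt(colSums(bc^2))
  region_r <- colSums(ac * bc) / (sa * sb)
  bad <- sa == 0 | sb == 0 | is.na(region_r)
  if (any(bad)) {
    region_r[bad] <- NA_real_
    warning(sum(bad), " region(s) with constant timecourse dropped from ",
            "similarity means")
  }
  names(region_r) <- colnames(a) %||% paste0("r", seq_len(k))
  ok <- !is.na(region_r)
  w <- parcel_sizes[ok]
  structure(list(dyad_id = dyad_id,
                 region_r = region_r,
                 whole_brain = mean(region_r[ok]),
                 weighted = sum(w * region_r[ok]) / sum(w),
                 n_regions_used = sum(ok),
                 n_regions_dropped = sum(!ok)),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("Dyad similarity profile", if (!is.na(x$dyad_id)) paste0("(", x$dyad_id, ")"),
      "\n  regions used:", x$n_regions_used,
      if (x$n_regions_dropped) paste0(" (", x$n_regions_dropped, " dropped)"),
      "\n  whole-brain similarity:", format(x$whole_brain, digits = 4),
      "\n  parcel-size-weighted:  ", format(x$weighted, digits = 4), "\n")
  invisible(x)
}

#' Motion similarity between partners
#'
#' Pearson correlation between the two partners' framewise-displacement
#' series over the same retained volumes used for the ISC computation; used
#' downstream as a nuisance covariate in every model containing neural
#' similarity.
#'
#' @param fd_a,fd_b numeric FD series of equal length.
#' @return correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   series is constant.
#' @export
fd_similarity <- function(fd_a, fd_b) {
  if (length(fd_a) != length(fd_b))
    stop("FD series length mismatch: ", length(fd_a), " vs ", length(fd_b))
  if (stats::sd(fd_a) == 0 || stats::sd(fd_b) == 0) {
    warning("constant FD series; motion similarity undefined")
    return(NA_real_)
  }
  stats::cor(fd_a, fd_b)
}

#' Apply run-exclusion rules to a dyad manifest
#'
#' Subjects with more than two flagged runs are excluded outright; subjects
#' with one or two flagged runs simply lose those runs from
#' `retained_runs`. `n_runs_used` and `minutes_used` (retained post-trim
#' stimulus volumes times TR) are recomputed.
#'
#' @param manifest data frame with `participant_id` and a `retained_runs`
#'   column of semicolon-separated run indices.
#' @param bad_runs named list: participant id -> integer vector of flagged
#'   runs (subjects absent from the list are untouched).
#' @param config a [simulation_config()] (or any list providing `n_runs`,
#'   `trim_volumes`, `video_end_volume`, `tr`) used to recompute minutes.
#' @param max_bad_runs exclusion threshold (default 2: more than two flagged
#'   runs excludes the subject).
#' @return updated manifest with `retained_runs`, `excluded`,
#'   `exclusion_reason`, `n_runs_used`, `minutes_used`.
#' @export
apply_run_exclusions <- function(manifest, bad_runs, config,
                                 max_bad_runs = 2L) {
  stopifnot(is.data.frame(manifest), "participant_id" %in% names(manifest))
  n_runs <- config$n_runs
  end_vol <- rep_len(config$video_end_volume, n_runs)
  run_minutes <- (end_vol - config$trim_volumes) * config$tr / 60
  if (!"excluded" %in% names(manifest)) manifest$excluded <- FALSE
  if (!"exclusion_reason" %in% names(manifest))
    manifest$exclusion_reason <- ""

  retained <- lapply(strsplit(manifest$retained_runs, ";", fixed = TRUE),
                     as.integer)
  for (i in seq_len(nrow(manifest))) {
    bad <- bad_runs[[manifest$participant_id[i]]]
    if (is.null(bad)) bad <- integer(0)
    bad <- as.integer(bad)
    if (length(bad) && (any(bad < 1L) || any(bad > n_runs)))
      stop("invalid run index for ", manifest$participant_id[i])
    if (length(bad) > max_bad_runs) {
      manifest$excluded[i] <- TRUE
      manifest$exclusion_reason[i] <-
        sprintf("bad data in %d of %d runs", length(bad), n_runs)
    }
    retained[[i]] <- setdiff(retained[[i]], bad)
  }
  manifest$retained_runs <- vapply(retained, paste, "", collapse = ";")
  manifest$n_runs_used <- lengths(retained)
  manifest$minutes_used <- vapply(retained, function(r)
    sum(run_minutes[r]), numeric(1))
  manifest
}

#' Compute similarity profiles for every non-excluded dyad of a dataset
#'
#' For each dyad, intersects the partners' retained runs, trims and
#' concatenates both partners over that intersection, and computes the
#' region-wise/summary ISC plus FD similarity. Confederate runs are assumed
#' complete unless listed in `confederate_bad_runs`.
#'
#' @param dataset a [simulate_dyad_dataset()] result with BOLD included (or
#'   any list with `config`, `manifest` and `bold` shaped the same way).
#' @param parcel_sizes optional per-region voxel counts.
#' @return list with `summary` (one row per dyad: whole_brain, weighted,
#'   fd_similarity, n_runs_used, minutes_used) and `regions` (dyads x
#'   regions matrix of region-wise correlations).
#' @export
dataset_similarity <- function(dataset, parcel_sizes = NULL) {
  cfg <- dataset$config
  man <- dataset$manifest
  keep <- !man$excluded
  end_vol <- rep_len(cfg$video_end_volume, cfg$n_runs)
  rows <- list(); regions <- list()
  for (i in which(keep)) {
    pid <- man$participant_id[i]
    runs <- as.integer(strsplit(man$retained_runs[i], ";", fixed = TRUE)[[1]])
    pair <- dataset$bold[[pid]]
    a <- trim_and_concatenate(pair$participant[runs], cfg$trim_volumes,
                              end_vol[runs])
    b <- trim_and_concatenate(pair$confederate[runs], cfg$trim_volumes,
                              end_vol[runs])
    prof <- pairwise_similarity(a, b, parcel_sizes, dyad_id = pid)
    fda <- trim_and_concatenate(lapply(pair$fd$participant[runs], as.matrix),
                                cfg$trim_volumes, end_vol[runs])
    fdb <- trim_and_concatenate(lapply(pair$fd$confederate[runs], as.matrix),
                                cfg$trim_volumes, end_vol[runs])
    rows[[pid]] <- data.frame(participant_id = pid,
                              whole_brain = prof$whole_brain,
                              weighted = prof$weighted,
                              fd_similarity = fd_similarity(fda[, 1], fdb[, 1]),
                              n_runs_used = length(runs),
                              minutes_used = man$minutes_used[i])
    regions[[pid]] <- prof$region_r
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       regions = do.call(rbind, regions))
}
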