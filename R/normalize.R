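#' Embryo volume from labeled frames
#'
#' The embryo volume at each frame is the labeled (non-exterior) voxel count
#' times the voxel volume; since the embryonic volume changes only slightly
#' through development, the median over frames is used as the embryo volume.
#'
#' @param frames list of [labeled_volume()] objects.
#' @return Median embryo volume in um^3.
#' @export
embryo_volume <- function(frames) {
  stopifnot(length(frames) >= 1)
  v <- vapply(frames, function(lv) {
    n <- sum(lv$labels > 0L)
    if (n == 0L) stop("frame contains no labeled voxels")
    n * voxel_volume(lv)
  }, 0)
  stats::median(v)
}

#' Linear size-normalization factor for one embryo
#'
#' Embryos are linearly scaled so their volume matches the cohort mean:
#' the linear factor is `(mean_volume / median_volume)^(1/3)`.
#'
#' @param median_volume the embryo's median volume (um^3).
#' @param cohort_mean_volume mean of the cohort's embryo volumes (um^3).
#' @param id optional embryo identifier.
#' @return An `embryo_scale` object with the linear `factor`.
#' @export
embryo_scale <- function(median_volume, cohort_mean_volume, id = NA) {
  stopifnot(median_volume > 0, cohort_mean_volume > 0)
  structure(list(id = id, median_volume = median_volume,
                 cohort_mean_volume = cohort_mean_volume,
                 factor = (cohort_mean_volume / median_volume)^(1 / 3)),
            class = "embryo_scale")
}

#' Scale feature tracks to the cohort mean embryo size
#'
#' Applies the linear factor by dimensional analysis: lengths (centroids)
#' scale by `f`, areas by `f^2`, volumes by `f^3`; sphericity is
#' dimensionless and untouched.  Exactly invertible by the reciprocal
#' factor.
#'
#' @param tracks a `feature_tracks` data frame.
#' @param scale an [embryo_scale()] (or a bare numeric linear factor).
#' @return The rescaled tracks.
#' @export
scale_features <- function(tracks, scale) {
  f <- if (inherits(scale, "embryo_scale")) scale$factor else as.numeric(scale)
  stopifnot(f > 0)
  tracks$volume <- tracks$volume * f^3
  tracks$surface_area <- tracks$surface_area * f^2
  for (col in c("cx", "cy", "cz"))
    if (col %in% names(tracks)) tracks[[col]] <- tracks[[col]] * f
  tracks
}

#' Normalize a cell's feature dynamics to a common temporal length
#'
#' Resamples each numeric feature of one cell's track to exactly `n_out`
#' points spanning the cell cycle, by natural cubic spline through the
#' original samples.  The output time axis is rescaled to `target_min`
#' minutes regardless of the true cycle length, removing developmental-rate
#' differences before cross-embryo comparison.
#'
#' @param track one cell's rows of a `feature_tracks` data frame (at least
#'   4 frames, as required for a cubic spline).
#' @param n_out number of output samples (default 50).
#' @param target_min nominal output cycle length in minutes (default 25).
#' @return A data frame with `n_out` rows: `cell`, `norm_time` (0 ..
#'   `target_min`), and each numeric feature resampled.
#' @export
normalize_time <- function(track, n_out = 50L, target_min = 25) {
  ord <- if ("time_min" %in% names(track)) track$time_min else track$norm_time
  track <- track[order(ord), , drop = FALSE]
  if (nrow(track) < 4)
    stop(sprintf("track too short for spline resampling (%d < 4 frames)%s",
                 nrow(track),
                 if (length(unique(track$cell)) == 1)
                   paste0(": cell ", track$cell[1]) else ""))
  if (length(unique(track$cell)) != 1)
    stop("normalize_time expects a single cell's track")
  x <- if ("time_min" %in% names(track)) track$time_min else track$norm_time
  xo <- seq(min(x), max(x), length.out = n_out)
  feats <- setdiff(names(track)[vapply(track, is.numeric, TRUE)],
                   c("frame", "time_min", "norm_time"))
  out <- data.frame(cell = track$cell[1],
                    norm_time = seq(0, target_min, length.out = n_out),
                    stringsAsFactors = FALSE)
  for (f in feats)
    out[[f]] <- stats::splinefun(x, track[[f]], method = "natural")(xo)
  out
}

#' Time-normalize all complete cells of an embryo
#'
#' Applies [normalize_time()] to every cell that completed its cycle within
#' the movie; cells with incomplete cycles or fewer than 4 frames are
#' excluded (and listed in the `skipped` attribute).
#'
#' @param tracks a `feature_tracks` data frame.
#' @param tree the embryo's [lineage_tree()].
#' @inheritParams normalize_time
#' @return Long data frame of normalized tracks (`cell`, `norm_time`,
#'   features), with attribute `skipped`.
#' @export
normalize_embryo_time <- function(tracks, tree, n_out = 50L, target_min = 25) {
  cells <- intersect(unique(tracks$cell), tree$name[tree$cycle_complete])
  skipped <- setdiff(unique(tracks$cell), cells)
  out <- list()
  for (cl in cells) {
    tr <- cell_track(tracks, cl)
    if (nrow(tr) < 4) { skipped <- c(skipped, cl); next }
    out[[cl]] <- normalize_time(tr, n_out = n_out, target_min = target_min)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
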