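#' Daughter-volume asymmetry of one division
#'
#' The division ratio is the larger over the smaller of the daughters'
#' median cell-cycle volumes.  The segmentation-uncertainty band `u` is
#' built from each daughter's one-voxel boundary layer: with `L` the median
#' layer volume (layer voxel count times voxel volume) and `V` the median
#' cell volume, `u = (L_A/V_A + L_B/V_B)/2` (`uncertainty = "mean"`, the
#' default) or the sum of the two fractions (`"sum"`).  The division is
#' deemed significantly asymmetric iff `ratio - 1 > u`, i.e. the volume
#' difference exceeds what a one-voxel boundary shift could produce.
#'
#' @param track_a,track_b the daughters' `feature_tracks` rows (from
#'   [extract_features()] with `layer = TRUE` if an uncertainty band is
#'   wanted).
#' @param voxel_volume voxel volume in um^3 (needed to convert layer voxel
#'   counts); `NULL` leaves the uncertainty `NA`.
#' @param uncertainty combine the two layer fractions by `"mean"` or
#'   `"sum"`.
#' @return One-row data frame: daughter names, median volumes, `ratio`
#'   (>= 1), `uncertainty`, `significant`.
#' @export
division_ratio <- function(track_a, track_b, voxel_volume = NULL,
                           uncertainty = c("mean", "sum")) {
  uncertainty <- match.arg(uncertainty)
  stopifnot(nrow(track_a) >= 1, nrow(track_b) >= 1)
  va <- stats::median(track_a$volume)
  vb <- stats::median(track_b$volume)
  if (va <= 0 || vb <= 0) stop("daughter median volume must be positive")
  ratio <- max(va, vb) / min(va, vb)
  u <- NA_real_
  if (!is.null(voxel_volume) &&
      all(c("layer_voxels") %in% names(track_a)) &&
      all(c("layer_voxels") %in% names(track_b)) &&
      !anyNA(track_a$layer_voxels) && !anyNA(track_b$layer_voxels)) {
    la <- stats::median(track_a$layer_voxels) * voxel_volume / va
    lb <- stats::median(track_b$layer_voxels) * voxel_volume / vb
    u <- if (uncertainty == "mean") (la + lb) / 2 else la + lb
  }
  data.frame(daughter_a = track_a$cell[1], daughter_b = track_b$cell[1],
             median_volume_a = va, median_volume_b = vb,
             ratio = ratio, uncertainty = u,
             significant = if (is.na(u)) NA else ratio - 1 > u,
             stringsAsFactors = FALSE)
}

#' Cohort table of division asymmetries
#'
#' Evaluates every division whose two daughters are measured in at least
#' `min_embryos` embryos: per-embryo ratios (larger/smaller of the median
#' cycle volumes), their cohort median and sd, the median uncertainty band,
#' and the significance call `median ratio - 1 > median uncertainty`.
#'
#' @param cohort an `embryo_cohort`; each embryo needs `features`
#'   (including `layer_voxels` for uncertainty bands), `tree` and `spec`.
#' @param min_embryos minimum embryos with both daughters measured.
#' @inheritParams division_ratio
#' @return Data frame: one row per division (`mother`, daughters, cohort
#'   `median_ratio`, `sd_ratio`, `median_uncertainty`, `significant`,
#'   `n_embryos`).
#' @export
cohort_asymmetry_table <- function(cohort, min_embryos = 3L,
                                   uncertainty = c("mean", "sum")) {
  uncertainty <- match.arg(uncertainty)
  rows <- list()
  for (emb in cohort) {
    tree <- emb$tree
    voxvol <- prod(emb$spec$spacing)
    mothers <- unique(tree$parent[!is.na(tree$parent)])
    for (m in mothers) {
      dts <- tree$name[!is.na(tree$parent) & tree$parent == m]
      if (length(dts) != 2) next
      ta <- cell_track(emb$features, dts[1])
      tb <- cell_track(emb$features, dts[2])
      if (nrow(ta) == 0 || nrow(tb) == 0) next
      dr <- division_ratio(ta, tb, voxel_volume = voxvol,
                           uncertainty = uncertainty)
      dr$mother <- m; dr$embryo <- emb$id
      rows[[length(rows) + 1L]] <- dr
    }
  }
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no divisions with measured daughters")
  out <- lapply(split(per, per$mother), function(g) {
    if (nrow(g) < min_embryos) return(NULL)
    mu <- stats::median(g$uncertainty)
    mr <- stats::median(g$ratio)
    data.frame(mother = g$mother[1],
               daughter_a = g$daughter_a[1], daughter_b = g$daughter_b[1],
               median_ratio = mr, sd_ratio = stats::sd(g$ratio),
               median_uncertainty = mu,
               significant = if (is.na(mu)) NA else mr - 1 > mu,
               n_embryos = nrow(g), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "per_embryo") <- per
  res
}
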