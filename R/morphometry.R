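#' Extract per-cell feature tracks from labeled volumes
#'
#' For every labeled cell and frame, measures volume (voxel count times
#' voxel volume), isosurface surface area, Wadell sphericity, and centroid.
#' Optionally records the one-voxel boundary-layer count used for
#' segmentation-uncertainty bands.  Every label in the images must map to a
#' cell name through the lineage tree's `label` column.
#'
#' @param frames list of [labeled_volume()] objects.
#' @param tree a [lineage_tree()] giving the label-to-name mapping.
#' @param layer also record `layer_voxels` per cell and frame.
#' @param surface measure surface areas (and hence sphericity); disabling
#'   this skips the isosurface meshing, which dominates the runtime, for
#'   volume-only analyses.
#' @return A `feature_tracks` data frame: one row per cell x frame with
#'   columns `cell`, `frame`, `time_min`, `volume`, `surface_area`,
#'   `sphericity`, `cx`, `cy`, `cz` (and `layer_voxels` if requested).
#' @export
extract_features <- function(frames, tree, layer = FALSE, surface = TRUE) {
  max_lab <- max(tree$label)
  rows <- lapply(frames, function(lv) {
    labs <- present_labels(lv)
    unknown <- setdiff(labs, tree$label)
    if (length(unknown))
      stop("unannotated labels with no lineage name: ",
           paste(unknown, collapse = ", "))
    d <- dim(lv$labels)
    st <- cpp_label_stats(as.vector(lv$labels), d[1], d[2], d[3],
                          lv$spacing, max_lab)
    lay <- if (layer)
      cpp_boundary_counts(as.vector(lv$labels), d[1], d[2], d[3], max_lab)
    vv <- voxel_volume(lv)
    out <- lapply(labs, function(lb) {
      vol <- st$count[lb] * vv
      area <- if (surface) cell_surface_area(lv, lb) else NA_real_
      data.frame(cell = tree$name[match(lb, tree$label)],
                 frame = lv$frame, time_min = lv$time_min,
                 volume = vol, surface_area = area,
                 sphericity = if (surface) sphericity(vol, area)
                 else NA_real_,
                 cx = st$cx[lb], cy = st$cy[lb], cz = st$cz[lb],
                 layer_voxels = if (layer) lay[lb] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (!layer) out$layer_voxels <- NULL
  out <- out[order(out$cell, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("feature_tracks", "data.frame")
  out
}

#' Extract cell-cell contact tracks from labeled volumes
#'
#' Two cells are in contact at a frame iff at least one face-adjacent
#' (6-connectivity) voxel pair carries their two labels; the contact area is
#' the summed physical area of those shared faces (faces normal to x
#' contribute `dy*dz`, etc.).  Diagonal adjacency does not count.
#'
#' @inheritParams extract_features
#' @return A `contact_tracks` data frame: one row per unordered cell pair x
#'   frame with columns `cell_a`, `cell_b` (alphabetical), `frame`,
#'   `time_min`, `area`.
#' @export
extract_contacts <- function(frames, tree) {
  rows <- lapply(frames, function(lv) {
    d <- dim(lv$labels)
    m <- cpp_contact_areas(as.vector(lv$labels), d[1], d[2], d[3], lv$spacing)
    if (nrow(m) == 0) return(NULL)
    a <- tree$name[match(m[, 1], tree$label)]
    b <- tree$name[match(m[, 2], tree$label)]
    if (anyNA(a) || anyNA(b))
      stop("contact involves a label with no lineage name")
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(cell_a = a, cell_b = b, frame = lv$frame,
               time_min = lv$time_min, area = m[, 3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_a = character(), cell_b = character(),
                      frame = integer(), time_min = numeric(),
                      area = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contact_tracks", "data.frame")
  out
}

#' Volume deviation between adjacent time points
#'
#' Mean over consecutive frame pairs of `|V(t+1) - V(t)| / mean(V(t),
#' V(t+1))`.  With a 30 s frame interval the true volume is nearly constant
#' between adjacent frames, so this deviation measures segmentation noise.
#'
#' @param volumes numeric vector of a cell's per-frame volumes (in frame
#'   order), or a `feature_tracks` data frame together with `cell`.
#' @param cell cell name when `volumes` is a feature-track table.
#' @return Mean relative deviation (unitless), or `NA` for tracks shorter
#'   than two frames.
#' @export
adjacent_frame_volume_deviation <- function(volumes, cell = NULL) {
  if (is.data.frame(volumes)) {
    stopifnot(!is.null(cell))
    v <- volumes$volume[volumes$cell == cell][order(volumes$frame[volumes$cell == cell])]
  } else v <- as.numeric(volumes)
  if (length(v) < 2) return(NA_real_)
  a <- v[-length(v)]; b <- v[-1]
  mean(abs(b - a) / ((a + b) / 2))
}

#' Per-cell track from a feature-track table
#' @param tracks a `feature_tracks` data frame; `cell` a cell name.
#' @return The cell's rows, frame-ordered.
#' @export
cell_track <- function(tracks, cell) {
  out <- tracks[tracks$cell == cell, , drop = FALSE]
  out[order(out$frame), , drop = FALSE]
}
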