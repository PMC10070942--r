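# File interfaces: tidy CSV for features/contacts/nuclei, JSON for
# lineages, multi-page TIFF for label stacks.

#' Write / read feature tracks as tidy CSV
#'
#' One row per cell x frame.
#' @param tracks a `feature_tracks` data frame.
#' @param path output file.
#' @export
write_features_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("feature_tracks", "data.frame")
  out
}

#' Write / read contact tracks as tidy CSV
#'
#' One row per unordered cell pair x frame.
#' @param contacts a `contact_tracks` data frame.
#' @param path output file.
#' @export
write_contacts_csv <- function(contacts, path) {
  utils::write.csv(as.data.frame(contacts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts_csv
#' @export
read_contacts_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("contact_tracks", "data.frame")
  out
}

#' Write / read a lineage tree as JSON
#'
#' @param tree a [lineage_tree()].
#' @param path output file.
#' @export
write_lineage_json <- function(tree, path) {
  payload <- list(frame_interval = attr(tree, "frame_interval"),
                  n_frames = attr(tree, "n_frames"),
                  cells = as.data.frame(tree))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_lineage_json
#' @export
read_lineage_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- payload$cells
  for (col in c("birth_frame", "division_frame", "anaphase_frame"))
    cells[[col]] <- as.integer(cells[[col]])
  lineage_tree(cells[c("name", "parent", "birth_frame", "division_frame",
                       "anaphase_frame")],
               payload$frame_interval, payload$n_frames)
}

#' Write / read nucleus sets as CSV
#'
#' Columns: `frame`, `x`, `y`, `z`, and `name` when annotated.
#' @param sets a [nucleus_set()] or list of them.
#' @param path output file.
#' @export
write_nuclei_csv <- function(sets, path) {
  if (inherits(sets, "nucleus_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    out <- data.frame(frame = s$frame, x = s$points[, 1],
                      y = s$points[, 2], z = s$points[, 3])
    out$name <- if (is.null(s$names)) NA_character_ else s$names
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuclei_csv
#' @export
read_nuclei_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$frame), function(g) {
    nucleus_set(as.matrix(g[, c("x", "y", "z")]),
                names = if (all(is.na(g$name))) NULL else g$name,
                frame = g$frame[1])
  })
}

#' Write / read a labeled volume as a multi-page 16-bit TIFF
#'
#' Pages are z-slices; labels are stored as 16-bit integers.  Voxel
#' spacing and frame metadata are not stored in the TIFF and must be
#' supplied when reading.
#'
#' @param vol a [labeled_volume()].
#' @param path output file.
#' @export
write_labels_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  d <- dim(vol$labels)
  pages <- lapply(seq_len(d[3]), function(k)
    t(vol$labels[, , k]) / 65535)   # tiff wants [row=y, col=x] in [0,1]
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @param spacing,frame,time_min metadata restored on read.
#' @export
read_labels_tiff <- function(path, spacing, frame = 0L, time_min = 0) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                           length(pages)))
  for (k in seq_along(pages))
    arr[, , k] <- as.integer(round(t(pages[[k]]) * 65535))
  labeled_volume(arr, spacing, frame = frame, time_min = time_min)
}
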