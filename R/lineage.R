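#' Lineage tree of named cells
#'
#' A data frame of cells with parent/daughter links and division timings.
#' Frames are 0-based movie indices.  `division_frame` is the first frame of
#' the daughters (cytokinesis complete); `anaphase_frame` is the nuclear
#' division (anaphase onset), earlier by the karyokinesis-cytokinesis lag.
#' The mother is present on frames `birth_frame .. division_frame - 1`.
#' `generation` counts divisions from the zygote (zygote = generation 0, so
#' AB and P1 are generation 1).
#'
#' @param cells data frame with columns `name`, `parent`, `birth_frame`,
#'   `division_frame`, `anaphase_frame` (the latter two `NA` for cells that
#'   do not divide within the movie).
#' @param frame_interval frame interval in seconds.
#' @param n_frames number of frames in the movie.
#' @return An object of classes `lineage_tree` and `data.frame`, with added
#'   columns `label` (stable integer id), `generation`, `lineage` (founder
#'   lineage) and `cycle_complete`.
#' @export
lineage_tree <- function(cells, frame_interval, n_frames) {
  need <- c("name", "parent", "birth_frame", "division_frame", "anaphase_frame")
  if (!all(need %in% names(cells)))
    stop("`cells` must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cells$name)) stop("cell names must be unique")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  cells$label <- seq_len(nrow(cells))
  cells$generation <- cell_generation(cells$name, cells$parent)
  cells$lineage <- founder_lineage(cells$name)
  cells$cycle_complete <- !is.na(cells$division_frame) &
    cells$division_frame <= n_frames
  structure(cells, class = c("lineage_tree", "data.frame"),
            frame_interval = as.numeric(frame_interval),
            n_frames = as.integer(n_frames))
}

#' Generation index (divisions from the zygote)
#'
#' @param names,parents character vectors describing the tree; parents `NA`
#'   or absent from `names` are treated as tree roots.
#' @return Integer generations; roots get the generation implied by their
#'   Sulston name (AB and P1 are generation 1).
#' @export
cell_generation <- function(names, parents) {
  root_gen <- function(nm) {
    # generation of a cell from its Sulston name alone
    if (nm %in% c("P0", "zygote")) return(0L)
    if (nm %in% c("AB", "P1")) return(1L)
    if (nm %in% c("EMS", "P2")) return(2L)
    if (nm %in% c("MS", "E", "C", "P3")) return(3L)
    if (nm %in% c("D", "P4")) return(4L)
    if (grepl("^AB", nm)) return(1L + nchar(sub("^AB", "", nm)))
    if (grepl("^MS", nm)) return(3L + nchar(sub("^MS", "", nm)))
    if (grepl("^E", nm)) return(3L + nchar(sub("^E", "", nm)))
    if (grepl("^C", nm)) return(3L + nchar(sub("^C", "", nm)))
    if (grepl("^D", nm)) return(4L + nchar(sub("^D", "", nm)))
    NA_integer_
  }
  gen <- rep(NA_integer_, length(names))
  idx <- stats::setNames(seq_along(names), names)
  depth <- function(i) {
    if (!is.na(gen[i])) return(gen[i])
    p <- parents[i]
    if (is.na(p) || is.na(idx[p])) root_gen(names[i]) else depth(idx[[p]]) + 1L
  }
  for (i in seq_along(names)) gen[i] <- depth(i)
  gen
}

#' Founder lineage from a Sulston cell name
#'
#' Maps names to the founder lineages of the invariant *C. elegans* lineage:
#' AB, MS, E, C, D and P (germline; includes P0-P4, Z2, Z3).  EMS, the
#' mother of MS and E, is reported as its own group `"EMS"`.
#'
#' @param names character vector of Sulston names.
#' @return Character vector of founder lineages (`NA` if unrecognized).
#' @export
founder_lineage <- function(names) {
  out <- rep(NA_character_, length(names))
  out[grepl("^AB", names)] <- "AB"
  out[grepl("^MS", names)] <- "MS"
  out[grepl("^E($|[ap])", names)] <- "E"
  out[grepl("^C($|[ap])", names)] <- "C"
  out[grepl("^D($|[ap])", names)] <- "D"
  out[names %in% c("P0", "P1", "P2", "P3", "P4", "Z2", "Z3")] <- "P"
  out[names == "EMS"] <- "EMS"
  out
}

#' Daughter names under Sulston nomenclature
#'
#' Anterior/posterior daughters of AB-lineage and most somatic cells append
#' `a`/`p`; the second AB division appends `l`/`r`; germline (P) and the
#' early founder divisions use their fixed historical names.
#'
#' @param mother mother cell name.
#' @return Character vector of the two daughter names.
#' @export
sulston_daughters <- function(mother) {
  fixed <- list(P0 = c("AB", "P1"), P1 = c("EMS", "P2"), EMS = c("MS", "E"),
                P2 = c("C", "P3"), P3 = c("D", "P4"), P4 = c("Z2", "Z3"))
  if (mother %in% names(fixed)) return(fixed[[mother]])
  if (mother %in% c("ABa", "ABp")) return(paste0(mother, c("l", "r")))
  paste0(mother, c("a", "p"))
}

tree_dt_min <- function(tree) attr(tree, "frame_interval") / 60

tree_cell <- function(tree, name) {
  i <- match(name, tree$name)
  if (is.na(i)) stop(sprintf("cell '%s' not in lineage tree", name))
  tree[i, , drop = FALSE]
}

#' Last frame of a cell's existence
#' @param tree a [lineage_tree()]; `name` a cell name.
#' @return 0-based index of the cell's last frame in the movie.
#' @export
cell_last_frame <- function(tree, name) {
  row <- tree_cell(tree, name)
  n <- attr(tree, "n_frames")
  if (is.na(row$division_frame)) n - 1L else min(row$division_frame - 1L, n - 1L)
}
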