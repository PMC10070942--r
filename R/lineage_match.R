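#' Nucleus point cloud at one time point
#'
#' @param points numeric matrix (n x 3) of nucleus centroids in um.
#' @param names optional cell names aligned to the rows (must be unique).
#' @param frame 0-based frame index.
#' @return A `nucleus_set` object.
#' @export
nucleus_set <- function(points, names = NULL, frame = 0L) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  if (!is.null(names)) {
    stopifnot(length(names) == nrow(points))
    if (anyDuplicated(names)) stop("nucleus names must be unique")
  }
  structure(list(points = unname(points), names = names,
                 frame = as.integer(frame)),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei, frame %d%s\n", nrow(x$points),
              x$frame, if (is.null(x$names)) "" else ", named"))
  invisible(x)
}

#' Align a nucleus cloud to its principal axes
#'
#' Centers the cloud and rotates it into its PCA coordinate system (axes
#' ordered by decreasing variance).  Axis signs are fixed deterministically
#' by making the largest-magnitude loading of each principal axis positive,
#' so two rigidly rotated copies of a cloud land on identical coordinates
#' up to residual axis-sign ambiguity.
#'
#' @param set a [nucleus_set()].
#' @return The set in PC coordinates (attribute `rotation` holds the
#'   applied loadings matrix).
#' @export
pca_align <- function(set) {
  p <- set$points
  if (nrow(p) < 3) stop("degenerate geometry: need at least 3 nuclei for PCA")
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-9 * pc$sdev[1])
    stop("degenerate geometry: nucleus cloud is (nearly) collinear")
  rot <- pc$rotation
  for (j in 1:3) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]   # keep the frame right-handed
  out <- sweep(p, 2, pc$center) %*% rot
  res <- nucleus_set(out, names = set$names, frame = set$frame)
  attr(res, "rotation") <- rot
  res
}

#' Candidate rotations for annotation search
#'
#' A full sweep around the first principal axis in 2-degree steps, crossed
#' with small swings about the second and third axes.
#'
#' @param swing_deg maximum swing about PC2/PC3 in degrees (default 4).
#' @param swing_step swing increment in degrees (default 2; must be > 0).
#' @param pc1_step step for the PC1 sweep in degrees (default 2).
#' @return List of 3x3 rotation matrices; the identity is always included.
#' @export
candidate_transforms <- function(swing_deg = 4, swing_step = 2,
                                 pc1_step = 2) {
  stopifnot(swing_step > 0, pc1_step > 0)
  a1 <- seq(0, 360 - pc1_step, by = pc1_step)
  sw <- if (swing_deg > 0) seq(-swing_deg, swing_deg, by = swing_step) else 0
  out <- vector("list", length(a1) * length(sw) * length(sw))
  i <- 0L
  for (t1 in a1) for (t2 in sw) for (t3 in sw) {
    i <- i + 1L
    out[[i]] <- rotation_matrix(t1, t2, t3)
  }
  out
}

#' Per-axis scaling of a target cloud to a reference
#'
#' Both clouds must be in their PC frames; each target axis is multiplied
#' by `sd_ref / sd_target` so the positional variance matches the
#' reference on every axis.
#'
#' @param target,reference [nucleus_set()] objects in PC coordinates.
#' @return The scaled target; attribute `scales` holds the three factors.
#' @export
scale_to_reference <- function(target, reference) {
  st <- apply(target$points, 2, stats::sd)
  sr <- apply(reference$points, 2, stats::sd)
  if (any(st < 1e-12))
    stop("degenerate geometry: zero variance along a target axis")
  f <- sr / st
  out <- nucleus_set(sweep(target$points, 2, f, "*"),
                     names = target$names, frame = target$frame)
  attr(out, "scales") <- f
  out
}

euclidean_cost <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Minimum-cost bijection between two nucleus clouds
#'
#' Finds the one-to-one assignment of target to reference nuclei that
#' minimizes the summed Euclidean distances (the Hungarian method, via
#' `clue::solve_LSAP`).
#'
#' @param target,reference [nucleus_set()] objects with equal point counts.
#' @return A `match_result`: `assignment` (reference index per target
#'   point) and `cost` (um).
#' @export
match_hungarian <- function(target, reference) {
  if (nrow(target$points) != nrow(reference$points))
    stop(sprintf("size mismatch: %d target vs %d reference nuclei",
                 nrow(target$points), nrow(reference$points)))
  D <- euclidean_cost(target$points, reference$points)
  asg <- as.integer(clue::solve_LSAP(D))
  structure(list(assignment = asg,
                 cost = sum(D[cbind(seq_along(asg), asg)])),
            class = "match_result")
}

# right-handed axis-sign combinations tried on top of each rotation
.sign_combos <- list(diag(c(1, 1, 1)), diag(c(1, -1, -1)),
                     diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))

#' Annotate a nucleus cloud against annotated references
#'
#' PCA-aligns target and references, sweeps the candidate rotations (and
#' the four right-handed axis-sign combinations) about the target's
#' principal axes, scales per axis to each size-matched reference, and
#' scores each configuration by minimum-cost matching.  Names are copied
#' from the globally cheapest (reference x transform) combination.  Ties
#' resolve to the first combination encountered in the deterministic
#' iteration order (references, then sign combinations, then PC1/PC2/PC3
#' angles).
#'
#' @param target a [nucleus_set()] (unnamed).
#' @param references list of named [nucleus_set()] objects.
#' @inheritParams candidate_transforms
#' @return List: `set` (the target with names filled in), `cost`,
#'   `reference` (index of the winning reference), `assignment`.
#' @export
annotate_nuclei <- function(target, references, swing_deg = 4,
                            swing_step = 2, pc1_step = 2) {
  if (inherits(references, "nucleus_set")) references <- list(references)
  n <- nrow(target$points)
  usable <- which(vapply(references, function(r) nrow(r$points) == n, TRUE))
  if (length(usable) == 0)
    stop("no reference with a matching nucleus count")
  tp <- pca_align(target)
  transforms <- candidate_transforms(swing_deg, swing_step, pc1_step)
  best <- list(cost = Inf)
  for (ri in usable) {
    rp <- pca_align(references[[ri]])
    if (is.null(rp$names)) stop("references must be named")
    sr <- apply(rp$points, 2, stats::sd)
    st <- apply(tp$points, 2, stats::sd)
    if (any(st < 1e-12)) stop("degenerate geometry: flat target cloud")
    for (S in .sign_combos) {
      base <- tp$points %*% S
      for (R in transforms) {
        q <- base %*% t(R)
        q <- sweep(q, 2, sr / apply(q, 2, stats::sd), "*")
        D <- euclidean_cost(q, rp$points)
        asg <- as.integer(clue::solve_LSAP(D))
        cost <- sum(D[cbind(seq_len(n), asg)])
        if (cost < best$cost - 1e-12)
          best <- list(cost = cost, reference = ri, assignment = asg)
      }
    }
  }
  named <- nucleus_set(target$points,
                       names = references[[best$reference]]$names[best$assignment],
                       frame = target$frame)
  list(set = named, cost = best$cost, reference = best$reference,
       assignment = best$assignment)
}

#' Frame-to-frame tracking links from named nucleus sets
#'
#' Builds the tracking structure consumed by [trace_back()] from a series
#' of ground-truth-named nucleus sets: each nucleus links to its own
#' position in the next frame, or to its two daughters across a division.
#'
#' @param tree a [lineage_tree()].
#' @param sets list of named [nucleus_set()] objects in frame order.
#' @return List, one element per frame, each with `set` and `succ` (the
#'   successor row indices in the next frame; the names on `set` are the
#'   hidden ground truth and may be stripped before annotation).
#' @export
tracking_from_tree <- function(tree, sets) {
  T_ <- length(sets)
  out <- vector("list", T_)
  for (t in seq_len(T_)) {
    s <- sets[[t]]
    if (is.null(s$names)) stop("tracking requires named nucleus sets")
    succ <- NULL
    if (t < T_) {
      nxt <- sets[[t + 1]]$names
      succ <- lapply(s$names, function(nm) {
        j <- match(nm, nxt)
        if (!is.na(j)) return(j)
        dts <- tree$name[!is.na(tree$parent) & tree$parent == nm]
        j <- match(dts, nxt)
        if (length(j) != 2 || anyNA(j))
          stop(sprintf("tracking link broken for %s at frame %d", nm, t))
        j
      })
    }
    out[[t]] <- list(set = s, succ = succ)
  }
  out
}

#' Backward lineage tracing of nucleus annotations
#'
#' Propagates the final-frame annotation backward through frame-to-frame
#' tracking links: a nucleus with one successor keeps its name; a nucleus
#' whose two successors are named as sister cells takes their mother's
#' name.  If the propagated names ever contradict the lineage tree (the
#' two successors are not sisters, or names collide), the final-frame
#' annotation is deemed wrong and the procedure restarts with the previous
#' frame as the annotation target, repeating until tracing succeeds.
#'
#' @param tracked list, one element per frame, each with `set` (a
#'   [nucleus_set()]) and `succ` (list of integer successor row indices in
#'   the next frame; absent/NULL for the last frame).
#' @param tree the [lineage_tree()] consulted for sister relations.
#' @param annotate_frame function(frame_index) returning the character
#'   names for that frame's nuclei (e.g. a closure around
#'   [annotate_nuclei()] with frame-matched references).
#' @return List: `names` (per-frame character vectors up to the frame
#'   finally annotated), `restarts`, `final_frame`.
#' @export
trace_back <- function(tracked, tree, annotate_frame) {
  T_ <- length(tracked)
  parent_of <- stats::setNames(tree$parent, tree$name)
  for (f_final in T_:1) {
    nm_final <- annotate_frame(f_final)
    names_list <- vector("list", f_final)
    names_list[[f_final]] <- nm_final
    ok <- !anyDuplicated(nm_final)
    if (ok && f_final > 1) {
      for (t in (f_final - 1):1) {
        nxt <- names_list[[t + 1]]
        succ <- tracked[[t]]$succ
        nm <- character(nrow(tracked[[t]]$set$points))
        for (i in seq_along(nm)) {
          s <- succ[[i]]
          if (length(s) == 1) nm[i] <- nxt[s]
          else if (length(s) == 2) {
            p <- unique(parent_of[nxt[s]])
            if (length(p) != 1 || is.na(p)) { ok <- FALSE; break }
            nm[i] <- p
          } else { ok <- FALSE; break }
        }
        if (!ok || anyDuplicated(nm)) { ok <- FALSE; break }
        names_list[[t]] <- nm
      }
    }
    if (ok)
      return(list(names = names_list, restarts = T_ - f_final,
                  final_frame = f_final))
  }
  stop("annotation failed: no candidate final frame yields a consistent trace")
}
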