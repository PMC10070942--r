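#' Register feature dynamics at the end of metaphase
#'
#' Aligns one cell type's per-embryo feature dynamics so that t = 0 is the
#' end of metaphase — the last frame at or before anaphase onset (taken
#' from the lineage table's nuclear-division timing).  Offsets count
#' backward in minutes on the acquisition grid; no interpolation is
#' performed, every matrix entry is an original track value.  Volume
#' dynamics are additionally normalized by each embryo's value at t = 0.
#'
#' @param cohort an `embryo_cohort` (list of embryos with `tree` and
#'   `features`).
#' @param cell cell type name.
#' @param feature feature column name (e.g. `"sphericity"`, `"volume"`).
#' @return A `registered_dynamics` object: `offsets` (minutes, <= 0),
#'   `mat` (embryo x offset), `mean` (across-embryo mean per offset),
#'   `n_embryos`.  Embryos lacking an anaphase frame for the cell are
#'   excluded (listed in `excluded`).
#' @export
register_at_metaphase_end <- function(cohort, cell, feature = "sphericity") {
  per <- list()
  excluded <- integer(0)
  for (e in seq_along(cohort)) {
    emb <- cohort[[e]]
    i <- match(cell, emb$tree$name)
    if (is.na(i) || is.na(emb$tree$anaphase_frame[i])) {
      excluded <- c(excluded, e); next
    }
    dt <- spec_dt_min(emb$spec)
    t0 <- min(emb$tree$anaphase_frame[i], emb$tree$division_frame[i] - 1L)
    tr <- cell_track(emb$features, cell)
    tr <- tr[tr$frame <= t0, , drop = FALSE]
    if (nrow(tr) == 0) { excluded <- c(excluded, e); next }
    vals <- tr[[feature]]
    if (feature == "volume") {
      v0 <- vals[tr$frame == t0]
      if (length(v0) != 1) { excluded <- c(excluded, e); next }
      vals <- vals / v0
    }
    per[[length(per) + 1L]] <-
      list(embryo = e, offsets = (tr$frame - t0) * dt, values = vals)
  }
  if (length(per) == 0)
    stop(sprintf("no embryo provides anaphase-registered dynamics for %s", cell))
  dt <- spec_dt_min(cohort[[1]]$spec)
  kmax <- max(vapply(per, function(p) -min(p$offsets), 0))
  offsets <- round(seq(-kmax, 0, by = dt), 10)
  mat <- matrix(NA_real_, nrow = length(per), ncol = length(offsets),
                dimnames = list(vapply(per, function(p) p$embryo, 0L),
                                format(offsets)))
  for (r in seq_along(per)) {
    idx <- match(round(per[[r]]$offsets, 10), offsets)
    mat[r, idx] <- per[[r]]$values
  }
  structure(list(cell = cell, feature = feature, offsets = offsets,
                 mat = mat, mean = colMeans(mat, na.rm = TRUE),
                 n_embryos = nrow(mat), excluded = excluded),
            class = "registered_dynamics")
}

#' Estimate the mitotic-rounding onset from averaged dynamics
#'
#' Averages the across-embryo mean dynamics over all supplied cell types
#' (on the shared offset grid) and returns the offset of the minimum within
#' `window`.  The minimum marks the onset of mitotic rounding; ties resolve
#' to the earliest offset.
#'
#' @param registered list of `registered_dynamics` (one per cell type).
#' @param window offsets (minutes) searched for the minimum.
#' @return Onset offset in minutes (<= 0), with attribute `tie` if the
#'   minimum was not unique.
#' @export
estimate_rounding_window <- function(registered, window = c(-10, 0)) {
  if (inherits(registered, "registered_dynamics"))
    registered <- list(registered)
  all_off <- sort(unique(unlist(lapply(registered, `[[`, "offsets"))))
  acc <- matrix(NA_real_, nrow = length(registered), ncol = length(all_off))
  for (i in seq_along(registered)) {
    r <- registered[[i]]
    acc[i, match(round(r$offsets, 10), round(all_off, 10))] <- r$mean
  }
  grand <- colMeans(acc, na.rm = TRUE)
  keep <- all_off >= window[1] & all_off <= window[2] & is.finite(grand)
  off <- all_off[keep]; g <- grand[keep]
  hits <- which(g <= min(g) + 1e-12)
  onset <- off[min(hits)]
  attr(onset, "tie") <- length(hits) > 1
  onset
}

#' Offset of the registered dynamics' peak
#'
#' Offset (minutes) at which the across-embryo mean is maximal; ties
#' resolve to the latest offset.
#'
#' @param registered a `registered_dynamics`.
#' @return Peak offset in minutes.
#' @export
peak_offset <- function(registered) {
  g <- registered$mean
  ok <- is.finite(g)
  off <- registered$offsets[ok]; g <- g[ok]
  hits <- which(g >= max(g) - 1e-12)
  off[max(hits)]
}

#' Paired begin-vs-end window test for mitotic rounding/swelling
#'
#' For each embryo, the feature is averaged over a begin window (default
#' -7.5 to -6.5 min) and an end window (default -1.0 to 0 min) of the
#' registered dynamics; the per-embryo window means are compared by a
#' paired t-test.  The percent increase is computed from the across-embryo
#' means.  Degenerate tests (all paired differences equal) are reported as
#' non-significant with p = 1.  With fewer than 3 contributing embryos the
#' result is flagged underpowered and no significance is claimed.
#'
#' @param registered a `registered_dynamics`.
#' @param begin,end window bounds in minutes (inclusive).
#' @param alpha significance level (default 0.05).
#' @return One-row data frame: `cell`, `feature`, `n`, `begin_mean`,
#'   `end_mean`, `percent_increase`, `p_value`, `significant`,
#'   `underpowered`, `truncated` (some embryo's cycle did not cover the
#'   full begin window).
#' @export
test_window_increase <- function(registered, begin = c(-7.5, -6.5),
                                 end = c(-1, 0), alpha = 0.05) {
  off <- round(registered$offsets, 10)
  bi <- off >= begin[1] - 1e-9 & off <= begin[2] + 1e-9
  ei <- off >= end[1] - 1e-9 & off <= end[2] + 1e-9
  wmean <- function(row, idx) {
    v <- row[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  b <- apply(registered$mat, 1, wmean, idx = bi)
  e <- apply(registered$mat, 1, wmean, idx = ei)
  dt <- if (length(off) > 1) min(diff(off)) else 0.5
  n_slots <- length(seq(begin[1], begin[2], by = dt))
  full_b <- apply(registered$mat, 1, function(r) sum(!is.na(r[bi])))
  truncated <- any(!is.na(b) & full_b < n_slots)
  ok <- !is.na(b) & !is.na(e)
  b <- b[ok]; e <- e[ok]
  n <- sum(ok)
  underpowered <- n < 3
  if (n == 0) {
    p <- NA_real_; pct <- NA_real_; bm <- NA_real_; em <- NA_real_
  } else {
    bm <- mean(b); em <- mean(e)
    pct <- 100 * (em - bm) / bm
    d <- e - b
    p <- if (underpowered) NA_real_
    else if (stats::sd(d) == 0) 1
    else stats::t.test(e, b, paired = TRUE)$p.value
  }
  data.frame(cell = registered$cell, feature = registered$feature, n = n,
             begin_mean = bm, end_mean = em, percent_increase = pct,
             p_value = p,
             significant = !underpowered & !is.na(p) & p < alpha,
             underpowered = underpowered, truncated = truncated,
             stringsAsFactors = FALSE)
}

#' Window tests for every cell type of a cohort
#'
#' Runs [register_at_metaphase_end()] and [test_window_increase()] for each
#' cell type completing its cycle in at least `min_embryos` embryos.
#'
#' @inheritParams register_at_metaphase_end
#' @inheritParams test_window_increase
#' @param min_embryos minimum embryos contributing a registered cycle.
#' @return Data frame with one row per cell type.
#' @export
cohort_mitotic_tests <- function(cohort, feature = "sphericity",
                                 begin = c(-7.5, -6.5), end = c(-1, 0),
                                 alpha = 0.05, min_embryos = 3L) {
  counts <- table(unlist(lapply(cohort, function(e)
    e$tree$name[e$tree$cycle_complete])))
  cells <- names(counts)[counts >= min_embryos]
  out <- lapply(cells, function(cl) {
    reg <- register_at_metaphase_end(cohort, cl, feature)
    test_window_increase(reg, begin = begin, end = end, alpha = alpha)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
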