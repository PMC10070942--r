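# Cross-embryo contact reproducibility, contact categories, and the
# neighbor-conservation metrics used for cross-species comparison.

pair_key <- function(a, b) {
  if (any(a == b)) stop("a cell cannot contact itself")
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

contact_rows <- function(contacts, pair) {
  k <- pair_key(contacts$cell_a, contacts$cell_b)
  contacts[k == pair_key(pair[1], pair[2]), , drop = FALSE]
}

#' Reproducibility of one cell-cell contact across a cohort
#'
#' The number of embryos where the contact is formed divided by the number
#' of embryos in which both cells complete their cell cycles (contacts can
#' only be assessed where both cells are fully observed).
#'
#' @param pair character length-2: the two cell names.
#' @param cohort an `embryo_cohort`; each embryo needs `tree` and
#'   `contacts`.
#' @return Fraction in `[0, 1]`, or `NA` if no embryo has both cells
#'   completing their cycles.
#' @export
contact_reproducibility <- function(pair, cohort) {
  denom <- 0L; num <- 0L
  for (emb in cohort) {
    cc <- emb$tree$cycle_complete[match(pair, emb$tree$name)]
    if (length(cc) != 2 || anyNA(cc) || !all(cc)) next
    denom <- denom + 1L
    if (nrow(contact_rows(emb$contacts, pair)) > 0) num <- num + 1L
  }
  if (denom == 0L) return(NA_real_)
  num / denom
}

#' Integral contact area
#'
#' Plain sum of the per-frame contact areas over a contact's lifetime
#' (um^2; note the value scales with the frame rate).  `per_minute = TRUE`
#' instead weights each frame by the frame interval, giving um^2 x min.
#'
#' @param track contact-track rows for one pair in one embryo.
#' @param per_minute weight frames by the frame interval in minutes.
#' @param frame_interval frame interval in seconds (needed when
#'   `per_minute = TRUE`).
#' @return Integral area (um^2, or um^2 min).
#' @export
integral_area <- function(track, per_minute = FALSE, frame_interval = 30) {
  if (nrow(track) == 0) return(0)
  if (per_minute) sum(track$area) * frame_interval / 60 else sum(track$area)
}

# life interval (first, last frame) of a cell in one embryo's tree
life_interval <- function(tree, cell) {
  i <- match(cell, tree$name)
  if (is.na(i)) return(NULL)
  c(tree$birth_frame[i], cell_last_frame(tree, cell))
}

#' Is a variable contact explainable by division-timing shifts?
#'
#' For every embryo where the pair never touches, checks whether the two
#' cells' life intervals simply fail to overlap and whether shifting one
#' cell's interval by at most `max_shift` frames would create co-existence.
#' If so in every non-contact embryo, the missing contact is attributed to
#' division-timing variability; if the cells do co-exist without touching
#' in some embryo, the variability is attributed to cell arrangement
#' instead.
#'
#' @inheritParams contact_reproducibility
#' @param max_shift maximum virtual shift in frames (default 2).
#' @return `TRUE` (timing-variable), `FALSE` (not timing-explainable), or
#'   `NA` if the pair is not variable in this cohort.
#' @export
detect_timing_variability <- function(pair, cohort, max_shift = 2L) {
  any_noncontact <- FALSE
  for (emb in cohort) {
    cc <- emb$tree$cycle_complete[match(pair, emb$tree$name)]
    if (length(cc) != 2 || anyNA(cc) || !all(cc)) next
    if (nrow(contact_rows(emb$contacts, pair)) > 0) next
    any_noncontact <- TRUE
    ia <- life_interval(emb$tree, pair[1])
    ib <- life_interval(emb$tree, pair[2])
    overlap <- min(ia[2], ib[2]) - max(ia[1], ib[1]) + 1L
    if (overlap > 0) return(FALSE)   # co-alive yet untouching: arrangement
    if (-overlap + 1L > max_shift) return(FALSE)
  }
  if (!any_noncontact) return(NA)
  TRUE
}

#' Summarize every contact of a cohort
#'
#' One row per observed cell pair: reproducibility, mean integral area over
#' the embryos forming the contact, timing-variability flag, and a
#' false-detection-candidate flag (integral area below `area_floor` and
#' never lasting more than a single frame).
#'
#' @inheritParams detect_timing_variability
#' @param area_floor integral-area floor (um^2) for the false-detection
#'   candidate flag.
#' @return Data frame of contact summaries.
#' @export
summarize_contacts <- function(cohort, max_shift = 2L, area_floor = 5) {
  keys <- unique(unlist(lapply(cohort, function(emb)
    if (nrow(emb$contacts)) pair_key(emb$contacts$cell_a, emb$contacts$cell_b))))
  rows <- lapply(keys, function(k) {
    pair <- strsplit(k, "|", fixed = TRUE)[[1]]
    areas <- c(); max_dur <- 0L
    for (emb in cohort) {
      tr <- contact_rows(emb$contacts, pair)
      if (nrow(tr) > 0) {
        areas <- c(areas, integral_area(tr))
        max_dur <- max(max_dur, nrow(tr))
      }
    }
    rep_ <- contact_reproducibility(pair, cohort)
    timing <- if (!is.na(rep_) && rep_ < 1)
      isTRUE(detect_timing_variability(pair, cohort, max_shift)) else NA
    data.frame(cell_a = pair[1], cell_b = pair[2],
               reproducibility = rep_,
               integral_area = mean(areas),
               n_embryos_contact = length(areas),
               timing_variable = timing,
               false_detection = mean(areas) < area_floor & max_dur <= 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorize contacts and report category shares
#'
#' Splits contacts into three categories — timing-variable,
#' arrangement-variable, perfectly reproducible — and reports each
#' category's share of the total contact count and of the total integral
#' area.  False-detection candidates are reported separately, not deleted.
#' Also reports the biphasic split around an integral-area threshold
#' (contacts above it are expected to be mostly perfectly reproducible).
#'
#' @param summaries output of [summarize_contacts()].
#' @param area_threshold biphasic integral-area threshold (um^2), default
#'   1000.
#' @return List: `proportions` (per category: count share and area share,
#'   in percent), `biphasic` (per side of the threshold: n and percent
#'   perfectly reproducible), `false_detections` (the flagged rows).
#' @export
categorize_contacts <- function(summaries, area_threshold = 1000) {
  s <- summaries[!is.na(summaries$reproducibility), , drop = FALSE]
  cat_of <- ifelse(s$reproducibility >= 1, "perfectly-reproducible",
                   ifelse(!is.na(s$timing_variable) & s$timing_variable,
                          "timing-variable", "arrangement-variable"))
  lev <- c("timing-variable", "arrangement-variable", "perfectly-reproducible")
  cnt <- table(factor(cat_of, levels = lev))
  ar <- tapply(s$integral_area, factor(cat_of, levels = lev), sum,
               default = 0)
  props <- data.frame(category = lev,
                      n = as.integer(cnt),
                      pct_count = 100 * as.numeric(cnt) / nrow(s),
                      pct_area = 100 * as.numeric(ar) / sum(s$integral_area),
                      stringsAsFactors = FALSE)
  hi <- s$integral_area > area_threshold
  biphasic <- data.frame(
    side = c("above", "below"),
    n = c(sum(hi), sum(!hi)),
    pct_perfect = 100 * c(
      if (any(hi)) mean(s$reproducibility[hi] >= 1) else NA,
      if (any(!hi)) mean(s$reproducibility[!hi] >= 1) else NA),
    stringsAsFactors = FALSE)
  list(proportions = props, biphasic = biphasic,
       false_detections = s[s$false_detection, , drop = FALSE])
}

# neighbor sets of `cell` at `n_points` evenly sampled frames of its cycle,
# after removing contacts below `area_frac` of the cell's surface area
neighbor_sets <- function(emb, cell, n_points = 50L, area_frac = 0.05) {
  iv <- life_interval(emb$tree, cell)
  if (is.null(iv)) stop(sprintf("cell %s absent from embryo", cell))
  frames <- round(seq(iv[1], iv[2], length.out = n_points))
  tr <- cell_track(emb$features, cell)
  touches <- emb$contacts$cell_a == cell | emb$contacts$cell_b == cell
  cc <- emb$contacts[touches, , drop = FALSE]
  lapply(frames, function(f) {
    sa <- tr$surface_area[tr$frame == f]
    if (length(sa) != 1) return(character(0))
    rows <- cc[cc$frame == f & cc$area >= area_frac * sa, , drop = FALSE]
    setdiff(unique(c(rows$cell_a, rows$cell_b)), cell)
  })
}

#' Neighbor-reproducibility score of one cell between two embryos
#'
#' At each of `n_points` normalized time points of the cell's cycle, the
#' filtered neighbor sets (contacts below `area_frac` of the cell's surface
#' area are removed as noise) of the two embryos are compared as
#' `|intersection| / |union|`; the score is the maximum of this fraction
#' across the cycle.  1 means the neighbor sets coincide at some time
#' (and trivially when they coincide at every time); 0 means no common
#' neighbor at any time.
#'
#' @param cell cell name (must complete its cycle in both embryos).
#' @param emb_a,emb_b embryo objects (`tree`, `features`, `contacts`).
#' @param n_points normalized time resolution (default 50).
#' @param area_frac noise filter fraction of the cell surface (default
#'   0.05).
#' @param agreement `"union"` (Jaccard, default) or `"min"` (shared count
#'   over the smaller set).
#' @return Score in `[0, 1]`.
#' @export
neighbor_reproducibility <- function(cell, emb_a, emb_b, n_points = 50L,
                                     area_frac = 0.05,
                                     agreement = c("union", "min")) {
  agreement <- match.arg(agreement)
  na <- neighbor_sets(emb_a, cell, n_points, area_frac)
  nb <- neighbor_sets(emb_b, cell, n_points, area_frac)
  frac <- vapply(seq_len(n_points), function(t) {
    a <- na[[t]]; b <- nb[[t]]
    denom <- if (agreement == "union") length(union(a, b))
    else min(length(a), length(b))
    if (denom == 0) 0 else length(intersect(a, b)) / denom
  }, 0)
  max(frac)
}

#' Contact duration as a fraction of the shorter cell cycle
#'
#' @param track contact-track rows for one pair in one embryo (or an
#'   integer count of contact frames).
#' @param cycle_a,cycle_b the two cells' cycle lengths in frames.
#' @return Fraction in `[0, 1]`.
#' @export
contact_duration_fraction <- function(track, cycle_a, cycle_b) {
  stopifnot(cycle_a > 0, cycle_b > 0)
  n <- if (is.data.frame(track)) length(unique(track$frame)) else track
  min(1, n / min(cycle_a, cycle_b))
}

#' Neighbor-conservation percentages by generation
#'
#' Aggregates neighbor-reproducibility scores per cell (median across
#' embryo pairs) and reports, per cell generation, the percentage of cells
#' whose aggregated score reaches each threshold.
#'
#' @param scores data frame with columns `cell`, `generation`, `score`
#'   (one row per cell x embryo pair).
#' @param thresholds score thresholds (default `c(0.5, 0.8)`).
#' @return Data frame: `generation`, `threshold`, `pct_cells`, `n_cells`.
#' @export
conservation_summary <- function(scores, thresholds = c(0.5, 0.8)) {
  agg <- stats::aggregate(score ~ cell + generation, data = scores,
                          FUN = stats::median)
  out <- list()
  for (g in sort(unique(agg$generation))) {
    sub <- agg[agg$generation == g, ]
    for (th in thresholds)
      out[[length(out) + 1L]] <- data.frame(
        generation = g, threshold = th,
        pct_cells = 100 * mean(sub$score >= th),
        n_cells = nrow(sub))
  }
  do.call(rbind, out)
}
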