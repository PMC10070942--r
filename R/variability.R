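# Pairwise variability metrics and the lineage/generation/time/contact
# dependence analyses.

#' Variability of two feature-dynamics vectors
#'
#' For two equal-length, strictly positive dynamics `f_a(t)` and `f_b(t)`,
#' `v = (1/n) * sum_t |f_a(t) - f_b(t)| / (f_a(t) + f_b(t))`.  The value
#' lies in `[0, 1)`: 0 for identical dynamics, approaching 1 for very
#' different ones.  Symmetric in the two inputs.
#'
#' @param fa,fb numeric vectors of equal length, strictly positive
#'   (feature dynamics after time normalization).
#' @return The variability `v`.
#' @export
variability_v <- function(fa, fb) {
  if (length(fa) != length(fb))
    stop("feature dynamics must have equal length")
  if (any(!is.finite(fa)) || any(!is.finite(fb)) ||
      any(fa <= 0) || any(fb <= 0))
    stop("variability metric requires strictly positive dynamics")
  mean(abs(fa - fb) / (fa + fb))
}

#' Volume-variability metric between two cells
#'
#' `Mv = |V_A - V_B| / (V_A + V_B)` for two median cell-cycle volumes;
#' 0 when the volumes are equal, approaching 1 for very different volumes.
#'
#' @param va,vb median cell-cycle volumes (um^3, > 0).
#' @return The variability `Mv` in `[0, 1)`.
#' @export
mv <- function(va, vb) {
  if (any(!is.finite(c(va, vb))) || any(c(va, vb) <= 0))
    stop("Mv requires strictly positive volumes")
  abs(va - vb) / (va + vb)
}

#' Integral RMSD between two cells' normalized feature dynamics
#'
#' Per feature, the root-mean-square error over the normalized time points
#' is divided by the mean of the two cells' pooled values of that feature,
#' and the normalized RMSEs are summed across features.  Invariant to a
#' common positive rescaling of both inputs.
#'
#' @param track_a,track_b normalized tracks of the two cells (data frames
#'   with a `norm_time` column and the feature columns; equal lengths).
#' @param features feature column names (default volume, surface area,
#'   sphericity).
#' @return List: `value` (summed normalized RMSE) and `components` (named
#'   per-feature contributions).
#' @export
integral_rmsd <- function(track_a, track_b,
                          features = c("volume", "surface_area",
                                       "sphericity")) {
  if (nrow(track_a) != nrow(track_b))
    stop("tracks must be time-normalized to equal length")
  miss <- setdiff(features, intersect(names(track_a), names(track_b)))
  if (length(miss))
    stop("feature(s) missing from a track: ", paste(miss, collapse = ", "))
  comp <- vapply(features, function(f) {
    a <- track_a[[f]]; b <- track_b[[f]]
    sqrt(mean((a - b)^2)) / mean(c(a, b))
  }, 0)
  list(value = sum(comp), components = comp)
}

#' Eq.-style pairwise variability scores for a normalized cohort
#'
#' Computes [variability_v()] of one feature for every cell type and every
#' unordered embryo pair in which the cell completed its cycle.
#'
#' @param norm_cohort list (one element per embryo) of normalized feature
#'   tables as returned by [normalize_embryo_time()].
#' @param feature feature column (default `"volume"`).
#' @return Data frame: `cell`, `embryo_a`, `embryo_b`, `v`.
#' @export
pairwise_variability <- function(norm_cohort, feature = "volume") {
  n <- length(norm_cohort)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- intersect(unique(norm_cohort[[i]]$cell),
                        unique(norm_cohort[[j]]$cell))
    for (cl in common) {
      fa <- norm_cohort[[i]][norm_cohort[[i]]$cell == cl, feature]
      fb <- norm_cohort[[j]][norm_cohort[[j]]$cell == cl, feature]
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cl, embryo_a = i, embryo_b = j,
        v = variability_v(fa, fb), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type distinguishability from integral RMSDs
#'
#' A cell type X is distinguished from type Y when the integral RMSDs
#' among X's replicates (intra-type, across embryos) are significantly
#' smaller than the X-vs-Y distances (one-sided Welch test at `alpha`).
#' Reports, per type, the fraction of other types distinguished, plus two
#' cohort summaries: the percentage of types distinguished from at least
#' `frac_threshold` of the others, and the mean distinguished fraction.
#'
#' @inheritParams pairwise_variability
#' @param features features entering the integral RMSD.
#' @param alpha significance level (default 0.05).
#' @param frac_threshold per-type fraction defining the headline summary
#'   (default 0.95).
#' @return List: `per_type` data frame, `pct_types_above`, `mean_fraction`,
#'   `excluded` (types with too few replicates).
#' @export
distinguishability <- function(norm_cohort,
                               features = c("volume", "surface_area",
                                            "sphericity"),
                               alpha = 0.05, frac_threshold = 0.95) {
  inst <- list()   # (cell, embryo) -> track
  for (e in seq_along(norm_cohort)) {
    tab <- norm_cohort[[e]]
    for (cl in unique(tab$cell))
      inst[[paste(cl, e, sep = "@")]] <- tab[tab$cell == cl, , drop = FALSE]
  }
  meta <- do.call(rbind, strsplit(names(inst), "@", fixed = TRUE))
  cells <- meta[, 1]
  types <- sort(unique(cells))
  reps <- table(cells)
  usable <- names(reps)[reps >= 3]
  excluded <- setdiff(types, usable)
  dmat <- matrix(NA_real_, length(inst), length(inst))
  for (i in seq_along(inst)) for (j in seq_len(i - 1)) {
    dmat[i, j] <- dmat[j, i] <-
      integral_rmsd(inst[[i]], inst[[j]], features)$value
  }
  intra <- function(x) {
    ii <- which(cells == x)
    dmat[ii, ii][lower.tri(matrix(0, length(ii), length(ii)))]
  }
  res <- lapply(usable, function(x) {
    dx <- intra(x)
    others <- setdiff(usable, x)
    disting <- vapply(others, function(y) {
      dxy <- as.vector(dmat[cells == x, cells == y])
      if (stats::sd(dx) == 0 && stats::sd(dxy) == 0)
        return(mean(dxy) > mean(dx) + 1e-12)   # degenerate: compare levels
      p <- tryCatch(stats::t.test(dx, dxy, alternative = "less")$p.value,
                    error = function(e) NA_real_)
      !is.na(p) && p < alpha
    }, TRUE)
    data.frame(cell = x, n_other = length(others),
               fraction_distinguished = mean(disting),
               stringsAsFactors = FALSE)
  })
  per_type <- do.call(rbind, res)
  list(per_type = per_type,
       pct_types_above =
         100 * mean(per_type$fraction_distinguished >= frac_threshold),
       mean_fraction = mean(per_type$fraction_distinguished),
       excluded = excluded)
}

#' Integral-RMSD distance matrix for external embedding
#'
#' Builds the symmetric, zero-diagonal distance matrix over all (cell x
#' embryo) instances, for use as a precomputed distance in an external
#' embedding (e.g. UMAP); the embedding itself is decorative and not
#' validated here.  Since the score is not guaranteed to be a metric,
#' triangle-inequality violations are counted and reported.
#'
#' @inheritParams distinguishability
#' @return List: `matrix`, `labels` (data frame `cell`, `embryo`),
#'   `triangle_violations` (count of ordered pairs whose direct distance
#'   exceeds some two-leg path).
#' @export
distance_matrix_export <- function(norm_cohort,
                                   features = c("volume", "surface_area",
                                                "sphericity")) {
  inst <- list(); lab <- list()
  for (e in seq_along(norm_cohort)) {
    tab <- norm_cohort[[e]]
    for (cl in unique(tab$cell)) {
      inst[[length(inst) + 1L]] <- tab[tab$cell == cl, , drop = FALSE]
      lab[[length(lab) + 1L]] <- data.frame(cell = cl, embryo = e,
                                            stringsAsFactors = FALSE)
    }
  }
  n <- length(inst)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1))
    D[i, j] <- D[j, i] <- integral_rmsd(inst[[i]], inst[[j]], features)$value
  best <- matrix(Inf, n, n)
  for (k in seq_len(n))
    best <- pmin(best, outer(D[, k], D[k, ], "+"))
  viol <- sum(D > best + 1e-12) / 2
  list(matrix = D, labels = do.call(rbind, lab), triangle_violations = viol)
}

#' Grouped variability distributions with Welch tests
#'
#' Groups pairwise variability scores by founder lineage or by cell
#' generation, summarizes each group (n, median, quartiles, mean), and
#' runs pairwise Welch two-sample t-tests between groups.
#'
#' @param scores data frame from [pairwise_variability()].
#' @param tree a [lineage_tree()] used to resolve generations.
#' @param grouping `"lineage"` or `"generation"`.
#' @param alpha significance level for the pairwise tests (default 0.01).
#' @return List: `summary` (per group), `tests` (pairwise Welch results).
#' @export
variability_by_group <- function(scores, tree,
                                 grouping = c("lineage", "generation"),
                                 alpha = 0.01) {
  grouping <- match.arg(grouping)
  g <- if (grouping == "lineage") founder_lineage(scores$cell)
  else tree$generation[match(scores$cell, tree$name)]
  keep <- !is.na(g)
  scores <- scores[keep, , drop = FALSE]
  g <- g[keep]
  counts <- table(g)
  groups <- names(counts)[counts >= 2]
  summ <- do.call(rbind, lapply(groups, function(x) {
    v <- scores$v[g == x]
    data.frame(group = x, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               mean = mean(v), stringsAsFactors = FALSE)
  }))
  tests <- list()
  if (length(groups) >= 2)
    for (ij in utils::combn(groups, 2, simplify = FALSE)) {
      va <- scores$v[g == ij[1]]; vb <- scores$v[g == ij[2]]
      p <- tryCatch(stats::t.test(va, vb)$p.value,
                    error = function(e) NA_real_)
      tests[[length(tests) + 1L]] <- data.frame(
        group_a = ij[1], group_b = ij[2],
        mean_a = mean(va), mean_b = mean(vb), p_value = p,
        significant = !is.na(p) && p < alpha, stringsAsFactors = FALSE)
    }
  list(summary = summ, tests = do.call(rbind, tests))
}

#' Per-time-point variability course
#'
#' Evaluates the variability summand `|f_a - f_b| / (f_a + f_b)` at each
#' normalized time point for every cell and embryo pair, plus a Welch test
#' between the initial and final time points (testing whether variability
#' grows over the cell cycle / with developmental time).
#'
#' @inheritParams pairwise_variability
#' @param alpha significance level (default 0.01).
#' @return List: `course` (data frame `cell`, `embryo_a`, `embryo_b`,
#'   `norm_time`, `v_t`), `mean_course`, `p_initial_vs_final`,
#'   `significant`.
#' @export
variability_time_course <- function(norm_cohort, feature = "volume",
                                    alpha = 0.01) {
  n <- length(norm_cohort)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- intersect(unique(norm_cohort[[i]]$cell),
                        unique(norm_cohort[[j]]$cell))
    for (cl in common) {
      a <- norm_cohort[[i]][norm_cohort[[i]]$cell == cl, ]
      b <- norm_cohort[[j]][norm_cohort[[j]]$cell == cl, ]
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cl, embryo_a = i, embryo_b = j, norm_time = a$norm_time,
        v_t = abs(a[[feature]] - b[[feature]]) /
          (a[[feature]] + b[[feature]]),
        stringsAsFactors = FALSE)
    }
  }
  course <- do.call(rbind, rows)
  rownames(course) <- NULL
  tmin <- min(course$norm_time); tmax <- max(course$norm_time)
  vi <- course$v_t[course$norm_time == tmin]
  vf <- course$v_t[course$norm_time == tmax]
  p <- tryCatch(stats::t.test(vi, vf)$p.value, error = function(e) NA_real_)
  mean_course <- stats::aggregate(v_t ~ norm_time, data = course, FUN = mean)
  list(course = course, mean_course = mean_course,
       p_initial_vs_final = p,
       significant = !is.na(p) && p < alpha)
}

#' Contact dependence of variability
#'
#' Correlates the variability dynamics of cell pairs across embryo pairs:
#' for each contacting same-generation cell pair, the Pearson correlation
#' between the two cells' variability scores over the shared embryo pairs;
#' the same for count-matched mock pairs (same generation, never
#' contacting in any embryo), sampled with a fixed seed.
#'
#' @param scores data frame from [pairwise_variability()].
#' @param contact_pairs data frame with columns `cell_a`, `cell_b` of pairs
#'   observed in contact (in any embryo).
#' @param tree a [lineage_tree()] for generation lookup.
#' @param seed seed for mock-pair sampling.
#' @return List: `contact` and `mock` data frames of per-pair correlations,
#'   `mean_contact_r`, `mean_mock_r`, `n_contact`, `n_mock`.
#' @export
contact_dependence <- function(scores, contact_pairs, tree, seed = 1L) {
  if (any(contact_pairs$cell_a == contact_pairs$cell_b))
    stop("a cell cannot contact itself")
  gen <- stats::setNames(tree$generation, tree$name)
  cells <- sort(unique(scores$cell))
  ckeys <- unique(pair_key(contact_pairs$cell_a, contact_pairs$cell_b))
  pair_r <- function(a, b) {
    sa <- scores[scores$cell == a, ]
    sb <- scores[scores$cell == b, ]
    m <- merge(sa, sb, by = c("embryo_a", "embryo_b"))
    if (nrow(m) < 3 || stats::sd(m$v.x) == 0 || stats::sd(m$v.y) == 0)
      return(NA_real_)
    stats::cor(m$v.x, m$v.y)
  }
  all_pairs <- utils::combn(cells, 2, simplify = FALSE)
  same_gen <- Filter(function(p) {
    !is.na(gen[p[1]]) && !is.na(gen[p[2]]) && gen[p[1]] == gen[p[2]]
  }, all_pairs)
  is_contact <- vapply(same_gen, function(p)
    pair_key(p[1], p[2]) %in% ckeys, TRUE)
  contact_list <- same_gen[is_contact]
  mock_pool <- same_gen[!is_contact]
  r_of <- function(lst) {
    if (!length(lst)) return(data.frame(cell_a = character(),
                                        cell_b = character(), r = numeric()))
    out <- do.call(rbind, lapply(lst, function(p) data.frame(
      cell_a = p[1], cell_b = p[2], r = pair_r(p[1], p[2]),
      stringsAsFactors = FALSE)))
    out[!is.na(out$r), , drop = FALSE]
  }
  contact_df <- r_of(contact_list)
  n_mock <- min(length(mock_pool), max(nrow(contact_df), 1L))
  mock_sel <- if (length(mock_pool))
    with_seed(seed, sample(mock_pool, n_mock)) else list()
  mock_df <- r_of(mock_sel)
  list(contact = contact_df, mock = mock_df,
       mean_contact_r = if (nrow(contact_df)) mean(contact_df$r) else NA_real_,
       mean_mock_r = if (nrow(mock_df)) mean(mock_df$r) else NA_real_,
       n_contact = nrow(contact_df), n_mock = nrow(mock_df))
}
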