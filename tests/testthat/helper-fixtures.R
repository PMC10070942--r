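# Shared fixtures and independent oracles (deliberately naive code paths).

# Small six-division program with one strongly asymmetric division (2.9).
tiny_program <- function(ratio_p2 = 2.9, jitter_sd = 1) {
  lineage_program(
    divisions = data.frame(
      mother = c("AB", "P1", "ABa", "ABp", "EMS", "P2"),
      mean_min = c(6, 8, 20, 20.5, 21, 22),
      ratio = c(1, 1.45, 1, 1, 1.25, ratio_p2),
      jitter_sd = jitter_sd),
    roots = data.frame(name = c("AB", "P1"), fraction = c(0.55, 0.45),
                       px = c(-0.35, 0.42), py = c(0.05, -0.05),
                       pz = c(0, 0)),
    cell_programs = data.frame(name = c("ABa", "ABp"), sph_amp = NA,
                               vol_amp = NA, onset_min = NA,
                               plateau_min = 4.5, lag_frames = NA))
}

tiny_spec <- function(n_frames = 56L, rate_factor = 1) {
  embryo_spec(semi_axes = c(17, 11, 11), dims = c(72, 48, 48),
              n_frames = n_frames, rate_factor = rate_factor)
}

# labeled_volume holding axis-aligned blocks: blocks is a list of
# list(label=, lo=c(i,j,k), hi=c(i,j,k)) in 1-based voxel indices
block_volume <- function(dims, blocks, spacing = c(0.5, 0.5, 0.5),
                         frame = 0L) {
  arr <- array(0L, dim = dims)
  for (b in blocks)
    arr[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- b$label
  labeled_volume(arr, spacing, frame = frame, time_min = frame * 0.5)
}

# digitized ball of radius r voxels in an odd cube, spacing in um
ball_volume <- function(r, spacing = c(1, 1, 1), label = 1L) {
  n <- 2L * (r + 5L) + 1L
  c0 <- r + 6L
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  inside <- (idx$i - c0)^2 + (idx$j - c0)^2 + (idx$k - c0)^2 <= r^2
  arr <- array(0L, dim = c(n, n, n))
  arr[as.matrix(idx[inside, ])] <- label
  labeled_volume(arr, spacing)
}

# Brute-force contact enumeration: walk every voxel and its 3 forward
# 6-neighbors in plain R.  Independent of the compiled path.
bf_contacts <- function(vol) {
  a <- vol$labels
  d <- dim(a)
  sp <- vol$spacing
  acc <- list()
  add <- function(l1, l2, area) {
    key <- paste(min(l1, l2), max(l1, l2))
    acc[[key]] <<- (if (is.null(acc[[key]])) 0 else acc[[key]]) + area
  }
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    l <- a[i, j, k]
    if (l == 0L) next
    if (i < d[1] && a[i + 1, j, k] != 0L && a[i + 1, j, k] != l)
      add(l, a[i + 1, j, k], sp[2] * sp[3])
    if (j < d[2] && a[i, j + 1, k] != 0L && a[i, j + 1, k] != l)
      add(l, a[i, j + 1, k], sp[1] * sp[3])
    if (k < d[3] && a[i, j, k + 1] != 0L && a[i, j, k + 1] != l)
      add(l, a[i, j, k + 1], sp[1] * sp[2])
  }
  if (length(acc) == 0)
    return(data.frame(a = integer(), b = integer(), area = numeric()))
  pairs <- do.call(rbind, strsplit(names(acc), " "))
  out <- data.frame(a = as.integer(pairs[, 1]), b = as.integer(pairs[, 2]),
                    area = unname(unlist(acc)))
  out[order(out$a, out$b), ]
}

# Exhaustive-permutation assignment oracle for small n.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1))
    for (pos in 0:(n - 1))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

bf_assignment <- function(cost) {
  n <- nrow(cost)
  best <- NULL; best_cost <- Inf
  for (p in all_permutations(n)) {
    cc <- sum(cost[cbind(1:n, p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(assignment = unlist(best), cost = best_cost)
}

# Minimal embryo stub for contact analyses that need only tree + contacts.
stub_tree <- function(names, complete = TRUE, birth = 0L, division = 40L,
                      n_frames = 60L) {
  n <- length(names)
  cells <- data.frame(name = names, parent = NA_character_,
                      birth_frame = rep_len(birth, n),
                      division_frame = if (complete)
                        rep_len(division, n) else rep(NA_integer_, n),
                      anaphase_frame = if (complete)
                        rep_len(division - 2L, n) else rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
  lineage_tree(cells, 30, n_frames)
}

stub_contacts <- function(...) {
  rows <- list(...)
  if (length(rows) == 0)
    return(structure(data.frame(cell_a = character(), cell_b = character(),
                                frame = integer(), time_min = numeric(),
                                area = numeric()),
                     class = c("contact_tracks", "data.frame")))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(cell_a = pmin(r$pair[1], r$pair[2]),
               cell_b = pmax(r$pair[1], r$pair[2]),
               frame = r$frames, time_min = r$frames * 0.5,
               area = rep_len(r$area, length(r$frames)),
               stringsAsFactors = FALSE)))
  structure(out, class = c("contact_tracks", "data.frame"))
}

# Embryo whose focal cell has exactly the given neighbor sets at each of
# its 50 cycle frames; all contact areas sit far above the 5% filter.
neighbor_embryo <- function(cell, neighbors_by_frame, others,
                            n_frames = 50L) {
  stopifnot(length(neighbors_by_frame) == n_frames)
  tree <- stub_tree(c(cell, others), division = n_frames,
                    n_frames = n_frames + 10L)
  frames <- 0:(n_frames - 1L)
  features <- data.frame(cell = cell, frame = frames,
                         time_min = frames * 0.5, volume = 1000,
                         surface_area = 100, sphericity = 0.85,
                         cx = 0, cy = 0, cz = 0, stringsAsFactors = FALSE)
  rows <- list()
  for (t in seq_len(n_frames))
    for (nb in neighbors_by_frame[[t]])
      rows[[length(rows) + 1L]] <-
        list(pair = c(cell, nb), frames = frames[t], area = 50)
  contacts <- do.call(stub_contacts, rows)
  list(id = 1L, tree = tree, features = features, contacts = contacts)
}
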