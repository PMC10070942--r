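#' Synthetic embryo specification
#'
#' Imaging-like geometry and timing for a synthetic embryo: an ellipsoidal
#' eggshell rasterized on an anisotropy-capable voxel grid, a fixed frame
#' interval, and a per-embryo developmental-rate multiplier.  Defaults mimic
#' a desk-scale early *C. elegans* recording: 0.5 um voxels, 30 s frames,
#' eggshell semi-axes (23, 15, 15) um inside a 96x64x64 grid.
#'
#' @param semi_axes eggshell semi-axes (um), length 3.
#' @param spacing voxel spacing `(dx, dy, dz)` (um).
#' @param dims grid size in voxels, length 3.
#' @param frame_interval frame interval in seconds.
#' @param n_frames number of frames.
#' @param rate_factor developmental-rate multiplier (1 = nominal; larger is
#'   faster).  Must lie within `rate_band`.
#' @param rate_band allowed band for `rate_factor`; the default `[1/1.1,
#'   1.1]` keeps the fastest/slowest ratio at 1.2 across a cohort.
#' @return An `embryo_spec` object.
#' @export
embryo_spec <- function(semi_axes = c(23, 15, 15),
                        spacing = c(0.5, 0.5, 0.5),
                        dims = c(96, 64, 64),
                        frame_interval = 30,
                        n_frames = 120,
                        rate_factor = 1,
                        rate_band = c(1 / 1.1, 1.1)) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            length(spacing) == 3, all(spacing > 0),
            length(dims) == 3, all(dims >= 4),
            frame_interval > 0, n_frames >= 2)
  if (rate_factor < rate_band[1] || rate_factor > rate_band[2])
    stop(sprintf("rate_factor %.3f outside the allowed band [%.3f, %.3f]",
                 rate_factor, rate_band[1], rate_band[2]))
  if (any(2 * semi_axes > dims * spacing))
    stop("eggshell does not fit inside the voxel grid")
  structure(list(semi_axes = semi_axes, spacing = spacing,
                 dims = as.integer(dims), frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), rate_factor = rate_factor,
                 rate_band = rate_band),
            class = "embryo_spec")
}

spec_center <- function(spec) spec$dims * spec$spacing / 2
spec_dt_min <- function(spec) spec$frame_interval / 60

#' Lineage program for the synthetic generator
#'
#' The ground-truth developmental program: a division table (mother, mean
#' division time, timing jitter, daughter volume ratio), root cells with
#' their initial volume fractions, and per-cell mitotic programs (rounding
#' onset and sphericity amplitude, swelling amplitude, optional plateau,
#' karyokinesis-cytokinesis lag).  Daughter names follow Sulston
#' nomenclature via [sulston_daughters()]; the first-listed daughter is the
#' larger one when `ratio > 1`.
#'
#' @param divisions data frame with columns `mother`, `mean_min` (mean
#'   division time, minutes from movie start), and optionally `jitter_sd`
#'   (frames) and `ratio` (daughter volume ratio >= 1).
#' @param roots data frame with columns `name`, `fraction` (initial volume
#'   fractions summing to 1) and `px`, `py`, `pz` (initial positions in
#'   units of the eggshell semi-axes).
#' @param cell_programs optional data frame overriding per-cell defaults;
#'   columns `name` plus any of `sph_amp`, `vol_amp`, `onset_min`,
#'   `plateau_min`, `lag_frames`.
#' @param defaults named list of per-cell defaults: `sph_amp` (fractional
#'   sphericity amplitude of mitotic rounding), `vol_amp` (fractional volume
#'   amplitude of mitotic swelling), `onset_min` (rounding/swelling onset
#'   before anaphase, minutes), `plateau_min` (minutes before anaphase at
#'   which the sphericity rise plateaus; 0 = rise to the end), `lag_frames`
#'   (karyokinesis-cytokinesis lag), `jitter_sd` (frames), `ratio`.
#' @return A `lineage_program` object.
#' @export
lineage_program <- function(divisions, roots,
                            cell_programs = NULL,
                            defaults = list()) {
  defaults <- utils::modifyList(
    list(sph_amp = 0.12, vol_amp = 0.096, onset_min = 7, plateau_min = 0,
         sph_decline = 0.04, vol_decline = 0.03,
         lag_frames = 2L, jitter_sd = 1, ratio = 1), defaults)
  stopifnot(all(c("mother", "mean_min") %in% names(divisions)))
  if (is.null(divisions$jitter_sd)) divisions$jitter_sd <- defaults$jitter_sd
  if (is.null(divisions$ratio)) divisions$ratio <- defaults$ratio
  if (any(divisions$ratio < 1)) stop("daughter volume ratios must be >= 1")
  stopifnot(all(c("name", "fraction", "px", "py", "pz") %in% names(roots)))
  if (abs(sum(roots$fraction) - 1) > 1e-8)
    stop("root volume fractions must sum to 1")
  if (defaults$onset_min < 0 || defaults$plateau_min < 0)
    stop("onset offsets must be >= 0")
  structure(list(divisions = divisions[order(divisions$mean_min), ],
                 roots = roots, cell_programs = cell_programs,
                 defaults = defaults),
            class = "lineage_program")
}

# per-cell program with defaults filled in
cell_program <- function(program, name) {
  out <- program$defaults
  cp <- program$cell_programs
  if (!is.null(cp)) {
    i <- match(name, cp$name)
    if (!is.na(i))
      for (f in setdiff(names(cp), "name"))
        if (!is.na(cp[[f]][i])) out[[f]] <- cp[[f]][i]
  }
  out
}

#' Default early *C. elegans* lineage program
#'
#' A stylized two-cell to ~26-cell program with invariant Sulston names,
#' asymmetric germline (P lineage) divisions, rounding in every cell,
#' swelling in most cells (Ea/Ep programmed non-swelling), and an early
#' sphericity plateau in ABa/ABp.  Timings compress the real early lineage
#' into a one-hour movie starting at the two-cell stage.
#'
#' @param jitter_sd division-timing jitter sd in frames.
#' @param sph_amp,vol_amp default rounding/swelling amplitudes (fractions).
#' @param lag_frames karyokinesis-cytokinesis lag in frames.
#' @param extra_divisions optional data frame rows appended to the division
#'   table (e.g. deeper divisions with programmed ratios).
#' @return A [lineage_program()].
#' @export
celegans_program <- function(jitter_sd = 1, sph_amp = 0.12, vol_amp = 0.096,
                             lag_frames = 2L, extra_divisions = NULL) {
  div <- data.frame(
    mother = c("AB", "P1", "ABa", "ABp", "EMS", "P2",
               "ABal", "ABar", "ABpl", "ABpr", "MS", "C", "E", "P3",
               "ABala", "ABalp", "ABara", "ABarp",
               "ABpla", "ABplp", "ABpra", "ABprp",
               "MSa", "MSp", "Ca", "Cp", "Ea", "Ep", "D"),
    mean_min = c(10, 12, 24, 24.5, 26, 28,
                 38, 38.5, 39, 39.5, 43, 44, 46, 47,
                 52, 52.5, 53, 53.5, 54, 54.5, 55, 55.5,
                 57, 57.5, 58, 58.5, 62, 62.5, 63),
    ratio = c(1, 1.45, 1, 1, 1.25, 1.55,
              1, 1, 1, 1, 1, 1, 1, 1.65,
              1, 1, 1, 1, 1, 1, 1, 1,
              1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  div$jitter_sd <- jitter_sd
  if (!is.null(extra_divisions)) {
    if (is.null(extra_divisions$jitter_sd)) extra_divisions$jitter_sd <- jitter_sd
    if (is.null(extra_divisions$ratio)) extra_divisions$ratio <- 1
    div <- rbind(div, extra_divisions[names(div)])
  }
  roots <- data.frame(name = c("AB", "P1"), fraction = c(0.55, 0.45),
                      px = c(-0.35, 0.42), py = c(0.05, -0.05), pz = c(0, 0),
                      stringsAsFactors = FALSE)
  cellp <- data.frame(name = c("ABa", "ABp", "Ea", "Ep"),
                      sph_amp = NA, vol_amp = c(NA, NA, 0, 0),
                      onset_min = NA, plateau_min = c(4.5, 4.5, NA, NA),
                      lag_frames = NA, stringsAsFactors = FALSE)
  lineage_program(div, roots, cell_programs = cellp,
                  defaults = list(sph_amp = sph_amp, vol_amp = vol_amp,
                                  lag_frames = lag_frames,
                                  jitter_sd = jitter_sd))
}

#' Generate a lineage tree from a program
#'
#' Division frames are the programmed means scaled by the embryo's
#' developmental rate (faster embryos divide earlier) plus Gaussian jitter
#' in frames.  Divisions landing beyond the movie leave the mother
#' cycle-incomplete rather than erroring.
#'
#' @param program a [lineage_program()].
#' @param spec an [embryo_spec()].
#' @param seed integer seed for the timing jitter.
#' @return A [lineage_tree()].
#' @export
generate_lineage <- function(program, spec, seed) {
  fpm <- 60 / spec$frame_interval           # frames per minute
  with_seed(seed, {
    cells <- data.frame(name = program$roots$name,
                        parent = NA_character_,
                        birth_frame = 0L,
                        division_frame = NA_integer_,
                        anaphase_frame = NA_integer_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(program$divisions))) {
      d <- program$divisions[i, ]
      j <- match(d$mother, cells$name)
      if (is.na(j)) next   # mother itself never born inside the movie
      cp <- cell_program(program, d$mother)
      f <- round(d$mean_min * fpm / spec$rate_factor +
                   stats::rnorm(1, 0, d$jitter_sd))
      f <- max(f, cells$birth_frame[j] + 4L)    # minimal 4-frame cycle
      if (f >= spec$n_frames) next              # cycle incomplete
      cells$division_frame[j] <- as.integer(f)
      cells$anaphase_frame[j] <-
        as.integer(max(f - cp$lag_frames, cells$birth_frame[j] + 1L))
      dn <- sulston_daughters(d$mother)
      cells <- rbind(cells, data.frame(
        name = dn, parent = d$mother, birth_frame = as.integer(f),
        division_frame = NA_integer_, anaphase_frame = NA_integer_,
        stringsAsFactors = FALSE))
    }
    lineage_tree(cells, spec$frame_interval, spec$n_frames)
  })
}

# Base (pre-swelling) volume fraction of each cell, by recursive ratio split.
base_fractions <- function(tree, program) {
  fr <- stats::setNames(rep(NA_real_, nrow(tree)), tree$name)
  fr[program$roots$name] <- program$roots$fraction
  for (i in seq_len(nrow(tree))) {
    nm <- tree$name[i]
    if (!is.na(fr[nm])) next
    p <- tree$parent[i]
    d <- program$divisions[program$divisions$mother == p, ][1, ]
    r <- if (is.na(d$ratio)) 1 else d$ratio
    dn <- sulston_daughters(p)
    fr[nm] <- fr[p] * if (nm == dn[1]) r / (1 + r) else 1 / (1 + r)
  }
  fr
}

# ramp in [0,1]: 0 before (anaphase - onset), 1 at (anaphase - plateau)
mitotic_ramp <- function(t_min, t_ana_min, onset_min, plateau_min = 0) {
  span <- max(onset_min - plateau_min, 1e-9)
  clamp((t_min - (t_ana_min - onset_min)) / span, 0, 1)
}

# interphase progress in [0,1]: 0 at birth, 1 at the mitotic onset
interphase_progress <- function(t_min, t_birth_min, t_ana_min, onset_min) {
  end <- t_ana_min - onset_min
  if (end <= t_birth_min) return(rep(1, length(t_min)))
  clamp((t_min - t_birth_min) / (end - t_birth_min), 0, 1)
}

# Ground-truth cell-intrinsic volume program (n_frames x n_cells), in units
# of eggshell-volume fractions before confinement: a slow interphase
# decline (gradual compression by neighbors) followed by mitotic swelling.
target_volume_program <- function(tree, program, spec) {
  nf <- spec$n_frames
  dt <- spec_dt_min(spec)
  base <- base_fractions(tree, program)
  m <- matrix(0, nrow = nf, ncol = nrow(tree),
              dimnames = list(NULL, tree$name))
  for (i in seq_len(nrow(tree))) {
    nm <- tree$name[i]
    cp <- cell_program(program, nm)
    last <- cell_last_frame(tree, nm)
    frames <- tree$birth_frame[i]:last
    t <- frames * dt
    mult <- rep(1, length(frames))
    if (!is.na(tree$anaphase_frame[i])) {
      t_ana <- tree$anaphase_frame[i] * dt
      t_birth <- tree$birth_frame[i] * dt
      mult <- 1 - cp$vol_decline *
        interphase_progress(t, t_birth, t_ana, cp$onset_min)
      if (cp$vol_amp != 0)
        mult <- mult * (1 + cp$vol_amp *
                          mitotic_ramp(t, t_ana, cp$onset_min))
    }
    m[frames + 1L, i] <- base[nm] * mult
  }
  m
}

# Per-frame volume fractions for rasterization: the volume program
# renormalized over live cells so the eggshell stays exactly filled.
target_fractions <- function(tree, program, spec) {
  m <- target_volume_program(tree, program, spec)
  sweep(m, 1, rowSums(m), "/")
}

# Deterministic per-cell-type base sphericity in [0.78, 0.84]: cell shape
# at interphase is stereotyped across embryos, so the base depends on the
# cell name only (a simple string hash), never on the embryo seed.
base_sphericity <- function(names) {
  h <- vapply(names, function(nm) {
    u <- utf8ToInt(nm)
    sum(u * seq_along(u) * 2654435761) %% 10000 / 10000
  }, 0)
  0.78 + 0.06 * h
}

# Ground-truth sphericity dynamics (n_frames x n_cells); NA when dead.
target_sphericity <- function(tree, program, spec, seed) {
  nf <- spec$n_frames
  dt <- spec_dt_min(spec)
  bases <- base_sphericity(tree$name)
  m <- matrix(NA_real_, nrow = nf, ncol = nrow(tree),
              dimnames = list(NULL, tree$name))
  for (i in seq_len(nrow(tree))) {
    nm <- tree$name[i]
    cp <- cell_program(program, nm)
    last <- cell_last_frame(tree, nm)
    frames <- tree$birth_frame[i]:last
    t <- frames * dt
    mult <- rep(1, length(frames))
    if (!is.na(tree$anaphase_frame[i])) {
      t_ana <- tree$anaphase_frame[i] * dt
      t_birth <- tree$birth_frame[i] * dt
      mult <- 1 - cp$sph_decline *
        interphase_progress(t, t_birth, t_ana, cp$onset_min)
      if (cp$sph_amp != 0) {
        ramp <- mitotic_ramp(t, t_ana, cp$onset_min, cp$plateau_min)
        if (cp$plateau_min > 0) {
          # plateau cells relax slightly after the peak, so the sphericity
          # maximum sits near the plateau onset rather than at anaphase
          past <- clamp((t - (t_ana - cp$plateau_min)) / cp$plateau_min, 0, 1)
          ramp <- ramp * (1 - 0.03 * past)
        }
        mult <- mult * (1 + cp$sph_amp * ramp)
      }
    }
    m[frames + 1L, i] <- bases[i] * mult
  }
  m
}

# Static seed position per cell: roots from the program, daughters displaced
# from the mother along a seeded random axis, kept inside the eggshell.
seed_positions <- function(tree, program, spec, seed) {
  ctr <- spec_center(spec)
  ax <- spec$semi_axes
  egg_vol <- 4 / 3 * pi * prod(ax)
  base <- base_fractions(tree, program)
  pos <- matrix(NA_real_, nrow = nrow(tree), ncol = 3,
                dimnames = list(tree$name, c("x", "y", "z")))
  for (r in seq_len(nrow(program$roots)))
    pos[program$roots$name[r], ] <-
      ctr + ax * unlist(program$roots[r, c("px", "py", "pz")])
  with_seed(seed + 13L, {
    for (i in seq_len(nrow(tree))) {
      nm <- tree$name[i]
      if (!any(is.na(pos[nm, ]))) next
      p <- tree$parent[i]
      sibs <- sulston_daughters(p)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r_mother <- (3 * base[p] * egg_vol / (4 * pi))^(1 / 3)
      fa <- base[sibs[1]] / base[p]
      off <- 0.9 * r_mother
      pos[sibs[1], ] <- pos[p, ] - u * off * (1 - fa)
      pos[sibs[2], ] <- pos[p, ] + u * off * fa
      for (s in sibs) {
        e <- (pos[s, ] - ctr) / ax
        rr <- sqrt(sum(e^2))
        if (rr > 0.85) pos[s, ] <- ctr + (pos[s, ] - ctr) * 0.85 / rr
      }
    }
  })
  pos
}

#' Synthesize ground-truth feature dynamics with measurement noise
#'
#' Produces per-cell feature tracks directly from the program's ground
#' truth: volumes from the programmed fraction dynamics (eggshell volume
#' conserved), sphericity from the programmed rounding ramps, surface area
#' derived from volume and sphericity, centroids from the cell seed
#' positions.  Observed tracks add multiplicative lognormal noise per frame.
#' Noise magnitude can differ by founder lineage (`lineage_noise`), and
#' groups of cells can share a per-embryo noise-scale component
#' (`noise_groups`/`group_sd`) to emulate contact-coupled variability.
#'
#' @param tree a [lineage_tree()] from [generate_lineage()].
#' @param program the [lineage_program()] that generated it.
#' @param spec the [embryo_spec()].
#' @param seed integer seed.
#' @param noise_sd lognormal sd of per-frame multiplicative noise.
#' @param lineage_noise optional named vector of per-lineage noise sds,
#'   e.g. `c(AB = 0.03, P = 0.01)`.
#' @param noise_groups optional list of character vectors; cells within a
#'   group share a lognormal noise-scale factor with sd `group_sd`.
#' @param group_sd sd of the shared log noise-scale (0 = disabled).
#' @param time_noise_slope fractional growth of the noise sd across the
#'   movie (0 = stationary noise); emulates the increase of variability
#'   with developmental progression.
#' @return List with `features` (a tidy feature-track data frame: one row
#'   per cell x frame), `truth` (ground-truth matrices and centroids) and
#'   `tree`.
#' @export
synthesize_features <- function(tree, program, spec, seed,
                                noise_sd = 0.01, lineage_noise = NULL,
                                noise_groups = NULL, group_sd = 0,
                                time_noise_slope = 0) {
  fr <- target_volume_program(tree, program, spec)
  sph <- target_sphericity(tree, program, spec, seed)
  pos <- seed_positions(tree, program, spec, seed)
  egg_vol <- 4 / 3 * pi * prod(spec$semi_axes)
  vol <- fr * egg_vol
  dt <- spec_dt_min(spec)
  sds <- stats::setNames(rep(noise_sd, nrow(tree)), tree$name)
  if (!is.null(lineage_noise)) {
    hit <- tree$lineage %in% names(lineage_noise)
    sds[hit] <- lineage_noise[tree$lineage[hit]]
  }
  scale_of <- stats::setNames(rep(1, nrow(tree)), tree$name)
  rows <- with_seed(seed + 29L, {
    if (group_sd > 0 && length(noise_groups))
      for (g in noise_groups)
        scale_of[g] <- exp(stats::rnorm(1, 0, group_sd))
    out <- vector("list", nrow(tree))
    for (i in seq_len(nrow(tree))) {
      nm <- tree$name[i]
      frames <- tree$birth_frame[i]:cell_last_frame(tree, nm)
      n <- length(frames)
      s_eff <- sds[nm] * scale_of[nm] *
        (1 + time_noise_slope * frames / max(spec$n_frames - 1L, 1L))
      v_obs <- vol[frames + 1L, i] * exp(stats::rnorm(n, 0, s_eff))
      s_obs <- sph[frames + 1L, i] * exp(stats::rnorm(n, 0, s_eff))
      s_obs <- pmin(s_obs, 1)
      a_obs <- pi^(1 / 3) * (6 * v_obs)^(2 / 3) / s_obs
      out[[i]] <- data.frame(
        cell = nm, frame = frames, time_min = frames * dt,
        volume = v_obs, surface_area = a_obs, sphericity = s_obs,
        cx = pos[nm, 1], cy = pos[nm, 2], cz = pos[nm, 3],
        stringsAsFactors = FALSE)
    }
    out
  })
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  class(features) <- c("feature_tracks", "data.frame")
  list(features = features,
       truth = list(fractions = fr, volume = vol, sphericity = sph,
                    centroids = pos, egg_volume = egg_vol),
       tree = tree)
}

# --- power-diagram rasterization ------------------------------------------

interior_voxels <- function(spec) {
  ctr <- spec_center(spec)
  out <- cpp_power_assign(spec$dims[1], spec$dims[2], spec$dims[3],
                          spec$spacing, ctr, spec$semi_axes,
                          matrix(ctr, 1, 3), 0)
  sum(out > 0L)
}

# Solve power-diagram weights so the rendered voxel volumes match targets.
solve_power_weights <- function(spec, seeds, targets_vox, w0 = NULL,
                                tol = 0.05, max_iter = 60, lr = 0.5) {
  n <- nrow(seeds)
  w <- if (is.null(w0)) rep(0, n) else w0
  ctr <- spec_center(spec)
  voxvol <- prod(spec$spacing)
  r2 <- (3 * targets_vox * voxvol / (4 * pi))^(2 / 3)
  labels <- NULL
  for (it in seq_len(max_iter)) {
    labels <- cpp_power_assign(spec$dims[1], spec$dims[2], spec$dims[3],
                               spec$spacing, ctr, spec$semi_axes, seeds, w)
    counts <- tabulate(labels[labels > 0L], nbins = n)
    rel <- abs(counts - targets_vox) / targets_vox
    big <- targets_vox >= 500
    if (all(counts > 0) && all(rel[big] <= tol) && all(rel[!big] <= 0.5))
      return(list(weights = w, labels = labels, counts = counts,
                  iterations = it, converged = TRUE))
    w <- w + lr * r2 * log(targets_vox / pmax(counts, 0.25))
    w <- w - mean(w)
  }
  list(weights = w, labels = labels,
       counts = tabulate(labels[labels > 0L], nbins = n),
       iterations = max_iter, converged = FALSE)
}

#' Render one frame of a synthetic embryo as a labeled volume
#'
#' Cells are convex regions of a power diagram (weighted Voronoi partition)
#' over per-cell seed points inside the ellipsoidal eggshell; weights are
#' solved by fixed-point iteration so each cell's voxel volume matches its
#' programmed volume fraction (5% relative tolerance for cells >= 500
#' voxels).  Voxel labels are the `label` ids of the lineage tree.
#'
#' @inheritParams synthesize_features
#' @param frame 0-based frame index to render.
#' @return A [labeled_volume()]; attribute `cell_names` maps label ids to
#'   cell names, `converged` reports the volume fit.
#' @export
render_labels <- function(tree, program, spec, frame, seed = 1L) {
  rendered <- render_embryo(tree, program, spec, seed, frames = frame)
  rendered$volumes[[1]]
}

#' Render a full synthetic embryo
#'
#' Renders a sequence of frames with warm-started power-diagram weights
#' (cell geometry changes slowly, so later frames converge in a few
#' iterations).
#'
#' @inheritParams render_labels
#' @param frames 0-based frame indices (default: every frame).
#' @param tol relative volume tolerance for cells >= 500 voxels.
#' @param max_iter weight-iteration cap per frame.
#' @return List with `volumes` (list of [labeled_volume()]), `target_vox`
#'   (matrix of programmed voxel counts) and `seeds`.
#' @export
render_embryo <- function(tree, program, spec, seed = 1L, frames = NULL,
                          tol = 0.05, max_iter = 60) {
  if (is.null(frames)) frames <- 0:(spec$n_frames - 1L)
  fr <- target_fractions(tree, program, spec)
  pos <- seed_positions(tree, program, spec, seed)
  n_in <- interior_voxels(spec)
  dt <- spec_dt_min(spec)
  w_by_cell <- stats::setNames(rep(0, nrow(tree)), tree$name)
  volumes <- vector("list", length(frames))
  tv <- matrix(0, nrow = length(frames), ncol = nrow(tree),
               dimnames = list(NULL, tree$name))
  prev_live <- character(0)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    live <- tree$name[fr[f + 1L, ] > 0]
    if (length(live) == 0) stop(sprintf("frame %d: no live cells", f))
    # daughters inherit the mother's weight as a warm start
    for (nm in setdiff(live, prev_live)) {
      p <- tree$parent[match(nm, tree$name)]
      if (!is.na(p)) w_by_cell[nm] <- w_by_cell[p]
    }
    targets <- fr[f + 1L, live] / sum(fr[f + 1L, live]) * n_in
    sol <- solve_power_weights(spec, pos[live, , drop = FALSE], targets,
                               w0 = unname(w_by_cell[live]),
                               tol = tol, max_iter = max_iter)
    if (!sol$converged)   # retry cold with a damped step
      sol <- solve_power_weights(spec, pos[live, , drop = FALSE], targets,
                                 tol = tol, max_iter = 3L * max_iter,
                                 lr = 0.25)
    if (!sol$converged && any(sol$counts == 0))
      stop(sprintf("frame %d: could not place %d cells in the eggshell",
                   f, sum(sol$counts == 0)))
    w_by_cell[live] <- sol$weights
    lab_ids <- tree$label[match(live, tree$name)]
    arr <- array(c(0L, lab_ids)[sol$labels + 1L], dim = spec$dims)
    lv <- labeled_volume(arr, spec$spacing, frame = f, time_min = f * dt)
    attr(lv, "cell_names") <- stats::setNames(live, lab_ids)
    attr(lv, "converged") <- sol$converged
    volumes[[fi]] <- lv
    tv[fi, live] <- targets
    prev_live <- live
  }
  list(volumes = volumes, target_vox = tv, seeds = pos, frames = frames)
}

#' Nucleus point clouds from a synthetic embryo
#'
#' One point per live cell and frame (the cell's seed position, standing in
#' for the nucleus centroid), optionally passed through a rigid rotation
#' about the embryo center and isotropic Gaussian jitter.  True cell names
#' ride along as ground truth.
#'
#' @inheritParams synthesize_features
#' @param rotation rotation angles (degrees) about the x, y, z axes through
#'   the embryo center, applied in that order.
#' @param jitter_sd isotropic Gaussian jitter sd (um).
#' @param frames 0-based frame indices (default all).
#' @param centroids optional cell-position matrix (rows named by cell);
#'   defaults to [seed_positions()] under `layout_seed`.
#' @param layout_seed seed for the cell layout (defaults to `seed`);
#'   keeping it fixed while varying `seed` re-jitters the same embryo.
#' @return List of [nucleus_set()] objects, one per frame.
#' @export
emit_nucleus_sets <- function(tree, spec, rotation = c(0, 0, 0),
                              jitter_sd = 0, seed = 1L, frames = NULL,
                              program = NULL, centroids = NULL,
                              layout_seed = seed) {
  stopifnot(jitter_sd >= 0)
  if (is.null(centroids)) {
    if (is.null(program)) stop("supply `centroids` or `program`")
    centroids <- seed_positions(tree, program, spec, layout_seed)
  }
  if (is.null(frames)) frames <- 0:(spec$n_frames - 1L)
  ctr <- spec_center(spec)
  R <- rotation_matrix(rotation[1], rotation[2], rotation[3])
  with_seed(seed + 41L, {
    lapply(frames, function(f) {
      live <- tree$name[tree$birth_frame <= f &
                          vapply(tree$name, function(nm)
                            cell_last_frame(tree, nm), 0L) >= f]
      pts <- centroids[live, , drop = FALSE]
      pts <- sweep(pts, 2, ctr) %*% t(R)
      pts <- sweep(pts, 2, ctr, "+")
      if (jitter_sd > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_sd),
                            ncol = 3)
      nucleus_set(pts, names = live, frame = f)
    })
  })
}

rotation_matrix <- function(ax_deg, ay_deg, az_deg) {
  a <- ax_deg * pi / 180; b <- ay_deg * pi / 180; c <- az_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Simulate a cohort of synthetic embryos
#'
#' Generates `n_embryos` independent embryos from one program: per-embryo
#' seeds derived from the master seed, developmental rates drawn uniformly
#' from the spec's rate band, jittered lineages, and ground-truth feature
#' tracks with noise.  With `render = TRUE` each embryo is additionally
#' rasterized to labeled volumes.
#'
#' @param n_embryos cohort size.
#' @param program a [lineage_program()].
#' @param spec an [embryo_spec()] template (its `rate_factor` is replaced
#'   per embryo).
#' @param master_seed master seed; all embryo seeds derive from it.
#' @param render rasterize labeled volumes per embryo (slower).  When
#'   rendered, `features` and `contacts` are measured from the label
#'   images by [extract_features()] (with boundary layers) and
#'   [extract_contacts()], and the noise-free synthesized tracks move to
#'   `features_true`.
#' @param frames frames to rasterize when `render = TRUE`.
#' @param ... passed to [synthesize_features()] (noise options).
#' @return An `embryo_cohort`: list of embryos, each with `id`, `spec`,
#'   `tree`, `features`, `truth`, and optionally `volumes`, `contacts`,
#'   `features_true`.
#' @export
simulate_cohort <- function(n_embryos, program = celegans_program(),
                            spec = embryo_spec(), master_seed = 1L,
                            render = FALSE, frames = NULL, ...) {
  seeds <- derive_seeds(master_seed, n_embryos)
  rates <- with_seed(master_seed + 1L,
                     stats::runif(n_embryos, spec$rate_band[1],
                                  spec$rate_band[2]))
  cohort <- lapply(seq_len(n_embryos), function(i) {
    sp <- spec
    sp$rate_factor <- rates[i]
    tree <- generate_lineage(program, sp, seeds[i])
    syn <- synthesize_features(tree, program, sp, seeds[i], ...)
    emb <- list(id = i, seed = seeds[i], spec = sp, tree = tree,
                features = syn$features, truth = syn$truth)
    if (render) {
      rend <- render_embryo(tree, program, sp, seeds[i], frames = frames)
      emb$volumes <- rend$volumes
      emb$features_true <- emb$features
      emb$features <- extract_features(rend$volumes, tree, layer = TRUE)
      emb$contacts <- extract_contacts(rend$volumes, tree)
    }
    emb
  })
  structure(cohort, class = "embryo_cohort", program = program)
}
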