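make_cloud <- function(n, seed) {
  set.seed(seed)
  cbind(rnorm(n, sd = 8), rnorm(n, sd = 4), rnorm(n, sd = 2))
}

test_that("PCA alignment is invariant to rigid rotation", {
  p <- make_cloud(30, 1)
  a <- pca_align(nucleus_set(p))
  R <- morphodyn:::rotation_matrix(25, 40, -15)
  b <- pca_align(nucleus_set(p %*% t(R)))
  # coordinates agree up to per-axis sign
  for (j in 1:3)
    expect_true(max(abs(a$points[, j] - b$points[, j])) < 1e-8 ||
                  max(abs(a$points[, j] + b$points[, j])) < 1e-8)
  expect_equal(colMeans(a$points), c(0, 0, 0))
  v <- apply(a$points, 2, var)
  expect_true(all(diff(v) <= 1e-9))
  expect_error(pca_align(nucleus_set(matrix(rnorm(6), 2, 3))), "degenerate")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(pca_align(nucleus_set(line)), "collinear")
})

test_that("candidate transform counts follow the sweep definition", {
  expect_length(candidate_transforms(swing_deg = 0), 180L)
  expect_length(candidate_transforms(swing_deg = 4, swing_step = 2), 4500L)
  has_identity <- any(vapply(candidate_transforms(swing_deg = 2),
                             function(R) max(abs(R - diag(3))) < 1e-12,
                             TRUE))
  expect_true(has_identity)
})

test_that("per-axis scaling matches the reference and round-trips", {
  p <- make_cloud(25, 2)
  ref <- pca_align(nucleus_set(p))
  tgt <- nucleus_set(ref$points * 2, frame = 0L)
  sc <- scale_to_reference(tgt, ref)
  expect_equal(attr(sc, "scales"), c(0.5, 0.5, 0.5),
               ignore_attr = TRUE)
  same <- scale_to_reference(ref, ref)
  expect_equal(attr(same, "scales"), c(1, 1, 1), ignore_attr = TRUE)
  stretched <- nucleus_set(sweep(ref$points, 2, c(2, 1, 1), "*"))
  back <- scale_to_reference(stretched, ref)
  expect_equal(back$points, ref$points, tolerance = 1e-12)
})

test_that("Hungarian matching equals exhaustive permutation search", {
  for (n in 3:6) for (seed in 1:3) {
    set.seed(100 * n + seed)
    a <- nucleus_set(matrix(runif(3 * n, 0, 10), n, 3))
    b <- nucleus_set(matrix(runif(3 * n, 0, 10), n, 3))
    got <- match_hungarian(a, b)
    D <- morphodyn:::euclidean_cost(a$points, b$points)
    want <- bf_assignment(D)
    expect_equal(got$cost, want$cost, tolerance = 1e-12)
  }
  p <- make_cloud(8, 3)
  s <- nucleus_set(p)
  self <- match_hungarian(s, s)
  expect_equal(self$assignment, 1:8)
  expect_equal(self$cost, 0)
  expect_error(match_hungarian(s, nucleus_set(p[1:5, ])), "mismatch")
})

test_that("annotation recovers names of rotated and jittered clouds", {
  pr <- tiny_program(jitter_sd = 0)
  sp <- tiny_spec()
  tr <- generate_lineage(pr, sp, 17)
  ref <- emit_nucleus_sets(tr, sp, seed = 17, program = pr, frames = 50)[[1]]
  tgt <- emit_nucleus_sets(tr, sp, rotation = c(34, 0, 0), seed = 17,
                           program = pr, frames = 50)[[1]]
  ann <- annotate_nuclei(nucleus_set(tgt$points), list(ref), swing_deg = 0)
  expect_equal(ann$set$names, tgt$names)
  expect_lt(ann$cost, 1e-6)
  # an exact-copy reference beats a distorted one
  distorted <- nucleus_set(ref$points +
                             matrix(rnorm(length(ref$points), 0, 2),
                                    ncol = 3),
                           names = ref$names, frame = ref$frame)
  ann2 <- annotate_nuclei(nucleus_set(ref$points), list(distorted, ref),
                          swing_deg = 0)
  expect_equal(ann2$reference, 2L)
  expect_lt(ann2$cost, 1e-6)
})

test_that("name-recovery accuracy does not increase with jitter", {
  pr <- tiny_program(jitter_sd = 0)
  sp <- tiny_spec()
  tr <- generate_lineage(pr, sp, 17)
  ref <- emit_nucleus_sets(tr, sp, seed = 17, program = pr, frames = 50)[[1]]
  mind <- min(dist(ref$points))
  acc_at <- function(sd_frac) {
    mean(vapply(1:8, function(s) {
      tgt <- emit_nucleus_sets(tr, sp, rotation = c(72, 2, -3),
                               jitter_sd = sd_frac * mind, seed = 300 + s,
                               layout_seed = 17, program = pr,
                               frames = 50)[[1]]
      a <- annotate_nuclei(nucleus_set(tgt$points), list(ref),
                           swing_deg = 0)
      mean(a$set$names == tgt$names)
    }, 0))
  }
  accs <- vapply(c(0.02, 0.15, 0.45), acc_at, 0)
  expect_true(all(diff(accs) <= 1e-9))
  expect_equal(accs[1], 1)
})

test_that("backward tracing handles clean, corrupted and single frames", {
  pr <- tiny_program(jitter_sd = 0)
  sp <- tiny_spec()
  tr <- generate_lineage(pr, sp, 11)
  sets <- emit_nucleus_sets(tr, sp, seed = 11, program = pr,
                            frames = seq(8, 48, by = 8))
  tracked <- tracking_from_tree(tr, sets)
  truth <- lapply(sets, function(s) s$names)
  T_ <- length(tracked)
  res <- trace_back(tracked, tr, function(f) truth[[f]])
  expect_equal(res$restarts, 0L)
  expect_equal(res$final_frame, T_)
  for (t in seq_len(T_)) expect_equal(res$names[[t]], truth[[t]])
  # corrupt the final frame: swap two non-sister cells born in the movie
  nm <- truth[[T_]]
  par <- tr$parent[match(nm, tr$name)]
  born <- tr$birth_frame[match(nm, tr$name)] > 8
  cand <- which(!is.na(par) & born)
  i <- cand[1]
  j <- cand[which(par[cand] != par[i])[1]]
  bad <- nm
  bad[c(i, j)] <- bad[c(j, i)]
  res2 <- trace_back(tracked, tr,
                     function(f) if (f == T_) bad else truth[[f]])
  expect_equal(res2$restarts, 1L)
  expect_equal(res2$final_frame, T_ - 1L)
  # single-frame input passes names through
  res3 <- trace_back(tracked[T_], tr, function(f) truth[[T_]])
  expect_equal(res3$names[[1]], truth[[T_]])
  expect_equal(res3$restarts, 0L)
})
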