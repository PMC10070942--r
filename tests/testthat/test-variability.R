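test_that("the pairwise variability metric obeys its analytic identities", {
  x <- runif(50, 0.5, 2)
  expect_identical(variability_v(x, x), 0)
  expect_equal(variability_v(rep(1, 50), rep(3, 50)), 0.5)
  expect_equal(variability_v(x, 3 * x), 0.5)
  # symmetric, bounded in [0, 1)
  for (s in 1:20) {
    set.seed(s)
    a <- rexp(50) + 1e-3
    b <- rexp(50) + 1e-3
    v <- variability_v(a, b)
    expect_identical(v, variability_v(b, a))
    expect_gte(v, 0)
    expect_lt(v, 1)
  }
  # approaches 1 for arbitrarily different dynamics
  expect_gt(variability_v(rep(1, 50), rep(1e8, 50)), 0.9999)
  expect_error(variability_v(1:5, 1:4), "equal length")
  expect_error(variability_v(c(1, -1, 1), c(1, 1, 1)), "positive")
})

test_that("the volume-variability metric Mv matches direct evaluation", {
  expect_identical(mv(100, 100), 0)
  expect_equal(mv(3, 1), 0.5)
  expect_equal(mv(1, 3), 0.5)
  expect_gt(mv(1, 1e9), 0.999)
  expect_error(mv(0, 1), "positive")
})

test_that("integral RMSD normalizes by the pooled mean and rescales", {
  t50 <- seq(0, 25, length.out = 50)
  a <- data.frame(cell = "X", norm_time = t50, volume = rep(2, 50))
  b <- data.frame(cell = "X", norm_time = t50, volume = rep(4, 50))
  r <- integral_rmsd(a, b, features = "volume")
  expect_equal(r$value, 2 / 3)
  expect_equal(integral_rmsd(a, a, features = "volume")$value, 0)
  # invariance to common positive rescaling
  a2 <- a; a2$volume <- a2$volume * 17.3
  b2 <- b; b2$volume <- b2$volume * 17.3
  expect_equal(integral_rmsd(a2, b2, features = "volume")$value, r$value)
  expect_error(integral_rmsd(a, b, features = "sphericity"), "missing")
})

test_that("well-separated cell programs are fully distinguishable", {
  co <- simulate_cohort(4, tiny_program(), tiny_spec(), master_seed = 64,
                        noise_sd = 0.002)
  norm <- lapply(co, function(e) normalize_embryo_time(e$features, e$tree))
  d <- distinguishability(norm)
  expect_equal(d$mean_fraction, 1)
  expect_equal(d$pct_types_above, 100)
  # two identical embryos: intra distance 0, inter positive
  e1 <- norm[[1]]
  d2 <- distinguishability(list(e1, e1, e1))
  expect_equal(d2$mean_fraction, 1)
})

test_that("the exported distance matrix is symmetric with zero diagonal", {
  co <- simulate_cohort(3, tiny_program(), tiny_spec(), master_seed = 2)
  norm <- lapply(co, function(e) normalize_embryo_time(e$features, e$tree))
  ex <- distance_matrix_export(norm)
  D <- ex$matrix
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_equal(nrow(ex$labels), nrow(D))
  expect_gte(ex$triangle_violations, 0)
  # permuting embryos permutes rows/columns consistently
  ex2 <- distance_matrix_export(norm[c(2, 1, 3)])
  key <- function(l) paste(l$cell, c(2, 1, 3)[l$embryo])
  m <- match(key(ex$labels), paste(ex2$labels$cell, ex2$labels$embryo))
  expect_equal(ex2$matrix[m, m], D, tolerance = 1e-12)
})

test_that("lineage-specific noise produces lineage-specific variability", {
  co <- simulate_cohort(10, tiny_program(), tiny_spec(), master_seed = 5,
                        noise_sd = 0.01,
                        lineage_noise = c(AB = 0.03, P = 0.01))
  norm <- lapply(co, function(e) normalize_embryo_time(e$features, e$tree))
  pv <- pairwise_variability(norm, "volume")
  vb <- variability_by_group(pv, co[[1]]$tree, "lineage")
  med <- function(g) vb$summary$median[vb$summary$group == g]
  expect_gt(med("AB"), 2 * med("P"))
  row <- vb$tests[vb$tests$group_a == "AB" & vb$tests$group_b == "P", ]
  expect_lt(row$p_value, 0.01)
  expect_true(row$significant)
  # group medians do not depend on embryo labels
  pv2 <- pv
  pv2$embryo_a <- pv$embryo_b
  pv2$embryo_b <- pv$embryo_a
  vb2 <- variability_by_group(pv2, co[[1]]$tree, "lineage")
  expect_equal(vb2$summary$median, vb$summary$median)
})

test_that("within-cycle noise growth shows up as a time-resolved increase", {
  co <- simulate_cohort(12, tiny_program(), tiny_spec(), master_seed = 21,
                        noise_sd = 0.01, time_noise_slope = 4)
  norm <- lapply(co, function(e) normalize_embryo_time(e$features, e$tree))
  tc <- variability_time_course(norm, "volume")
  expect_true(tc$significant)
  first <- tc$mean_course$v_t[which.min(tc$mean_course$norm_time)]
  last <- tc$mean_course$v_t[which.max(tc$mean_course$norm_time)]
  expect_gt(last, first)
})

test_that("coupled noise raises the contact correlation above mock pairs", {
  groups <- list(c("ABa", "ABp"), c("EMS", "P2"))
  co <- simulate_cohort(14, tiny_program(), tiny_spec(), master_seed = 83,
                        noise_sd = 0.01, noise_groups = groups,
                        group_sd = 0.6)
  norm <- lapply(co, function(e) normalize_embryo_time(e$features, e$tree))
  pv <- pairwise_variability(norm, "volume")
  contact_pairs <- data.frame(cell_a = c("ABa", "EMS"),
                              cell_b = c("ABp", "P2"))
  cd <- contact_dependence(pv, contact_pairs, co[[1]]$tree, seed = 4)
  expect_gt(cd$mean_contact_r, 0.3)
  expect_gt(cd$mean_contact_r, cd$mean_mock_r + 0.2)
  expect_error(contact_dependence(pv, data.frame(cell_a = "ABa",
                                                 cell_b = "ABa"),
                                  co[[1]]$tree),
               "cannot contact itself")
})
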