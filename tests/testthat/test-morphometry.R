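test_that("cell volume is voxel count times physical voxel volume", {
  vol <- block_volume(c(12, 12, 12),
                      list(list(label = 1L, lo = c(1, 1, 1),
                                hi = c(10, 10, 10))))
  expect_identical(cell_volume(vol, 1L), 1000 * 0.125)
  single <- block_volume(c(5, 5, 5),
                         list(list(label = 3L, lo = c(2, 2, 2),
                                   hi = c(2, 2, 2))),
                         spacing = c(0.4, 0.5, 0.6))
  expect_equal(cell_volume(single, 3L), 0.4 * 0.5 * 0.6)
  expect_error(cell_volume(vol, 9L), "absent")
})

test_that("sphericity matches closed forms and limits", {
  r <- 3.7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  s <- 2.5
  expect_equal(sphericity(s^3, 6 * s^2), (pi / 6)^(1 / 3))
  expect_lt(sphericity(10, 1e9), 1e-4)
  expect_error(sphericity(-1, 10), "positive")
  expect_error(sphericity(10, 0), "positive")
})

test_that("surface area of a digitized ball is close to the analytic area", {
  r <- 20
  vol <- ball_volume(r)
  a <- cell_surface_area(vol, 1L)
  expect_lt(abs(a - 4 * pi * r^2) / (4 * pi * r^2), 0.03)
  sph <- sphericity(cell_volume(vol, 1L), a)
  expect_gt(sph, 0.95)
  expect_lt(sph, 1.02)
})

test_that("surface area stays finite for tiny cells and scales exactly", {
  single <- block_volume(c(5, 5, 5),
                         list(list(label = 1L, lo = c(3, 3, 3),
                                   hi = c(3, 3, 3))))
  expect_gt(cell_surface_area(single, 1L), 0)
  # scaling covariance: spacing x c => areas x c^2, volumes x c^3
  vol1 <- ball_volume(10, spacing = c(1, 1, 1))
  vol2 <- ball_volume(10, spacing = c(3, 3, 3))
  expect_equal(cell_surface_area(vol2, 1L), 9 * cell_surface_area(vol1, 1L))
  expect_equal(cell_volume(vol2, 1L), 27 * cell_volume(vol1, 1L))
})

test_that("cutting a cube in two adds about twice the cut-plane area", {
  whole <- block_volume(c(20, 20, 20),
                        list(list(label = 1L, lo = c(4, 4, 4),
                                  hi = c(15, 15, 15))),
                        spacing = c(1, 1, 1))
  halves <- block_volume(c(20, 20, 20),
                         list(list(label = 1L, lo = c(4, 4, 4),
                                   hi = c(9, 15, 15)),
                              list(label = 2L, lo = c(10, 4, 4),
                                   hi = c(15, 15, 15))),
                         spacing = c(1, 1, 1))
  # raw (unsmoothed) meshes keep the flat cut faces exact
  a_whole <- cell_surface_area(whole, 1L, smooth = FALSE)
  a_sum <- cell_surface_area(halves, 1L, smooth = FALSE) +
    cell_surface_area(halves, 2L, smooth = FALSE)
  cut <- 12 * 12
  expect_lt(abs((a_sum - a_whole) - 2 * cut) / (2 * cut), 0.15)
})

test_that("contact areas follow face-counting semantics", {
  two <- block_volume(c(24, 12, 12),
                      list(list(label = 1L, lo = c(1, 1, 1),
                                hi = c(10, 10, 10)),
                           list(label = 2L, lo = c(11, 1, 1),
                                hi = c(20, 10, 10))))
  tree <- stub_tree(c("A", "B"))
  ct <- extract_contacts(list(two), tree)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$area, 100 * 0.25)   # 10x10 faces of 0.5 um voxels
  gap <- block_volume(c(24, 12, 12),
                      list(list(label = 1L, lo = c(1, 1, 1),
                                hi = c(10, 10, 10)),
                           list(label = 2L, lo = c(12, 1, 1),
                                hi = c(20, 10, 10))))
  expect_equal(nrow(extract_contacts(list(gap), tree)), 0L)
})

test_that("contact extraction equals brute-force adjacency on small grids", {
  for (seed in 1:3) {
    set.seed(seed)
    arr <- array(sample(0:4, 18^3, replace = TRUE), dim = c(18, 18, 18))
    vol <- labeled_volume(arr, c(0.5, 0.4, 0.7))
    tree <- stub_tree(c("c1", "c2", "c3", "c4"))
    got <- extract_contacts(list(vol), tree)
    want <- bf_contacts(vol)
    lab_of <- function(nm) tree$label[match(nm, tree$name)]
    got_key <- paste(pmin(lab_of(got$cell_a), lab_of(got$cell_b)),
                     pmax(lab_of(got$cell_a), lab_of(got$cell_b)))
    expect_setequal(got_key, paste(want$a, want$b))
    expect_equal(got$area[order(got_key)],
                 want$area[order(paste(want$a, want$b))])
  }
})

test_that("per-frame cell volumes partition the embryonic volume exactly", {
  pr <- tiny_program(jitter_sd = 0)
  sp <- tiny_spec(n_frames = 30L)
  tr <- generate_lineage(pr, sp, 3)
  rend <- render_embryo(tr, pr, sp, seed = 3, frames = c(0, 20, 29))
  fx <- extract_features(rend$volumes, tr)
  total <- vapply(rend$volumes, function(lv) sum(lv$labels > 0L) *
                    prod(lv$spacing), 0)
  for (i in seq_along(rend$volumes)) {
    f <- rend$volumes[[i]]$frame
    expect_equal(sum(fx$volume[fx$frame == f]), total[i])
  }
  expect_equal(length(unique(total)), 1L)   # fixed eggshell
})

test_that("feature tracks follow the division bookkeeping", {
  pr <- tiny_program(jitter_sd = 0)
  sp <- tiny_spec(n_frames = 24L)
  tr <- generate_lineage(pr, sp, 3)
  k <- tr$division_frame[match("AB", tr$name)]
  rend <- render_embryo(tr, pr, sp, seed = 3, frames = (k - 2):(k + 1))
  fx <- extract_features(rend$volumes, tr)
  expect_equal(max(fx$frame[fx$cell == "AB"]), k - 1L)
  expect_equal(min(fx$frame[fx$cell == "ABa"]), k)
  expect_equal(min(fx$frame[fx$cell == "ABp"]), k)
  # unannotated label errors
  bad <- rend$volumes[[1]]
  bad$labels[bad$labels > 0L][1] <- 99L
  expect_error(extract_features(list(bad), tr), "unannotated")
})

test_that("adjacent-frame volume deviation matches direct evaluation", {
  expect_equal(adjacent_frame_volume_deviation(c(5, 5, 5, 5)), 0)
  expect_equal(adjacent_frame_volume_deviation(c(100, 110)), 10 / 105)
  expect_equal(adjacent_frame_volume_deviation(c(1, 2, 4, 8)), 2 / 3)
  expect_true(is.na(adjacent_frame_volume_deviation(7)))
})

test_that("boundary layer counts match closed-form block values", {
  vol <- block_volume(c(14, 14, 14),
                      list(list(label = 1L, lo = c(2, 2, 2),
                                hi = c(11, 11, 11)),
                           list(label = 2L, lo = c(13, 13, 13),
                                hi = c(13, 13, 13)),
                           list(label = 3L, lo = c(2, 12, 2),
                                hi = c(4, 14, 4))))
  expect_equal(boundary_layer_count(vol, 1L), 1000L - 512L)
  expect_equal(boundary_layer_count(vol, 2L), 1L)
  expect_equal(boundary_layer_count(vol, 3L), 27L - 1L)
  expect_error(boundary_layer_count(vol, 7L), "absent")
})
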