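# stub cohort: n embryos in which the pair A|B touches in the first k
stub_cohort <- function(n_contact, n_total, cells = c("A", "B")) {
  lapply(seq_len(n_total), function(i) {
    contacts <- if (i <= n_contact)
      stub_contacts(list(pair = cells, frames = 0:9, area = 20))
    else stub_contacts()
    list(id = i, tree = stub_tree(cells), contacts = contacts)
  })
}

test_that("contact reproducibility is the formed-over-assessable fraction", {
  expect_equal(contact_reproducibility(c("A", "B"), stub_cohort(52, 52)), 1)
  expect_equal(contact_reproducibility(c("A", "B"), stub_cohort(13, 52)),
               0.25)
  expect_equal(contact_reproducibility(c("A", "B"), stub_cohort(0, 10)), 0)
  # embryos where a cell does not complete its cycle leave the denominator
  co <- stub_cohort(2, 2)
  co[[3]] <- list(id = 3, tree = stub_tree(c("A", "B"), complete = FALSE),
                  contacts = stub_contacts())
  expect_equal(contact_reproducibility(c("A", "B"), co), 1)
  none <- list(list(id = 1, tree = stub_tree(c("A", "B"),
                                             complete = FALSE),
                    contacts = stub_contacts()))
  expect_true(is.na(contact_reproducibility(c("A", "B"), none)))
})

test_that("integral area is a plain frame sum with a per-minute variant", {
  tr <- stub_contacts(list(pair = c("A", "B"), frames = 0:19, area = 10))
  expect_equal(integral_area(tr), 200)
  expect_equal(integral_area(stub_contacts()), 0)
  expect_equal(integral_area(tr, per_minute = TRUE, frame_interval = 30),
               100)
  # halving the frame interval with the same geometry doubles the sum
  tr2 <- stub_contacts(list(pair = c("A", "B"), frames = 0:39, area = 10))
  expect_equal(integral_area(tr2), 2 * integral_area(tr))
})

test_that("timing-variable contacts are told apart from arrangement", {
  base <- list(id = 1, tree = stub_tree(c("A", "B"), birth = c(0L, 0L),
                                        division = c(20L, 40L)),
               contacts = stub_contacts(list(pair = c("A", "B"),
                                             frames = 15:19, area = 5)))
  # timing loss: in embryo 2, B is born just after A divides
  timing <- list(id = 2,
                 tree = stub_tree(c("A", "B"), birth = c(0L, 21L),
                                  division = c(20L, 40L)),
                 contacts = stub_contacts())
  expect_true(detect_timing_variability(c("A", "B"), list(base, timing),
                                        max_shift = 2L))
  # arrangement loss: co-alive in embryo 3 yet never touching
  arrange <- list(id = 3, tree = stub_tree(c("A", "B"), birth = c(0L, 0L),
                                           division = c(20L, 40L)),
                  contacts = stub_contacts())
  expect_false(detect_timing_variability(c("A", "B"), list(base, arrange)))
  # a gap wider than the allowed shift is not timing-explainable
  far <- list(id = 4, tree = stub_tree(c("A", "B"), birth = c(0L, 30L),
                                       division = c(20L, 40L)),
              contacts = stub_contacts())
  expect_false(detect_timing_variability(c("A", "B"), list(base, far),
                                         max_shift = 2L))
  # fully reproducible pairs are out of scope
  expect_true(is.na(detect_timing_variability(c("A", "B"), list(base))))
})

test_that("contact categories partition counts and areas", {
  co <- stub_cohort(3, 3)
  s <- summarize_contacts(co)
  cc <- categorize_contacts(s)
  expect_equal(cc$proportions$pct_count[3], 100)
  expect_equal(cc$proportions$pct_area[3], 100)
  expect_equal(sum(cc$proportions$pct_count), 100)
  expect_equal(sum(cc$proportions$pct_area), 100)
  # mixed cohort keeps both shares summing to 100
  mixed <- lapply(1:4, function(i) {
    rows <- list(list(pair = c("A", "B"), frames = 0:30, area = 40))
    if (i <= 2)
      rows[[2]] <- list(pair = c("B", "C"), frames = 10L, area = 1)
    list(id = i, tree = stub_tree(c("A", "B", "C")),
         contacts = do.call(stub_contacts, rows))
  })
  sm <- summarize_contacts(mixed)
  cm <- categorize_contacts(sm)
  expect_equal(sum(cm$proportions$pct_count), 100)
  expect_equal(sum(cm$proportions$pct_area), 100)
  expect_gt(cm$biphasic$pct_perfect[1], 99)   # big contact above threshold
  expect_true(all(sm$reproducibility >= 0 & sm$reproducibility <= 1))
})

test_that("neighbor reproducibility matches the set-overlap conventions", {
  same <- replicate(50, c("a", "b", "c"), simplify = FALSE)
  othr <- replicate(50, c("d", "e"), simplify = FALSE)
  shifted <- replicate(50, c("a", "b", "d"), simplify = FALSE)
  e1 <- neighbor_embryo("X", same, c("a", "b", "c", "d", "e"))
  e2 <- neighbor_embryo("X", same, c("a", "b", "c", "d", "e"))
  e3 <- neighbor_embryo("X", othr, c("a", "b", "c", "d", "e"))
  e4 <- neighbor_embryo("X", shifted, c("a", "b", "c", "d", "e"))
  expect_equal(neighbor_reproducibility("X", e1, e2), 1)
  expect_equal(neighbor_reproducibility("X", e1, e3), 0)
  expect_equal(neighbor_reproducibility("X", e1, e4), 0.5)   # 2 / 4
  expect_equal(neighbor_reproducibility("X", e1, e4, agreement = "min"),
               2 / 3)
  # symmetric in the two embryos
  expect_equal(neighbor_reproducibility("X", e4, e1), 0.5)
})

test_that("the 5% surface-area filter removes weak contacts", {
  frames <- 0:49
  feat <- data.frame(cell = "X", frame = frames, time_min = frames / 2,
                     volume = 1000, surface_area = 100, sphericity = 0.85,
                     cx = 0, cy = 0, cz = 0)
  weak <- stub_contacts(list(pair = c("X", "a"), frames = frames,
                             area = 3))   # below 5 % of 100
  strong <- stub_contacts(list(pair = c("X", "a"), frames = frames,
                               area = 50))
  tree <- stub_tree(c("X", "a"), division = 50L, n_frames = 60L)
  e_weak <- list(id = 1, tree = tree, features = feat, contacts = weak)
  e_strong <- list(id = 2, tree = tree, features = feat, contacts = strong)
  expect_equal(neighbor_reproducibility("X", e_weak, e_strong), 0)
  expect_equal(neighbor_reproducibility("X", e_strong, e_strong), 1)
})

test_that("contact duration fraction is capped and exact", {
  tr <- stub_contacts(list(pair = c("A", "B"), frames = 0:49, area = 1))
  expect_equal(contact_duration_fraction(tr, 50, 60), 1)
  expect_equal(contact_duration_fraction(5, 50, 80), 0.1)
  expect_equal(contact_duration_fraction(0, 50, 50), 0)
})

test_that("conservation summaries count cells over thresholds", {
  scores <- data.frame(cell = c("a", "b", "c", "d"),
                       generation = 6L,
                       score = c(0.9, 0.7, 0.85, 0.95))
  out <- conservation_summary(scores)
  expect_equal(out$pct_cells[out$threshold == 0.8], 75)
  expect_equal(out$pct_cells[out$threshold == 0.5], 100)
  all1 <- data.frame(cell = letters[1:5], generation = rep(5:6, len = 5),
                     score = 1)
  expect_true(all(conservation_summary(all1)$pct_cells == 100))
})

test_that("rendered embryos give consistent contact pipelines end to end", {
  pr <- tiny_program(jitter_sd = 1)
  sp <- tiny_spec(n_frames = 40L)
  co <- simulate_cohort(3, pr, sp, master_seed = 8, render = TRUE,
                        frames = seq(0, 38, by = 2))
  s <- summarize_contacts(co)
  expect_true(all(s$reproducibility >= 0 & s$reproducibility <= 1,
                  na.rm = TRUE))
  expect_true(all(s$integral_area >= 0))
  assessable <- s[!is.na(s$reproducibility), ]
  big <- assessable[which.max(assessable$integral_area), ]
  expect_equal(big$reproducibility, 1)   # sister contact always forms
})
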