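test_that("fragment merging places the seam at the overlap midpoint", {
  st <- uniform_stream(32, 1200)
  single <- merge_fragments(list(st))
  expect_equal(single$t, st$t)
  fr <- inject_fragmentation(st, 500, overlap_s = 10)
  merged <- merge_fragments(fr)
  expect_equal(range(merged$t), c(0, 1200 - 1 / 32))
  expect_false(any(duplicated(merged$t)))
  expect_equal(max(merged$t[merged$frag == 1]), 495 - 1 / 32)
  expect_equal(min(merged$t[merged$frag == 2]), 495)
})

test_that("three-or-more fragments merge pairwise without duplicates", {
  st <- uniform_stream(25, 600)
  for (seed in 1:5) {
    set.seed(seed)
    ev <- sort(runif(2, 80, 520))
    if (diff(ev) < 20) next
    fr <- inject_fragmentation(st, ev, overlap_s = 10)
    merged <- merge_fragments(fr)
    expect_equal(range(merged$t), range(st$t))
    expect_false(any(duplicated(merged$t)))
  }
})

test_that("a gap between fragments raises a reconstruction error", {
  st <- uniform_stream(10, 100)
  a <- stream_slice(st, 0, 40)
  b <- stream_slice(st, 60, 100)
  expect_error(merge_fragments(list(a, b)), "gap")
})

test_that("edge trimming yields the effective segment", {
  st <- uniform_stream(10, 1200)
  tr <- trim_edges(st, 30)
  expect_equal(length(tr$t), 10 * 1140)
  expect_equal(min(tr$t), 0)
  expect_identical(trim_edges(st, 0), st)
  expect_error(trim_edges(uniform_stream(10, 59), 30), "too short")
})

test_that("expected grids are rate-exact", {
  expect_equal(build_expected_grid(128, 1140)$n_expected, 145920L)
  expect_equal(build_expected_grid(1, 1140)$n_expected, 1140L)
  expect_equal(build_expected_grid(500, 1140)$n_expected, 570000L)
  g <- build_expected_grid(4, 10)
  expect_equal(diff(g$times), rep(0.25, 39))
  expect_error(build_expected_grid(0.3, 7), "not an integer")
  expect_error(build_expected_grid(-1, 10), "positive")
})

test_that("grid alignment is the identity on already-gridded samples", {
  st <- uniform_stream(20, 30)
  rec <- align_to_grid(st, build_expected_grid(20, 30))
  expect_equal(rec$values[, 1], st$x[, 1])
  expect_false(any(rec$filled_mask))
})

test_that("alignment interpolates a missing interior sample exactly on linear data", {
  t <- (0:99) / 10
  x <- 2 * t + 1
  keep <- -51
  st <- sensor_stream("T", 10, t[keep], x[keep])
  rec <- align_to_grid(st, build_expected_grid(10, 10))
  expect_true(rec$filled_mask[51])
  expect_equal(rec$values[51, 1], x[51], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("alignment rejects degenerate inputs and duplicate collisions resolve to the closest sample", {
  grid <- build_expected_grid(10, 10)
  expect_error(align_to_grid(sensor_stream("T", 10, numeric(0), numeric(0)), grid),
               "empty")
  expect_error(align_to_grid(sensor_stream("T", 10, rep(1, 5), rnorm(5)), grid),
               "identical")
  # two samples near one grid index: temporally closest wins
  st <- sensor_stream("T", 10, c(0.47, 0.52, 1.0, 2.0, 3.0), c(10, 20, 3, 4, 5))
  rec <- align_to_grid(st, build_expected_grid(10, 4))
  expect_equal(unname(rec$values[6, 1]), 20) # 0.52 is closer to t = 0.5
  # exact tie resolves to the earlier sample
  st2 <- sensor_stream("T", 10, c(0.48, 0.52, 1.0, 2.0, 3.0), c(10, 20, 3, 4, 5))
  rec2 <- align_to_grid(st2, build_expected_grid(10, 4))
  expect_equal(unname(rec2$values[6, 1]), 10)
})

test_that("interpolation is local and shape-preserving", {
  t <- (0:49) / 5
  y <- cumsum(abs(rnorm(50))) # strictly increasing
  drop <- c(12, 13, 30)
  st <- sensor_stream("T", 5, t[-drop], y[-drop])
  rec <- align_to_grid(st, build_expected_grid(5, 10))
  expect_true(all(diff(rec$values[, 1]) >= -1e-12)) # monotone in, monotone out
  # perturb one observed sample far from index 30: fill at 30 unchanged
  y2 <- y; y2[45] <- y2[45] + 5
  st2 <- sensor_stream("T", 5, t[-drop], y2[-drop])
  rec2 <- align_to_grid(st2, build_expected_grid(5, 10))
  expect_equal(rec2$values[30, 1], rec$values[30, 1])
  expect_equal(rec2$values[12:13, 1], rec$values[12:13, 1])
})

test_that("boundary gaps take the nearest observed value", {
  st <- sensor_stream("T", 10, c(0.5, 0.6, 0.7), c(1, 2, 3))
  rec <- align_to_grid(st, build_expected_grid(10, 1))
  expect_equal(rec$values[1:4, 1], rep(1, 4))
  expect_equal(rec$values[9:10, 1], rep(3, 2))
})

test_that("session reconstruction reports fill fractions and matches grid lengths", {
  cfg <- tiny_config(seed = 21, sensors = c("EDA", "SKT"), n = 1, len = 130,
                     frag = 2)
  co <- generate_cohort(cfg)
  rec <- reconstruct_session(co$sessions[[1]], trim_s = 30)
  expect_equal(nrow(rec$streams$EDA$x), 128 * 70)
  expect_equal(nrow(rec$streams$SKT$x), 70)
  expect_true(rec$report$EDA$fill_fraction < 0.2)
})
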