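test_that("eye closure classifies null and coincident positions as closed", {
  pc <- matrix(0, 3, 3)
  pe <- rbind(c(NA, NA, NA), c(0, 0, 0), c(0.002, 0, 0))
  expect_equal(eye_closure(pe, pc), c(1L, 1L, 0L))
})

test_that("closure denoising matches the exhaustive fixed-point oracle", {
  expect_equal(denoise_closure(c(0, 1, 0)), c(0L, 0L, 0L))
  expect_equal(denoise_closure(c(1, 0, 1)), c(1L, 1L, 1L))
  expect_equal(denoise_closure(rep(1L, 6)), rep(1L, 6))
  for (len in 1:12) {
    for (code in 0:(2^len - 1)) {
      b <- as.integer(intToBits(code))[1:len]
      got <- denoise_closure(b)
      expect_identical(got, denoise_oracle(b))
      if (len >= 3) { # fixed point: no isolated interior singleton remains
        interior <- 2:(len - 1)
        expect_false(any(got[interior] == 1L & got[interior - 1] == 0L & got[interior + 1] == 0L))
        expect_false(any(got[interior] == 0L & got[interior - 1] == 1L & got[interior + 1] == 1L))
      }
    }
  }
})

test_that("closure combination obeys the lattice identities", {
  a <- c(0L, 1L, 1L, 0L)
  expect_equal(closure_combination(a, a), list(and = a, or = a))
  b <- 1L - a
  cc <- closure_combination(a, b)
  expect_equal(cc$and, rep(0L, 4))
  expect_equal(cc$or, rep(1L, 4))
  set.seed(17)
  x <- rbinom(50, 1, 0.3); y <- rbinom(50, 1, 0.3)
  cc2 <- closure_combination(x, y)
  expect_true(all(cc2$and <= cc2$or))
  expect_error(closure_combination(a, a[1:3]), "length")
})

test_that("blink rate counts rising edges per eye and averages", {
  expect_equal(blink_rate(rep(0L, 100), rep(0L, 100), 30), 0)
  mk <- function(k, n = 900) { b <- rep(0L, n); for (i in seq_len(k)) b[(i * 80):(i * 80 + 3)] <- 1L; b }
  expect_equal(blink_rate(mk(5), mk(3), 30), 8) # (10 + 6) / 2 per minute
  set.seed(18)
  for (i in 1:5) {
    b <- rbinom(60, 1, 0.4)
    rle_blinks <- sum(rle(b)$values == 1) - (b[1] == 1) # oracle: runs minus leading run
    expect_equal(blink_rate(b, b, 60), sum(diff(b) == 1))
    expect_equal(sum(diff(b) == 1), rle_blinks)
  }
})

test_that("convergence distance matches the skew-line minimization oracle", {
  d <- convergence_distance(matrix(c(-0.03, 0, 0), 1), matrix(c(0.03, 0, 0), 1),
                            matrix(c(0, 0, 1), 1), matrix(c(0, 0, 1), 1))
  expect_true(is.nan(d)) # parallel gazes
  # coplanar intersecting lines -> zero distance
  d2 <- suppressWarnings(convergence_distance(
    matrix(c(-0.03, 0, 0), 1), matrix(c(0.03, 0, 0), 1),
    matrix(c(0.03, 0, 1), 1) / sqrt(sum(c(0.03, 0, 1)^2)),
    matrix(c(-0.03, 0, 1), 1) / sqrt(sum(c(-0.03, 0, 1)^2))))
  expect_lt(d2, 1e-12)
  set.seed(19)
  for (i in 1:10) {
    pl <- matrix(rnorm(3, sd = 0.05), 1); pr <- matrix(rnorm(3, sd = 0.05), 1)
    dl <- matrix(rnorm(3), 1); dl <- dl / sqrt(sum(dl^2))
    dr <- matrix(rnorm(3), 1); dr <- dr / sqrt(sum(dr^2))
    got <- convergence_distance(pl, pr, dl, dr)
    if (is.nan(got)) next
    expect_equal(got, skewdist_oracle(pl[1, ], dl[1, ], pr[1, ], dr[1, ]),
                 tolerance = 1e-9)
  }
})

test_that("gaze angles follow the spherical conversion", {
  a <- gaze_angles(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(a$yaw, c(0, 90, 0))
  expect_equal(a$pitch, c(0, 0, 90))
  expect_error(gaze_angles(matrix(0, 1, 3)), "zero gaze")
})

test_that("heatmap entropy spans the degenerate and uniform limits", {
  expect_equal(heatmap_entropy(rep(1, 50), rep(1, 50)), 0)
  centers <- seq(-90 + 180 / 128, 90 - 180 / 128, length.out = 64)
  g <- expand.grid(yaw = centers, pitch = centers)
  expect_equal(heatmap_entropy(g$yaw, g$pitch), 12) # 64 x 64 uniform
  set.seed(20)
  yy <- runif(500, -120, 120); pp <- runif(500, -120, 120)
  bin <- function(a) pmin(pmax(floor((a + 90) / 180 * 64), 0), 63)
  tab <- table(paste(bin(yy), bin(pp))) # direct histogram oracle
  p <- as.numeric(tab) / sum(tab)
  expect_equal(heatmap_entropy(yy, pp), -sum(p * log2(p)), tolerance = 1e-12)
})

test_that("gaze velocity classifies saccades with the strict threshold", {
  d <- matrix(rep(c(0, 0, 1), each = 10), 10, 3)
  gv <- gaze_velocity(d, 30)
  expect_true(all(gv$velocity[-1] == 0))
  expect_equal(gv$saccade_ratio, 0)
  expect_equal(gv$fixation_ratio, 1)
  expect_equal(gv$path_length, 0)
  ang <- cumsum(rep(1, 20)) * pi / 180
  d2 <- cbind(sin(ang), 0, cos(ang)) # 1 degree per frame
  gv2 <- gaze_velocity(d2, 30)
  expect_equal(gv2$velocity[-1], rep(30, 19), tolerance = 1e-9)
  expect_equal(gv2$saccade_ratio, 0) # 30 deg/s is a fixation
  ang4 <- cumsum(rep(4, 20)) * pi / 180
  d4 <- cbind(sin(ang4), 0, cos(ang4))
  expect_equal(gaze_velocity(d4, 30)$saccade_ratio, 1) # 120 deg/s > 100
})

test_that("head direction signals are relative to the window-average rotation", {
  rot <- matrix(0, 50, 3) # constant orientation
  hd <- head_direction_signals(rot)
  expect_lt(max(abs(hd$yaw)), 1e-9)
  expect_lt(max(abs(hd$pitch)), 1e-9)
  tpp <- 5 * sin(2 * pi * (1:300) / 60) # pure +-5 degree pitch oscillation
  hd2 <- head_direction_signals(cbind(tpp, 0, 0))
  expect_equal(max(hd2$pitch), 5, tolerance = 0.05)
  expect_equal(min(hd2$pitch), -5, tolerance = 0.05)
  expect_lt(max(abs(hd2$yaw)), 0.05)
  expect_lt(abs(mean(hd2$pitch)), 0.05) # symmetric oscillation centers at 0
})

test_that("the VOR ratio honours its guard rules", {
  expect_equal(vor(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(vor(c(0, 0), c(5, 5)), 0)
  expect_true(is.na(vor(c(1, 2), c(1e-5, 1e-6)))) # stationary head
})
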