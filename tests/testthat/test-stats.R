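test_that("rmcorr recovers perfect within-participant linearity", {
  id <- rep(1:3, each = 5)
  x <- rep(1:5, 3)
  y <- 2 * x + rep(c(10, 20, 30), each = 5)
  res <- rmcorr(x, y, id)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-10)
  expect_equal(res$df, 15 - 3 - 1)
})

test_that("rmcorr is invariant to per-participant shifts and flips sign under negation", {
  set.seed(25)
  id <- rep(1:5, each = 8)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  base <- rmcorr(x, y, id)
  shifted <- rmcorr(x + rep(rnorm(5) * 100, each = 8),
                    y + rep(rnorm(5) * 100, each = 8), id)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_equal(rmcorr(-x, y, id)$r, -base$r, tolerance = 1e-12)
  expect_equal(rmcorr(3 * x, y, id)$r, base$r, tolerance = 1e-12)
})

test_that("rmcorr agrees with the design-matrix ANCOVA oracle", {
  set.seed(26)
  for (i in 1:5) {
    id <- rep(1:4, each = 6)
    x <- rnorm(24)
    y <- 0.3 * x + rnorm(24) + rep(rnorm(4), each = 6)
    got <- rmcorr(x, y, id)
    ora <- rmcorr_oracle(x, y, id)
    expect_equal(got$r, ora$r, tolerance = 1e-9)
    expect_equal(got$p, ora$p, tolerance = 1e-9)
    expect_equal(got$df, ora$df)
  }
})

test_that("rmcorr flags insufficient or degenerate data invalid", {
  expect_false(rmcorr(1:2, 1:2, c(1, 1))$valid) # df < 1
  expect_false(rmcorr(rep(1, 10), rnorm(10), rep(1:2, 5))$valid) # no x variance
  # single observations are dropped before fitting
  res <- rmcorr(c(1, 2, 3, 9), c(1, 2, 3, 9), c("a", "a", "a", "b"))
  expect_equal(res$n_participants, 1)
})

test_that("BH adjustment matches the textbook step-up oracle per family", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(27)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-15)
  }
  p <- runif(12)
  fam <- rep(c("a", "b"), each = 6)
  got <- bh_adjust(p, fam)
  expect_equal(got[fam == "a"], bh_oracle(p[fam == "a"]))
  expect_equal(got[fam == "b"], bh_oracle(p[fam == "b"]))
  # monotone within family
  o <- order(p[fam == "a"])
  expect_true(all(diff(got[fam == "a"][o]) >= 0))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(1.5), "0, 1")
})

test_that("SESOI tiers gate jointly on effect size and significance", {
  mk <- function(r, p) structure(list(r = r, p = p, valid = TRUE, df = 100,
                                      n_obs = 102, n_participants = 2),
                                 class = "rmcorr_result")
  s <- sesoi_screen(list(mk(0.25, 0.01), mk(0.40, 0.20), mk(-0.31, 0.001),
                         mk(0.21, 0.01), mk(0.26, 0.049)))
  expect_equal(s$tier, c("medium", "none", "large", "medium", "conservative"))
})

test_that("session means drop missing windows pairwise", {
  f <- data.frame(participant = "P01", ms_type = "CMS", id = "f1",
                  value = c(2, 4, NA))
  m <- session_mean_features(f)
  expect_equal(m$value, 3)
  set.seed(28)
  f2 <- data.frame(participant = rep(c("P01", "P02"), each = 6),
                   ms_type = "CMS", id = rep(c("a", "b"), 6),
                   value = rnorm(12))
  m2 <- session_mean_features(f2)
  ora <- tapply(f2$value, paste(f2$participant, f2$id), mean) # group-by oracle
  expect_equal(m2$value[m2$participant == "P01" & m2$id == "a"],
               unname(ora[["P01 a"]]))
})

test_that("the ANOVA delegation returns standard fits", {
  set.seed(29)
  d <- data.frame(y = rnorm(40), g = factor(rep(1:2, 20)),
                  h = factor(rep(1:2, each = 20)))
  fit <- mixed_anova(y ~ g * h, d, type = 1)
  expect_s3_class(fit, "aov")
  skip_if_not_installed("car")
  tab <- mixed_anova(y ~ g * h, d, type = 3)
  expect_true("Sum Sq" %in% colnames(tab))
})
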