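sim_xy <- function(n = 600, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 2 * x[, 1] - 1 * x[, 2] + rnorm(n, sd = 0.5)
  list(x = x, y = y)
}

test_that("the additive booster is deterministic and finds planted structure", {
  d <- sim_xy()
  f1 <- fit_ebm(d$x, d$y, seed = 42)
  f2 <- fit_ebm(d$x, d$y, seed = 42)
  expect_identical(f1$importance, f2$importance)
  expect_equal(names(f1$importance)[1], "f1")
  expect_gt(f1$metrics[["r2"]], 0.8)
  expect_true(all(abs(f1$metrics[c("plcc", "srcc")]) <= 1))
})

test_that("the booster approaches the linear-model fit on additive data", {
  d <- sim_xy(n = 1000)
  f <- fit_ebm(d$x, d$y, interactions = 0)
  lm_r2 <- summary(lm(d$y ~ d$x))$r.squared
  expect_gt(f$metrics[["r2"]], lm_r2 - 0.05)
})

test_that("importance ranking agrees with an independent boosted-tree cross-check", {
  skip_if_not_installed("xgboost")
  d <- sim_xy(n = 800, seed = 3)
  ours <- names(fit_ebm(d$x, d$y)$importance)[1]
  bst <- xgboost::xgboost(d$x, d$y, nrounds = 50, max_depth = 2, nthread = 1)
  imp <- xgboost::xgb.importance(model = bst)
  expect_equal(ours, imp$Feature[1])
})

test_that("constant targets are flagged as degenerate", {
  x <- matrix(rnorm(100), 50, 2)
  expect_warning(f <- fit_ebm(x, rep(3, 50)), "constant target")
  expect_true(is.na(f$metrics[["r2"]]))
  expect_error(fit_ebm(x, c(rep(1, 49), NA)), "non-finite target")
})

test_that("degradation follows the exact formula and sign convention", {
  expect_equal(degradation(0.9, 0.9), 0)
  expect_equal(degradation(0.9, 0), 100)
  expect_lt(degradation(0.8, 0.85), 0) # improvement on removal
  expect_equal(degradation(c(r2 = 0.5, plcc = 0.8), c(r2 = 0.25, plcc = 0.4)),
               c(r2 = 50, plcc = 50))
  expect_error(degradation(0, 0.5), "zero")
})

test_that("ablation, single-domain and combos run on identical rows and partition columns", {
  d <- sim_xy(n = 400, p = 6, seed = 5)
  domain <- c("EDA", "EDA", "Head", "Head", "PPG", "Eye")
  full <- fit_ebm(d$x, d$y)
  abl <- ablate_domains(d$x, d$y, domain, full$metrics)
  sing <- single_domain_eval(d$x, d$y, domain, full$metrics)
  expect_setequal(names(abl), unique(domain))
  # per-domain column counts partition the feature set
  expect_equal(sum(table(domain)), ncol(d$x))
  # ablated + single column sets are disjoint and union to the full set
  for (dm in unique(domain)) {
    expect_equal(sort(c(which(domain == dm), which(domain != dm))),
                 seq_along(domain))
  }
  # the domain holding the planted signal hurts most when ablated
  expect_equal(names(which.max(vapply(abl, function(a) a$delta[["r2"]], numeric(1)))),
               "EDA")
  # and suffices nearly alone
  expect_lt(sing$EDA$delta[["r2"]], sing$Eye$delta[["r2"]])
  cmb <- combo_eval(d$x, d$y, domain, full$metrics,
                    combos = list(all = unique(domain)))
  expect_equal(unname(cmb$all$delta), rep(0, 3)) # full set vs itself
  expect_length(default_combos(), 4)
})

test_that("participant-wise folds partition participants deterministically", {
  d <- sim_xy(n = 120, p = 3, seed = 6)
  part <- rep(sprintf("P%02d", 1:10), each = 12)
  cv <- participant_cv(d$x, d$y, part, k = 5, seed = 9)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_length(cv$folds, 10)
  cv2 <- participant_cv(d$x, d$y, part, k = 5, seed = 9)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$mean, cv2$mean)
  lopo <- participant_cv(d$x, d$y, part, k = 10, seed = 9)
  expect_equal(max(table(lopo$folds)), 1) # leave-one-participant-out
  expect_error(participant_cv(d$x, d$y, part, k = 11), "exceeds")
})

test_that("the feature matrix pivot preserves values and maps domains", {
  feats <- data.frame(participant = rep("P01", 4), ms_type = "CMS",
                      window = c(1, 1, 2, 2),
                      id = rep(c("EDA_raw_ptp", "HeadPose_rotPitch_var"), 2),
                      value = c(1, 2, 3, 4))
  fms <- data.frame(participant = "P01", ms_type = "CMS", window = 1:2,
                    fms = c(1, 2))
  fm <- feature_matrix(feats, fms)
  expect_equal(dim(fm$x), c(2L, 2L))
  expect_equal(fm$x["P01|CMS|1", "EDA_raw_ptp"], 1)
  expect_equal(fm$x["P01|CMS|2", "HeadPose_rotPitch_var"], 4)
  expect_equal(fm$domain, c("EDA", "Head"))
  expect_equal(fm$y, c(1, 2))
})
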