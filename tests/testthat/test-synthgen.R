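test_that("cohort generation is deterministic and counterbalanced", {
  cfg <- tiny_config(seed = 11, sensors = "SKT", n = 16, len = 70)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sort(a$truth$assignment$cell), 1:16) # each design cell once
  expect_equal(length(a$sessions), 16 * 3)
  cells <- counterbalance_cells()
  expect_equal(nrow(cells), 16)
  expect_equal(nrow(unique(cells[, c("vims_type", "scenario_version", "movie_order")])), 16)
})

test_that("streams come out at their nominal rates", {
  cfg <- synthetic_config(n_participants = 1, ms_types = "CMS",
                          session_length_s = 1200,
                          sensor_specs = default_sensor_specs()["PPG"],
                          fragmentation_rate = 0, jitter_chunks = 0, seed = 2)
  co <- generate_cohort(cfg)
  ppg <- co$sessions[[1]]$streams$PPG[[1]]
  expect_equal(length(ppg$t), 128 * 1200) # 153,600 samples before trimming
  expect_equal(ppg$rate, 128)
})

test_that("latent trajectory is reproducible, zero at zero susceptibility, and grows with it", {
  expect_identical(generate_msl_trajectory(300, 0, "CMS", 5), numeric(300))
  a <- generate_msl_trajectory(300, 1, "CMS", 5)
  expect_identical(a, generate_msl_trajectory(300, 1, "CMS", 5))
  expect_true(all(a >= 0))
  # on-average non-decreasing: late mean above early mean
  expect_gt(mean(tail(a, 60)), mean(head(a, 60)))
  terminal <- sapply(c(0.5, 1, 2), function(s) {
    mean(sapply(1:200, function(seed) {
      tail(generate_msl_trajectory(120, s, "CMS", seed), 1)
    }))
  })
  expect_true(all(diff(terminal) > 0))
})

test_that("fms reports are quantized to the 1-5 scale and follow the latent level", {
  z <- generate_msl_trajectory(1200, 2, "CoMS", 9)
  rep <- fms_reports_from_latent(z, seed = 9)
  expect_equal(rep$time_s, seq(30, 1200, by = 30))
  expect_true(all(rep$fms %in% 1:5))
  expect_gt(mean(tail(rep$fms, 10)), mean(head(rep$fms, 10)))
})

test_that("fragmentation reproduces the restart geometry and round-trips", {
  st <- uniform_stream(32, 1200)
  expect_identical(inject_fragmentation(st, numeric(0)), list(st))
  fr <- inject_fragmentation(st, 500, overlap_s = 10)
  expect_length(fr, 2)
  expect_equal(range(fr[[1]]$t), c(0, 500 - 1 / 32))
  expect_equal(min(fr[[2]]$t), 490)
  expect_equal(max(fr[[2]]$t), 1200 - 1 / 32)
  expect_error(inject_fragmentation(st, 1500), "outside")
  expect_error(inject_fragmentation(st, 500, overlap_s = 2), "at least 5")
  # 2 events -> 3 fragments; timeline round-trip recovers the signal
  fr3 <- inject_fragmentation(st, c(400, 800), overlap_s = 10)
  expect_length(fr3, 3)
  merged <- merge_fragments(fr3)
  grid <- build_expected_grid(32, 1200)
  rec <- align_to_grid(merged, grid)
  expect_lt(max(abs(rec$values[, 1] - sin(2 * pi * grid$times))), 1e-9)
})

test_that("chunk jitter perturbs save-block counts but preserves content", {
  st <- uniform_stream(128, 60)
  expect_identical(perturb_chunk_timing(st, max_dev_chunks = 0), st)
  j1 <- perturb_chunk_timing(st, seed = 4)
  j2 <- perturb_chunk_timing(st, seed = 4)
  expect_identical(j1, j2)
  bc <- attr(j1, "block_counts")
  expect_true(all(abs(bc[2:59] - 128) <= 8)) # one 16-Hz chunk = 8 samples
  expect_false(all(bc[1:59] == 128))
  expect_equal(length(j1$t), length(st$t)) # no loss without dropout
  # grid correction round-trip on a 10-Hz-bandlimited signal
  f <- function(t) sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 10 * t)
  st2 <- uniform_stream(128, 60, f)
  j0 <- perturb_chunk_timing(st2, seed = 8)
  rec0 <- align_to_grid(j0, build_expected_grid(128, 60))
  expect_lt(sqrt(mean((rec0$values[, 1] - f(rec0$grid$times))^2)), 1e-6)
  j <- perturb_chunk_timing(st2, seed = 8, drop_prob = 0.002)
  rec <- align_to_grid(j, build_expected_grid(128, 60))
  rmse <- sqrt(mean((rec$values[, 1] - f(rec$grid$times))^2))
  expect_lt(rmse, 0.05 * 1.5) # interpolated dropouts: < 5% of the amplitude
})

test_that("configuration errors are rejected", {
  expect_error(synthetic_config(session_length_s = 50), "exceed 60")
  expect_error(synthetic_config(n_participants = 0), "positive integer")
  specs <- default_sensor_specs()["SKT"]
  specs$SKT$rate <- -1
  expect_error(synthetic_config(sensor_specs = specs), "invalid sampling rate")
})

test_that("cohort directories are written as plain text", {
  cfg <- tiny_config(seed = 3, sensors = "SKT", n = 1, len = 70)
  co <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  sess_dir <- list.dirs(dir, recursive = FALSE)[1]
  csvs <- list.files(sess_dir, pattern = "\\.csv$")
  expect_true("fms.csv" %in% csvs)
  expect_true(any(grepl("^SKT_frag", csvs)))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_named(gt, c("latent_msl", "susceptibility", "planted_loadings"))
  unlink(dir, recursive = TRUE)
})
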