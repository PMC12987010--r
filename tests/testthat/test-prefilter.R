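test_that("notch suppression removes the target line and leaves the passband intact", {
  rate <- 500
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  line <- sin(2 * pi * 60 * t)
  out <- notch_suppress(line, rate, 60, halfwidth = 5)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(line^2)), 0.10)
  clean <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 35 * t)
  out2 <- notch_suppress(clean, rate, c(60, 120, 180, 240), halfwidth = 5)
  expect_lt(sqrt(mean((out2 - clean)^2)) / sqrt(mean(clean^2)), 0.01)
  expect_error(notch_suppress(clean, rate, 250), "Nyquist")
})

test_that("band-pass removes DC, preserves in-band amplitude, kills one octave out", {
  rate <- 128
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  out <- bandpass(rep(2, length(t)), rate, 0.5, 10)
  expect_lt(abs(mean(out)), 1e-6)
  inband <- sin(2 * pi * 3 * t)
  got <- bandpass(inband, rate, 0.5, 10)
  expect_equal(sqrt(mean(got^2)), sqrt(mean(inband^2)), tolerance = 0.05)
  octave <- sin(2 * pi * 20 * t) # one octave above the 10-Hz edge
  expect_lt(sqrt(mean(bandpass(octave, rate, 0.5, 10)^2)) /
              sqrt(mean(octave^2)), 0.1) # >= 20 dB
  expect_error(bandpass(inband, rate, 10, 5), "invalid band")
  expect_equal(bandpass_preset("ppg_wdf"), c(0.66, 3.33))
})

test_that("resistance-conductance conversion is the exact reciprocal law", {
  expect_equal(eda_resistance_to_conductance(1000), 1)
  expect_equal(eda_resistance_to_conductance(500), 2)
  r <- c(120, 350, 900)
  expect_equal(1000 / eda_resistance_to_conductance(r), r)
  expect_error(eda_resistance_to_conductance(-1), "non-positive")
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  x <- matrix(rnorm(400), 100, 4)
  y <- eeg_common_average_reference(x)
  expect_lt(max(abs(rowMeans(y))), 1e-12)
  expect_equal(eeg_common_average_reference(y), y)
  same <- matrix(rep(rnorm(100), 3), 100, 3)
  expect_lt(max(abs(eeg_common_average_reference(same))), 1e-12)
  expect_error(eeg_common_average_reference(matrix(1:5)), ">= 2 channels")
})

test_that("the artifact hook defaults to identity and rejects shape changes", {
  x <- matrix(rnorm(60), 20, 3)
  expect_identical(eeg_artifact_hook(x), x)
  expect_equal(eeg_artifact_hook(x, function(m) m * 0), x * 0)
  expect_error(eeg_artifact_hook(x, function(m) m[, 1:2]), "shape")
})

test_that("the hook runs after the common average reference in the EEG chain", {
  cfg <- tiny_config(seed = 5, sensors = "EEG", n = 1, len = 70)
  co <- generate_cohort(cfg)
  rec <- reconstruct_session(co$sessions[[1]], trim_s = 5)
  seen <- NULL
  preprocess_stream(rec$streams$EEG,
                    eeg_remover = function(m) { seen <<- m; m })
  expect_false(is.null(seen))
  expect_lt(max(abs(rowMeans(seen))), 1e-9) # CAR already applied on entry
})

test_that("the skin-temperature smoother is the 3-point mean with shortened edges", {
  expect_equal(skt_moving_average(rep(7, 10)), rep(7, 10))
  expect_equal(skt_moving_average(c(0, 3, 0))[2], 1)
  x <- rep(c(1, -1), 10)
  got <- skt_moving_average(x)
  conv <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2)) # oracle
  expect_equal(got[2:19], conv[2:19])
  expect_equal(got[2:19], -x[2:19] / 3)
  expect_equal(got[1], mean(x[1:2]))
  expect_error(skt_moving_average(c(1, 2)), "at least 3")
})

test_that("every chain preserves length and is deterministic", {
  cfg <- tiny_config(seed = 6, sensors = c("PPG", "EDA", "SKT", "Eye"), n = 1, len = 70)
  co <- generate_cohort(cfg)
  rec <- reconstruct_session(co$sessions[[1]], trim_s = 5)
  p1 <- preprocess_session(rec$streams)
  p2 <- preprocess_session(rec$streams)
  expect_identical(p1, p2)
  for (nm in names(p1)) expect_equal(nrow(p1[[nm]]$x), nrow(rec$streams[[nm]]$x))
  # EDA comes out in conductance units (uS), reciprocal of the kOhm input
  expect_false(identical(p1$EDA$x, rec$streams$EDA$x))
})
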