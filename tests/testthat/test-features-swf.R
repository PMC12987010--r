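test_that("windowing follows the floor rule", {
  expect_equal(windowize(1140)$n, 38L)
  expect_equal(windowize(30)$n, 1L)
  expect_equal(windowize(59)$n, 1L)
  expect_error(windowize(20), "shorter")
  w <- windowize(90, seams = c(45, 100))
  expect_length(w$windows[[2]]$segments, 2) # seam at 45 splits window 2
  expect_length(w$windows[[1]]$segments, 1)
})

test_that("FMS window values are the time-weighted mean of held reports", {
  rep1 <- data.frame(time_s = 10, fms = 4)
  expect_equal(map_fms(rep1, 0, 30), 4)
  rep2 <- data.frame(time_s = c(0, 15), fms = c(1, 3))
  expect_equal(map_fms(rep2, 0, 30), 2)
  expect_error(map_fms(data.frame(time_s = 99, fms = 1), 0, 30), "before window end")
  # brute-force 1-ms integration oracle on random report layouts
  set.seed(31)
  for (i in 1:10) {
    times <- sort(runif(5, 0, 60))
    vals <- sample(1:5, 5, replace = TRUE)
    reps <- data.frame(time_s = times, fms = vals)
    tt <- seq(30.0005, 60, by = 0.001)
    idx <- findInterval(tt, times)
    hold <- vals[pmax(idx, 1)]
    expect_equal(map_fms(reps, 30, 60), mean(hold), tolerance = 1e-4)
  }
})

test_that("the time-domain template handles degenerate and Gaussian inputs", {
  v <- swf_time(list(rep(3, 100)))
  expect_equal(v[["avg"]], 3)
  expect_equal(v[["var"]], 0)
  expect_equal(v[["ptp"]], 0)
  expect_equal(v[["sampen"]], 0) # zero-variance convention
  expect_true(is.na(v[["skw"]]) && is.na(v[["kut"]]))
  set.seed(7)
  g <- swf_time(list(rnorm(3000)))
  expect_lt(abs(g[["kut"]]), 0.2)
  expect_lt(abs(g[["skw"]]), 0.1)
  expect_lt(abs(g[["avg"]]), 0.05)
})

test_that("segment averaging matches direct per-segment computation", {
  set.seed(8)
  a <- rnorm(500); b <- rnorm(500)
  both <- swf_time(list(a, b), sampen = FALSE)
  ma <- swf_time(list(a), sampen = FALSE)
  mb <- swf_time(list(b), sampen = FALSE)
  expect_equal(both[["avg"]], (ma[["avg"]] + mb[["avg"]]) / 2)
  expect_equal(both[["var"]], (ma[["var"]] + mb[["var"]]) / 2)
})

test_that("sample entropy agrees exactly with the brute-force oracle", {
  x <- numeric(500); x[1] <- 0.4
  for (i in 2:500) x[i] <- 3.9 * x[i - 1] * (1 - x[i - 1]) # logistic map
  expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:3) {
    y <- rnorm(120)
    expect_equal(sample_entropy(y), sampen_oracle(y), tolerance = 1e-12)
  }
  expect_equal(sample_entropy(rep(1, 50)), 0)
})

test_that("PSD entropy separates tones from broadband noise", {
  rate <- 500
  spec <- welch_spec("EEG", rate) # segment = FFT length: no padding smear
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  f0 <- 41 * rate / spec$fft_length # tone exactly on a Welch bin (~10 Hz)
  tone <- swf_freq(list(sin(2 * pi * f0 * t)), rate, spec,
                   list(raw = c(1, 50)))
  expect_lt(tone["raw", "pse"], 2.5) # energy in the mainlobe bins only
  set.seed(10)
  noise <- swf_freq(list(rnorm(length(t))), rate, spec, list(raw = c(1, 50)))
  freqs <- seq(0, rate / 2, by = rate / spec$fft_length)
  nbins <- sum(freqs >= 1 & freqs <= 50)
  expect_equal(noise["raw", "pse"], log2(nbins), tolerance = 0.05 * log2(nbins))
  expect_gt(noise["raw", "pse"], tone["raw", "pse"] + 3)
})

test_that("EEG Welch resolution is ~0.24 Hz per bin", {
  spec <- welch_spec("EEG", 500)
  expect_equal(500 / spec$fft_length, 0.244140625)
  expect_equal(round(500 / spec$fft_length, 2), 0.24)
})

test_that("band decomposition partitions the spectrum", {
  rate <- 500
  set.seed(11)
  x <- rnorm(rate * 30)
  spec <- welch_spec("EEG", rate)
  psd <- welch_psd(x, rate, spec)
  scheme <- band_scheme("EEG")
  whole <- swf_freq_metrics(psd, scheme$raw)[["bpw"]]
  parts <- c(swf_freq_metrics(psd, scheme$delta, closed_upper = FALSE)[["bpw"]],
             swf_freq_metrics(psd, scheme$theta, closed_upper = FALSE)[["bpw"]],
             swf_freq_metrics(psd, scheme$alpha, closed_upper = FALSE)[["bpw"]],
             swf_freq_metrics(psd, scheme$beta, closed_upper = FALSE)[["bpw"]],
             swf_freq_metrics(psd, scheme$gamma, closed_upper = TRUE)[["bpw"]])
  expect_equal(sum(parts), whole, tolerance = 0.01 * whole)
})

test_that("band membership routes tones to the right sub-band", {
  rate <- 128
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 0.2 * t)
  m <- swf_freq(list(x), rate, welch_spec("PPG", rate), band_scheme("PPG"))
  expect_gt(m["HF", "bpw"], 20 * m["LF", "bpw"]) # 0.2 Hz is an HF tone
  eda <- band_signals(x, rate, band_scheme("EDA"), mode = "time")
  expect_named(eda, c("raw", "SCL", "SCR", "LF"))
  expect_error(swf_freq_metrics(welch_psd(x, rate, welch_spec("PPG", rate)),
                                c(0.001, 0.002)), "no PSD bins")
})

test_that("welch psd matches a direct single-segment periodogram", {
  rate <- 64
  x <- sin(2 * pi * 8 * seq(0, 4 - 1 / rate, by = 1 / rate))
  n <- length(x)
  spec <- list(fft_length = n, segment_length = n, overlap = 0.5)
  got <- welch_psd(x, rate, spec)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) # Hann oracle
  pg <- abs(fft(x * w))^2 / (rate * sum(w^2))
  pg <- pg[1:(n / 2 + 1)]
  pg[2:(n / 2)] <- 2 * pg[2:(n / 2)]
  expect_equal(got$psd, pg, tolerance = 1e-12)
  # total in-band power of a unit sine ~ 1/2 (Parseval)
  expect_equal(sum(got$psd) * got$df, 0.5, tolerance = 0.02)
})
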