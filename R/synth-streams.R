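# Per-sensor baseline signal models. Each stream is an oscillatory or noise
# process whose amplitude (or noise fraction) is modulated linearly by the
# latent MSL trajectory through the planted loadings, so that downstream
# windowed features carry a controllable within-session association with FMS.
# All generators assume the caller has already seeded the RNG.

pink_noise <- function(n, exponent = 1) {
  nf <- stats::nextn(n, 2)
  w <- rnorm(nf)
  sp <- fft(w)
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)
  sp <- sp * f^(-exponent / 2)
  x <- Re(fft(sp, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / sd(x)
}

# Narrowband oscillation with a slowly wandering AR(1) envelope (time constant
# tau_s), unit nominal amplitude.
narrowband <- function(t, f0, rate, tau_s = 1, env_depth = 0.15) {
  n <- length(t)
  phi <- exp(-1 / (tau_s * rate))
  innov <- rnorm(n, sd = env_depth * sqrt(1 - phi^2))
  env <- 1 + as.numeric(stats::filter(innov, phi, method = "recursive"))
  env * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
}

# Mean-reverting (OU-type) drift at 1 Hz, linearly interpolated to the
# target timestamps. Short memory (tau_s) keeps non-overlapping analysis
# windows nearly independent, which the null-calibration property relies on.
ou_drift <- function(duration_s, t, tau_s, sd_target) {
  n1 <- max(2L, as.integer(ceiling(duration_s)) + 1L)
  phi <- exp(-1 / tau_s)
  z <- as.numeric(stats::filter(rnorm(n1, sd = sd_target * sqrt(1 - phi^2)),
                                phi, method = "recursive"))
  approx(seq(0, by = 1, length.out = n1), z, xout = t, rule = 2)$y
}

gen_eda <- function(spec, duration_s, latent, beta) {
  rate <- spec$rate
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  tonic <- 3 + ou_drift(duration_s, t, tau_s = 5, sd_target = 0.1)
  # phasic: Poisson SCR events, amplitude modulated by the planted loading
  n_ev <- rpois(1, lambda = 6 * duration_s / 60)
  impulse <- numeric(n)
  if (n_ev > 0) {
    ev_t <- sort(runif(n_ev, 0, duration_s - 5))
    ev_a <- abs(rnorm(n_ev, 0.4, 0.15)) * msl_modulation(latent, ev_t, beta)
    idx <- pmin(round(ev_t * rate) + 1, n)
    impulse[idx] <- impulse[idx] + ev_a
  }
  tk <- seq(0, 5, by = 1 / rate)
  kernel <- (1 - exp(-tk / 0.3)) * exp(-tk / 1.0)
  kernel <- kernel / max(kernel)
  phasic <- fast_conv(impulse, kernel)[seq_len(n)]
  g_us <- pmax(tonic + phasic + rnorm(n, sd = 0.01), 0.1)
  sensor_stream("EDA", rate, t, 1000 / g_us, spec$channels)
}

gen_ppg <- function(spec, duration_s, latent, beta = 0) {
  rate <- spec$rate
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  hr <- 70 + 3 * sin(2 * pi * t / 90 + runif(1, 0, 2 * pi)) +
    ou_drift(duration_s, t, tau_s = 20, sd_target = 2)
  phase <- 2 * pi * cumsum(hr / 60) / rate
  x <- sin(phase) + 0.35 * sin(2 * phase + 0.6) + 0.18 * sin(3 * phase + 1.2) +
    0.02 * sin(2 * pi * 30 * t) + 0.02 * sin(2 * pi * 60 * t) +
    rnorm(n, sd = 0.05)
  sensor_stream("PPG", rate, t, x, spec$channels)
}

gen_eeg <- function(spec, duration_s, latent, beta) {
  rate <- spec$rate
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  mod <- msl_modulation(latent, t, beta) # beta < 0: broadband fraction shrinks
  ch <- spec$channels
  x <- matrix(0, n, length(ch))
  alpha_gain <- ifelse(grepl("^O", ch), 6, 3)
  for (j in seq_along(ch)) {
    broad <- 10 * pink_noise(n) * mod
    alpha <- alpha_gain[j] * narrowband(t, 10 + runif(1, -0.5, 0.5), rate, tau_s = 2)
    line <- 1.0 * sin(2 * pi * 60 * t + runif(1, 0, 2 * pi)) +
      0.3 * sin(2 * pi * 120 * t) + 0.15 * sin(2 * pi * 180 * t)
    x[, j] <- broad + alpha + line
  }
  sensor_stream("EEG", rate, t, x, ch)
}

gen_skt <- function(spec, duration_s, latent, beta = 0) {
  rate <- spec$rate
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  x <- 33 + ou_drift(duration_s, t, tau_s = 5, sd_target = 0.15) +
    rnorm(n, sd = 0.02)
  sensor_stream("SKT", rate, t, x, spec$channels)
}

gen_headpose <- function(spec, duration_s, latent, beta_pitch, beta_surge) {
  rate <- spec$rate
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  ch <- spec$channels
  x <- matrix(0, n, length(ch), dimnames = list(NULL, ch))
  amp_pos <- c(posSway = 0.015, posHeave = 0.015, posSurge = 0.02)
  for (nm in names(amp_pos)) {
    beta <- if (nm == "posSurge") beta_surge else 0
    base <- narrowband(t, runif(1, 0.2, 0.5), rate)
    x[, nm] <- amp_pos[[nm]] * base * msl_modulation(latent, t, beta) +
      rnorm(n, sd = 0.003)
  }
  amp_rot <- c(rotPitch = 2, rotYaw = 2, rotRoll = 1.5)
  for (nm in names(amp_rot)) {
    beta <- if (nm == "rotPitch") beta_pitch else 0
    base <- narrowband(t, runif(1, 0.3, 0.8), rate)
    x[, nm] <- amp_rot[[nm]] * base * msl_modulation(latent, t, beta) +
      rnorm(n, sd = 0.3)
  }
  sensor_stream("HeadPose", rate, t, x, ch)
}

gen_headimu <- function(spec, duration_s, latent, beta_pitch, beta_surge) {
  rate <- spec$rate
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  ch <- spec$channels
  x <- matrix(0, n, length(ch), dimnames = list(NULL, ch))
  for (nm in c("accSway", "accHeave", "accSurge")) {
    beta <- if (nm == "accSurge") beta_surge else 0
    x[, nm] <- 0.3 * rnorm(n) * msl_modulation(latent, t, beta) + 9.81 * (nm == "accHeave")
  }
  for (nm in c("gyrPitch", "gyrYaw", "gyrRoll")) {
    beta <- if (nm == "gyrPitch") beta_pitch else 0
    x[, nm] <- 5 * rnorm(n) * msl_modulation(latent, t, beta)
  }
  sensor_stream("HeadIMU", rate, t, x, ch)
}

angles_to_dir <- function(yaw_deg, pitch_deg) {
  yaw <- yaw_deg * pi / 180
  pitch <- pitch_deg * pi / 180
  cbind(x = cos(pitch) * sin(yaw), y = sin(pitch), z = cos(pitch) * cos(yaw))
}

gen_eye <- function(spec, duration_s, latent, beta_entropy) {
  rate <- spec$rate
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate
  mod <- msl_modulation(latent, t, beta_entropy) # beta > 0: noise floor grows
  yaw <- 4 * narrowband(t, 0.4, rate) + 1.5 * rnorm(n) * mod
  pitch <- 3 * narrowband(t, 0.3, rate) + 1.5 * rnorm(n) * mod
  dc <- angles_to_dir(yaw, pitch)
  pL <- cbind(x = -0.032 + rnorm(n, sd = 1e-4), y = rnorm(n, sd = 1e-4),
              z = rnorm(n, sd = 1e-4))
  pR <- cbind(x = 0.032 + rnorm(n, sd = 1e-4), y = rnorm(n, sd = 1e-4),
              z = rnorm(n, sd = 1e-4))
  pC <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  vergence_d <- 1.5 + 0.5 * sin(2 * pi * t / 15 + runif(1, 0, 2 * pi))
  target <- dc * vergence_d
  dL <- target - pL
  dR <- target - pR
  dL <- dL / sqrt(rowSums(dL^2))
  dR <- dR / sqrt(rowSums(dR^2))
  # blinks: both-eye closures; a fraction reported as null (NA) positions
  n_blink <- rpois(1, 15 * duration_s / 60)
  closed <- rep(FALSE, n)
  if (n_blink > 0) {
    bt <- runif(n_blink, 0, duration_s - 1)
    bd <- runif(n_blink, 0.15, 0.3)
    for (b in seq_len(n_blink)) {
      idx <- which(t >= bt[b] & t < bt[b] + bd[b])
      closed[idx] <- TRUE
    }
  }
  as_null <- closed & (runif(n) < 0.2)
  eq_center <- closed & !as_null
  pL[eq_center, ] <- pC[eq_center, ]
  pR[eq_center, ] <- pC[eq_center, ]
  dL[eq_center, ] <- dc[eq_center, ]
  dR[eq_center, ] <- dc[eq_center, ]
  pL[as_null, ] <- NA_real_
  pR[as_null, ] <- NA_real_
  dL[as_null, ] <- NA_real_
  dR[as_null, ] <- NA_real_
  x <- cbind(pL, pR, pC, dL, dR, dc)
  colnames(x) <- spec$channels
  sensor_stream("Eye", rate, t, x, spec$channels)
}

generate_session_streams <- function(config, latent, participant, ms_type) {
  es <- config$effect_sizes
  dur <- config$session_length_s
  out <- list()
  for (sp in config$sensor_specs) {
    seed <- derive_seed(config$seed, participant, ms_type, sp$name)
    out[[sp$name]] <- with_seed(seed, switch(
      sp$name,
      PPG = gen_ppg(sp, dur, latent),
      EDA = gen_eda(sp, dur, latent, es[["eda_amplitude"]]),
      EEG = gen_eeg(sp, dur, latent, es[["eeg_sample_entropy"]]),
      SKT = gen_skt(sp, dur, latent),
      HeadPose = gen_headpose(sp, dur, latent, es[["head_pitch_energy"]],
                              es[["head_surge_energy"]]),
      HeadIMU = gen_headimu(sp, dur, latent, es[["head_pitch_energy"]],
                            es[["head_surge_energy"]]),
      Eye = gen_eye(sp, dur, latent, es[["eye_dir_psd_entropy"]]),
      stopf("unknown sensor %s", sp$name)
    ))
  }
  out
}
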