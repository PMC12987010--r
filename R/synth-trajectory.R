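#' Latent motion-sickness trajectory
#'
#' Draws a non-negative, on-average non-decreasing latent MSL trajectory at
#' 1 Hz: a logistic ramp whose amplitude scales with the participant's
#' susceptibility, plus susceptibility-scaled AR(1) noise, clamped at zero.
#' Symptoms accumulate with exposure, so the ramp midpoint sits in the second
#' half of the session; the session type modulates the asymptote (composite
#' stimulation > classical > visual-only).
#'
#' @param duration_s session length in seconds (> 0).
#' @param susceptibility non-negative scalar; 0 yields the all-zero trajectory.
#' @param ms_type one of `"CMS"`, `"VIMS"`, `"CoMS"` (any other label gets the
#'   CMS gain).
#' @param seed integer seed; the trajectory is deterministic given the seed.
#' @return numeric vector of length `duration_s` (1 Hz samples at t = 1..T).
#' @export
generate_msl_trajectory <- function(duration_s, susceptibility, ms_type = "CMS",
                                    seed = 1L) {
  if (duration_s <= 0) stopf("duration_s must be positive")
  if (susceptibility < 0) stopf("susceptibility must be non-negative")
  n <- as.integer(round(duration_s))
  if (susceptibility == 0) return(numeric(n))
  gain <- switch(ms_type, CMS = 1.0, VIMS = 0.85, CoMS = 1.2, 1.0)
  with_seed(seed, {
    t0 <- duration_s * runif(1, 0.4, 0.6)
    tau <- duration_s * runif(1, 0.10, 0.16)
    tt <- seq_len(n)
    ramp <- susceptibility * gain / (1 + exp(-(tt - t0) / tau))
    phi <- 0.95
    innov <- rnorm(n, sd = 0.08 * susceptibility * sqrt(1 - phi^2))
    ar <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    pmax(ramp + ar, 0)
  })
}

# Normalized modulation of a signal family by the latent trajectory:
# multiplier m(t) = max(1 + beta * z(t), 0.05), with z the 1-Hz latent
# trajectory linearly interpolated to the target timestamps.
msl_modulation <- function(latent, t, beta) {
  if (beta == 0 || all(latent == 0)) return(rep(1, length(t)))
  z <- approx(seq_along(latent), latent, xout = pmin(pmax(t, 1), length(latent)),
              rule = 2)$y
  pmax(1 + beta * z, 0.05)
}

#' Map a latent trajectory to quantized FMS reports
#'
#' The latent value is mapped to the 1-5 report scale by a clipped affine
#' transform plus rounding, with Gaussian report noise, one report every
#' `interval_s` seconds.
#'
#' @param latent 1-Hz latent trajectory.
#' @param interval_s reporting interval (default 30 s).
#' @param noise_sd report noise before rounding.
#' @param seed integer seed.
#' @return data.frame with columns `time_s`, `fms`.
#' @export
fms_reports_from_latent <- function(latent, interval_s = 30, noise_sd = 0.25,
                                    seed = 1L) {
  times <- seq(interval_s, length(latent), by = interval_s)
  z <- latent[pmin(times, length(latent))]
  with_seed(seed, {
    raw <- 1 + 2.2 * z + rnorm(length(times), sd = noise_sd)
    data.frame(time_s = times, fms = pmin(pmax(round(raw), 1), 5))
  })
}
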