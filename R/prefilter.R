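# Zero-phase spectral filtering. Signals are even-extended (mirrored) before
# the FFT so the implied circular signal is continuous, which suppresses edge
# transients; the filter is applied as a real gain on the spectrum, giving
# exactly zero phase shift.

fft_gain_filter <- function(x, rate, gain_fun) {
  one <- function(v) {
    n <- length(v)
    ext <- c(v, rev(v))
    m <- length(ext)
    f <- (seq_len(m) - 1) * rate / m
    f <- pmin(f, rate - f) # fold negative frequencies
    g <- gain_fun(f)
    Re(fft(fft(ext) * g, inverse = TRUE) / m)[seq_len(n)]
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

#' Suppress narrowband interference (spectral notch)
#'
#' Zero-phase frequency-domain suppression: spectral content within
#' `freq +/- halfwidth` is removed for each listed frequency; the passband is
#' untouched. Used for power-line interference (60 Hz and harmonics) and the
#' 30-Hz acquisition artifact on PPG.
#'
#' @param x numeric vector or matrix (columns = channels).
#' @param rate sampling rate in Hz.
#' @param freqs notch center frequencies (each below the Nyquist rate).
#' @param halfwidth half-width of each notch in Hz.
#' @return filtered signal, same shape as `x`.
#' @export
notch_suppress <- function(x, rate, freqs, halfwidth = 1) {
  fft_gain_filter(x, rate, notch_gain(rate, freqs, halfwidth))
}

notch_gain <- function(rate, freqs, halfwidth) {
  if (any(freqs >= rate / 2)) stopf("notch frequency at or above Nyquist (%g Hz)", rate / 2)
  if (halfwidth <= 0) stopf("halfwidth must be positive")
  function(f) {
    g <- rep(1, length(f))
    for (f0 in freqs) g[abs(f - f0) <= halfwidth] <- 0
    g
  }
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain band-pass with raised-cosine transitions: unit gain inside
#' `[low, high]`, cosine roll-off over a transition band of 25% of each edge
#' frequency, zero outside. Stopband attenuation one octave outside the band
#' is complete, DC is removed whenever `low > 0`, and the response is exactly
#' zero-phase.
#'
#' @param x numeric vector or matrix (columns = channels).
#' @param rate sampling rate in Hz.
#' @param low,high band edges in Hz, `0 <= low < high < rate/2`. `low = 0`
#'   yields a pure low-pass.
#' @return filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, rate, low, high) {
  fft_gain_filter(x, rate, band_gain(rate, low, high))
}

band_gain <- function(rate, low, high) {
  nyq <- rate / 2
  if (!(low >= 0 && low < high && high < nyq)) {
    stopf("invalid band [%g, %g] Hz at rate %g Hz", low, high, rate)
  }
  tw_lo <- 0.25 * low
  tw_hi <- min(0.25 * high, 0.9 * (nyq - high))
  ramp <- function(f, a, b) { # 0 at a, 1 at b (a < b) via raised cosine
    u <- pmin(pmax((f - a) / (b - a), 0), 1)
    0.5 - 0.5 * cos(pi * u)
  }
  function(f) {
    g <- rep(1, length(f))
    if (low > 0) g <- g * ramp(f, low - tw_lo, low)
    g * (1 - ramp(f, high, high + tw_hi))
  }
}

#' Named band-pass presets
#'
#' `"ppg"` 0.1-10 Hz, `"eda"` 0.03-5 Hz, `"eeg"` 1-50 Hz, and `"ppg_wdf"`
#' 0.66-3.33 Hz (the 40-200 bpm pulse band applied before beat detection).
#'
#' @param name preset name.
#' @return numeric `c(low, high)` in Hz.
#' @export
bandpass_preset <- function(name) {
  presets <- list(ppg = c(0.1, 10), eda = c(0.03, 5), eeg = c(1, 50),
                  ppg_wdf = c(0.66, 3.33))
  if (!name %in% names(presets)) stopf("unknown band preset '%s'", name)
  presets[[name]]
}

#' Convert skin resistance to conductance
#'
#' The electrodermal sensor records skin resistance R in kilo-ohm; analyses
#' use conductance G in micro-siemens, related by G = 1/R, i.e.
#' `G_uS = 1000 / R_kOhm`.
#'
#' @param r_kohm resistance values in kilo-ohm (> 0).
#' @return conductance in micro-siemens.
#' @export
eda_resistance_to_conductance <- function(r_kohm) {
  if (any(r_kohm <= 0, na.rm = TRUE)) stopf("non-positive resistance")
  1000 / r_kohm
}

#' Common average reference for multichannel EEG
#'
#' Subtracts the per-sample mean across channels, so each output sample has
#' zero channel mean; idempotent.
#'
#' @param x numeric matrix, samples x channels (>= 2 channels).
#' @return re-referenced matrix.
#' @export
eeg_common_average_reference <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2L) stopf("common average reference needs >= 2 channels")
  x - rowMeans(x)
}

#' Pluggable EEG artifact-removal hook
#'
#' Slot for an external ICA-based artifact cleaner. The default remover is the
#' identity (the synthetic data contain no ocular artifacts). A supplied
#' `remover` must be a function taking and returning a samples-by-channels
#' matrix of identical shape; shape-changing removers are rejected.
#'
#' @param x numeric matrix, samples x channels.
#' @param remover function `matrix -> matrix`.
#' @return cleaned matrix.
#' @export
eeg_artifact_hook <- function(x, remover = identity) {
  out <- remover(x)
  if (!is.matrix(out) || !all(dim(out) == dim(x))) {
    stopf("artifact remover changed the signal shape")
  }
  out
}

#' Three-point moving average (skin temperature)
#'
#' Centered 3-point mean; at each edge the shortened 2-point mean of the
#' available neighbours is used, so no samples are added or dropped.
#'
#' @param x numeric vector of length >= 3.
#' @return smoothed vector, same length.
#' @export
skt_moving_average <- function(x) {
  n <- length(x)
  if (n < 3L) stopf("need at least 3 samples")
  out <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  out[1L] <- mean(x[1:2])
  out[n] <- mean(x[(n - 1L):n])
  out
}

#' Per-sensor preprocessing chains
#'
#' Applies the sensor's fixed chain, in order: PPG notch {30, 60} Hz then
#' band-pass 0.1-10 Hz; EDA resistance-to-conductance, notch {60} Hz,
#' band-pass 0.03-5 Hz; EEG notch {60, 120, 180, 240} Hz (+/- 5 Hz),
#' band-pass 1-50 Hz, common average reference, then the artifact hook; SKT
#' three-point moving average only. Other sensors pass through unchanged.
#' Every chain is length-preserving and deterministic.
#'
#' @param stream a [sensor_stream()].
#' @param eeg_remover artifact remover passed to [eeg_artifact_hook()].
#' @return preprocessed `sensor_stream`.
#' @export
preprocess_stream <- function(stream, eeg_remover = identity) {
  x <- stream$x
  rate <- stream$rate
  # notch and band-pass are both spectral gains, so each chain applies them
  # in a single zero-phase pass (the gains commute)
  x <- switch(stream$sensor,
    PPG = {
      b <- bandpass_preset("ppg")
      ng <- notch_gain(rate, c(30, 60), 1)
      bg <- band_gain(rate, b[1], b[2])
      fft_gain_filter(x, rate, function(f) ng(f) * bg(f))
    },
    EDA = {
      b <- bandpass_preset("eda")
      g <- eda_resistance_to_conductance(x)
      ng <- notch_gain(rate, 60, 1)
      bg <- band_gain(rate, b[1], b[2])
      fft_gain_filter(g, rate, function(f) ng(f) * bg(f))
    },
    EEG = {
      b <- bandpass_preset("eeg")
      ng <- notch_gain(rate, c(60, 120, 180, 240), 5)
      bg <- band_gain(rate, b[1], b[2])
      y <- fft_gain_filter(x, rate, function(f) ng(f) * bg(f))
      eeg_artifact_hook(eeg_common_average_reference(y), eeg_remover)
    },
    SKT = apply(x, 2, skt_moving_average),
    x
  )
  sensor_stream(stream$sensor, rate, stream$t, x, colnames(stream$x))
}

#' Preprocess all reconstructed streams of a session
#' @param streams named list of [sensor_stream()]s (from
#'   [reconstruct_session()]).
#' @param eeg_remover artifact remover for the EEG chain.
#' @return named list of preprocessed streams.
#' @export
preprocess_session <- function(streams, eeg_remover = identity) {
  lapply(streams, preprocess_stream, eeg_remover = eeg_remover)
}
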