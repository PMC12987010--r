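#' Detect pulse beats in a band-passed PPG window
#'
#' Local maxima above an adaptive threshold (mean + 0.5 SD of the window)
#' with a refractory period: peaks are accepted highest-first and any
#' candidate within `refractory_s` of an accepted beat is discarded.
#'
#' @param x numeric vector (0.66-3.33 Hz band-passed PPG).
#' @param rate sampling rate in Hz.
#' @param refractory_s minimum inter-beat spacing (default 0.3 s).
#' @return integer sample indices of detected beats, sorted.
#' @export
detect_beats <- function(x, rate, refractory_s = 0.3) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  thr <- mean(x) + 0.5 * sd(x)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n] &
                x[2:(n - 1L)] > thr) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  gap <- refractory_s * rate
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= gap)) kept <- c(kept, i)
  }
  sort(kept)
}

# Welch spectrum of the detrended inter-beat-interval series, evenly
# resampled at 4 Hz; used for the LF/HF and breath-rate WdFs.
ibi_spectrum <- function(beat_t, ibi_ms) {
  if (length(ibi_ms) < 4L) return(NULL)
  mid <- beat_t[-1L]
  ts <- seq(min(mid), max(mid), by = 1 / 4)
  if (length(ts) < 16L) return(NULL)
  y <- approx(mid, ibi_ms, xout = ts)$y
  y <- y - mean(y)
  welch_psd(y, 4, list(fft_length = 256L,
                       segment_length = min(80L, length(ts)), overlap = 0.5))
}

#' Window-derived PPG features
#'
#' Beat detection on the 0.66-3.33 Hz pre-filtered window, then HR (bpm),
#' mean IBI (ms), SDNN, RMSSD, the Poincare axes from the approximation
#' formulas SD1 = RMSSD/sqrt(2) and SD2^2 = 2 SDNN^2 - SDSD^2/2, SD1/SD2,
#' the Toichi indices CSI = L/T and CVI = log10(L x T) with T = 4 SD1 and
#' L = 4 SD2, the LF/HF ratio of the 4-Hz-resampled IBI spectrum (LF
#' 0.1-0.15 Hz, HF 0.15-0.4 Hz), and the breath rate (dominant respiratory
#' modulation of the IBI series, breaths/min, reported within [4, 60]).
#' Fewer than 5 detected beats flags every feature missing.
#'
#' @param x numeric vector (pre-filtered window signal).
#' @param rate sampling rate in Hz.
#' @return named numeric vector of the 12 WdFs (NA = missing).
#' @export
ppg_wdfs <- function(x, rate) {
  nms <- c("HR", "IBI", "SDNN", "RMSSD", "SD1", "SD2", "SD1SD2",
           "CSI", "CVI", "CSICVI", "LFHF", "BR")
  out <- setNames(rep(NA_real_, length(nms)), nms)
  beats <- detect_beats(x, rate)
  if (length(beats) < 5L) return(out)
  bt <- (beats - 1L) / rate
  ibi <- diff(bt) * 1000
  out["IBI"] <- mean(ibi)
  out["HR"] <- 60000 / mean(ibi)
  sdnn <- sd(ibi)
  sdsd <- sd(diff(ibi))
  rmssd <- sqrt(mean(diff(ibi)^2))
  out["SDNN"] <- sdnn
  out["RMSSD"] <- rmssd
  sd1 <- rmssd / sqrt(2)
  sd2 <- sqrt(max(2 * sdnn^2 - sdsd^2 / 2, 0))
  out["SD1"] <- sd1
  out["SD2"] <- sd2
  if (sd2 > 0) out["SD1SD2"] <- sd1 / sd2
  T_ <- 4 * sd1
  L_ <- 4 * sd2
  if (T_ > 0 && L_ > 0) {
    out["CSI"] <- L_ / T_
    out["CVI"] <- log10(L_ * T_)
    if (out["CVI"] != 0) out["CSICVI"] <- out["CSI"] / out["CVI"]
  }
  spec <- ibi_spectrum(bt, ibi)
  if (!is.null(spec)) {
    lf <- swf_freq_metrics(spec, c(0.1, 0.15), closed_upper = FALSE)[["bpw"]]
    hf <- swf_freq_metrics(spec, c(0.15, 0.4))[["bpw"]]
    if (hf > 0) out["LFHF"] <- lf / hf
    resp <- spec$freq >= 0.1 & spec$freq <= 0.5
    if (any(resp) && any(spec$psd[resp] > 0)) {
      f_peak <- spec$freq[resp][which.max(spec$psd[resp])]
      out["BR"] <- min(max(f_peak * 60, 4), 60)
    }
  }
  out
}
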