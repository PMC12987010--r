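#' Welch estimation parameters per sensor
#'
#' PPG/EDA (128 Hz): FFT length 8192, segment length 20 s (2560 samples), to
#' resolve narrow low-frequency bands. EEG (500 Hz): FFT length 2048, segment
#' length = FFT length (~0.24 Hz/bin). All other sensors: FFT length =
#' segment length = rate x 20 s. 50% segment overlap, Hann taper. The DC bin
#' is always excluded from band metrics and negative PSD values are clipped
#' to zero.
#'
#' @param sensor sensor name.
#' @param rate sampling rate in Hz.
#' @return list with `fft_length`, `segment_length`, `overlap`.
#' @export
welch_spec <- function(sensor, rate) {
  switch(sensor,
    PPG = ,
    EDA = list(fft_length = 8192L, segment_length = as.integer(20 * rate), overlap = 0.5),
    EEG = list(fft_length = 2048L, segment_length = 2048L, overlap = 0.5),
    list(fft_length = as.integer(round(20 * rate)),
         segment_length = as.integer(round(20 * rate)), overlap = 0.5)
  )
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Complex segment spectra for Welch-type estimates: returns a segments x bins
# matrix of one-sided FFTs of Hann-tapered segments, plus the scaling needed
# for a density PSD.
welch_segments <- function(x, rate, spec) {
  n <- length(x)
  L <- min(spec$segment_length, n)
  hop <- max(1L, as.integer(round(L * (1 - spec$overlap))))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- hann_window(L)
  nfft <- max(spec$fft_length, L)
  nb <- nfft %/% 2L + 1L
  segs <- matrix(0 + 0i, length(starts), nb)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + L - 1L)] * w
    segs[k, ] <- fft(c(seg, numeric(nfft - L)))[seq_len(nb)]
  }
  list(segs = segs, scale = 1 / (rate * sum(w^2)), nfft = nfft,
       freq = (seq_len(nb) - 1L) * rate / nfft)
}

#' Welch power spectral density
#'
#' One-sided Hann-tapered Welch estimate with the sensor's FFT/segment
#' lengths; density scaling (power per Hz). Negative values arising from
#' numerical noise are clipped to zero.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param spec a [welch_spec()] list.
#' @return list with `freq`, `psd`, `df` (bin width, Hz).
#' @export
welch_psd <- function(x, rate, spec) {
  ws <- welch_segments(x, rate, spec)
  p <- colMeans(abs(ws$segs)^2) * ws$scale
  nb <- length(p)
  p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)] # one-sided doubling, not DC/Nyquist
  list(freq = ws$freq, psd = pmax(p, 0), df = rate / ws$nfft)
}

#' Per-sensor frequency band schemes
#'
#' PPG: LF 0.1-0.15 Hz, HF 0.15-0.4 Hz (whole 0.1-10). EDA: SCL 0-0.05 Hz,
#' SCR 0.05-2 Hz, sympathetic LF 0.045-0.25 Hz (whole 0.03-5). EEG: delta
#' 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz (whole 1-50).
#'
#' @param sensor `"PPG"`, `"EDA"` or `"EEG"`.
#' @return named list of `c(low, high)` band edges, first entry `raw` = the
#'   processed whole band.
#' @export
band_scheme <- function(sensor) {
  switch(sensor,
    PPG = list(raw = c(0.1, 10), LF = c(0.1, 0.15), HF = c(0.15, 0.4)),
    EDA = list(raw = c(0.03, 5), SCL = c(0, 0.05), SCR = c(0.05, 2),
               LF = c(0.045, 0.25)),
    EEG = list(raw = c(1, 50), delta = c(1, 4), theta = c(4, 8),
               alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 50)),
    stopf("no band scheme for sensor %s", sensor)
  )
}

# Bin membership for a band on a Welch grid. DC excluded always. Interior
# edges are lower-inclusive/upper-exclusive so adjacent bands partition the
# grid; `closed_upper` includes the upper edge (used for the last band of a
# partition and for whole-band metrics).
band_bins <- function(freq, band, closed_upper = TRUE) {
  sel <- freq >= band[1] & (if (closed_upper) freq <= band[2] else freq < band[2])
  sel & freq > 0
}

#' Band power and PSD entropy from a Welch estimate
#'
#' Band power is the sum of in-band PSD bins times the bin width; PSD entropy
#' is the Shannon entropy (base 2) of the PSD normalized to unit sum over the
#' band. The DC bin never contributes.
#'
#' @param psd a [welch_psd()] result.
#' @param band numeric `c(low, high)` in Hz.
#' @param closed_upper include the upper band edge bin.
#' @return named numeric `c(bpw, pse)`.
#' @export
swf_freq_metrics <- function(psd, band, closed_upper = TRUE) {
  sel <- band_bins(psd$freq, band, closed_upper)
  if (!any(sel)) stopf("band [%g, %g] Hz contains no PSD bins", band[1], band[2])
  p <- pmax(psd$psd[sel], 0)
  total <- sum(p)
  pse <- if (total > 0) {
    q <- p[p > 0] / total
    -sum(q * log2(q))
  } else 0
  c(bpw = total * psd$df, pse = pse)
}

#' Decompose a signal into named sub-band signals or sub-band PSDs
#'
#' `mode = "time"`: zero-phase band-pass filtered copies of the signal, one
#' per band (the whole-band entry is returned unfiltered, it already carries
#' the processed band). `mode = "freq"`: the Welch PSD of the full-band
#' signal partitioned by band edges, each interior bin assigned to exactly
#' one band.
#'
#' @param x numeric vector (one processed whole-band signal).
#' @param rate sampling rate in Hz.
#' @param scheme a [band_scheme()] list.
#' @param mode `"time"` or `"freq"`.
#' @param spec Welch parameters for `mode = "freq"`.
#' @return named list of band signals, or of `list(freq, psd, df)` subsets.
#' @export
band_signals <- function(x, rate, scheme, mode = c("time", "freq"),
                         spec = NULL) {
  mode <- match.arg(mode)
  nms <- names(scheme)
  if (mode == "time") {
    out <- lapply(nms, function(nm) {
      if (nm == "raw") return(x)
      b <- scheme[[nm]]
      bandpass(x, rate, b[1], min(b[2], 0.999 * rate / 2))
    })
    names(out) <- nms
    return(out)
  }
  psd <- welch_psd(x, rate, spec %||% welch_spec("other", rate))
  out <- lapply(nms, function(nm) {
    b <- scheme[[nm]]
    sel <- band_bins(psd$freq, b, closed_upper = (nm == nms[length(nms)] || nm == "raw"))
    list(freq = psd$freq[sel], psd = psd$psd[sel], df = psd$df)
  })
  names(out) <- nms
  out
}

# Instantaneous phase of the analytic signal (FFT Hilbert transform).
hilbert_phase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(fft(x) * h, inverse = TRUE) / n)
}
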