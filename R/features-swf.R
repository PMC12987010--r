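#' Sample entropy
#'
#' Template-matching irregularity with embedding dimension `m` and tolerance
#' `r` (default 0.2 x SD of the series, the convention used throughout the
#' feature engine). Chebyshev distance, self-matches excluded. A
#' zero-variance series has entropy 0 (the tolerance degenerates to exact
#' matching, which every template satisfies).
#'
#' @param x numeric vector.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return sample entropy (nats), `NA` if the series is too short or has no
#'   recurrent templates at length `m + 1`.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  x <- x[is.finite(x)]
  if (length(x) < m + 2L) return(NA_real_)
  sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Split an effective session into aligned analysis windows
#'
#' Non-overlapping `length_s`-second windows starting at t = 0;
#' `floor(effective_length / length_s)` of them (an 1140-s session yields 38).
#' Discontinuity times (fragment seams surviving preprocessing) split each
#' window into segments that are processed separately downstream.
#'
#' @param effective_length_s effective session length in seconds.
#' @param length_s window length (default 30 s).
#' @param seams numeric vector of discontinuity times in effective seconds.
#' @return object of class `window_set`: list of windows, each with `start`,
#'   `end` and `segments` (list of `c(from, to)` spans).
#' @export
windowize <- function(effective_length_s, length_s = 30, seams = numeric(0)) {
  if (effective_length_s < length_s) {
    stopf("session (%g s) shorter than one window (%g s)", effective_length_s, length_s)
  }
  n <- floor(effective_length_s / length_s)
  windows <- lapply(seq_len(n), function(i) {
    s <- (i - 1) * length_s
    e <- i * length_s
    cuts <- sort(seams[seams > s & seams < e])
    bounds <- c(s, cuts, e)
    segs <- lapply(seq_len(length(bounds) - 1L),
                   function(k) c(bounds[k], bounds[k + 1L]))
    list(start = s, end = e, segments = segs)
  })
  structure(list(length_s = length_s, windows = windows, n = n),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d x %g-s windows>\n", x$n, x$length_s))
  invisible(x)
}

#' Time-weighted FMS value of a window
#'
#' FMS reports form a piecewise-constant severity trajectory (each report
#' holds until the next; the first report also covers any earlier time). The
#' window value is the integral of that trajectory over the window divided by
#' the window length.
#'
#' @param reports data.frame with `time_s` and `fms` columns.
#' @param start,end window span in seconds.
#' @return time-weighted mean FMS over the window.
#' @export
map_fms <- function(reports, start, end) {
  if (!nrow(reports)) stopf("no FMS reports")
  if (min(reports$time_s) > end) stopf("no FMS report at or before window end")
  ord <- order(reports$time_s)
  tt <- reports$time_s[ord]
  vv <- reports$fms[ord]
  knots <- sort(unique(c(start, end, tt[tt > start & tt < end])))
  val_at <- function(t) {
    i <- findInterval(t, tt)
    vv[pmax(i, 1L)] # before the first report, its value extends backward
  }
  mids <- head(knots, -1L)
  widths <- diff(knots)
  sum(val_at(mids) * widths) / (end - start)
}

#' Time-domain signal-wise feature template
#'
#' Mean, variance (n-1 denominator), excess kurtosis, skewness, sample
#' entropy (m = 2, r = 0.2 x segment SD) and peak-to-peak amplitude, computed
#' per segment and averaged across a window's segments. Non-finite samples
#' (e.g. vergence-loss frames) are excluded; skewness/kurtosis of a
#' zero-variance segment are undefined and propagate as `NA`.
#'
#' @param segments list of numeric vectors (one per window segment).
#' @param sampen_rate optional decimation: compute sample entropy on every
#'   `sampen_rate`-th sample (1 = no decimation).
#' @param sampen set `FALSE` to skip the (quadratic-cost) sample entropy;
#'   its slot is then `NA`.
#' @return named numeric vector `avg, var, kut, skw, sampen, ptp`.
#' @export
swf_time <- function(segments, sampen_rate = 1L, sampen = TRUE) {
  per_seg <- vapply(segments, function(s) {
    s <- s[is.finite(s)]
    n <- length(s)
    if (n < 4L) return(rep(NA_real_, 6L))
    mu <- mean(s)
    d <- s - mu
    m2 <- mean(d^2)
    v <- var(s)
    skw <- if (m2 > 0) mean(d^3) / m2^1.5 else NA_real_
    kut <- if (m2 > 0) mean(d^4) / m2^2 - 3 else NA_real_
    se_in <- if (sampen_rate > 1L) s[seq(1L, n, by = sampen_rate)] else s
    se <- if (sampen) sample_entropy(se_in) else NA_real_
    c(avg = mu, var = v, kut = kut, skw = skw, sampen = se,
      ptp = max(s) - min(s))
  }, numeric(6L))
  out <- rowMeans(per_seg, na.rm = TRUE) # short residual segments drop out
  out[!is.finite(out)] <- NA_real_
  names(out) <- c("avg", "var", "kut", "skw", "sampen", "ptp")
  out
}

#' Frequency-domain signal-wise feature template for one window
#'
#' Welch PSD per segment (DC excluded, negatives clipped), band power and PSD
#' entropy per band, averaged across segments.
#'
#' @param segments list of numeric vectors.
#' @param rate sampling rate in Hz.
#' @param spec a [welch_spec()] list.
#' @param scheme a [band_scheme()] list, or `NULL` for whole-band only (band
#'   = the full DC-excluded Welch range).
#' @return matrix bands x `c(bpw, pse)`.
#' @export
swf_freq <- function(segments, rate, spec, scheme = NULL) {
  bands <- scheme %||% list(raw = c(0, rate / 2))
  nms <- names(bands)
  acc <- matrix(0, length(nms), 2L, dimnames = list(nms, c("bpw", "pse")))
  nseg <- 0L
  for (s in segments) {
    s <- s[is.finite(s)]
    if (length(s) < 8L) next
    psd <- welch_psd(s, rate, spec)
    vals <- t(vapply(seq_along(nms), function(i) {
      swf_freq_metrics(psd, bands[[i]],
                       closed_upper = (i == length(nms) || nms[i] == "raw"))
    }, numeric(2L)))
    acc <- acc + vals
    nseg <- nseg + 1L
  }
  if (nseg == 0L) acc[] <- NA_real_ else acc <- acc / nseg
  acc
}

# Extract sample indices of a segment span from a grid-aligned signal.
segment_slice <- function(x, rate, span) {
  i0 <- floor(span[1] * rate) + 1L
  i1 <- min(floor(span[2] * rate), length(x))
  if (i0 > i1) return(numeric(0))
  x[i0:i1]
}
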