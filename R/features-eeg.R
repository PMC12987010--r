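eeg_regions <- function() {
  list(global = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
       frontal = c("F3", "F4"), central = c("C3", "C4"),
       parietal = c("P3", "P4"), occipital = c("O1", "O2"))
}

#' Region-averaged EEG band signals
#'
#' Averages the channel signals within each scalp region (global = all 8,
#' frontal F3/F4, central C3/C4, parietal P3/P4, occipital O1/O2), then
#' decomposes each region signal into the whole band plus the 5 standard
#' bands by zero-phase band-pass filtering: 5 regions x 6 bands = 30 signals.
#'
#' @param x numeric matrix, samples x 8 named channels (F3, F4, C3, C4, P3,
#'   P4, O1, O2).
#' @param rate sampling rate in Hz.
#' @return named list of 30 numeric vectors, names `<band>_<region>` with
#'   band `raw` for the whole processed band.
#' @export
eeg_region_band_signals <- function(x, rate) {
  regions <- eeg_regions()
  missing <- setdiff(regions$global, colnames(x))
  if (length(missing)) stopf("missing EEG channel(s): %s", paste(missing, collapse = ", "))
  scheme <- band_scheme("EEG")
  out <- list()
  for (rg in names(regions)) {
    sig <- rowMeans(x[, regions[[rg]], drop = FALSE])
    bs <- band_signals(sig, rate, scheme, mode = "time")
    for (bd in names(bs)) out[[paste(bd, rg, sep = "_")]] <- bs[[bd]]
  }
  out
}

#' EEG band-power ratios
#'
#' The seven ratios beta/alpha, (alpha+theta)/beta, theta/alpha, theta/beta,
#' (alpha+theta)/(alpha+beta), beta/(alpha+theta), and F-theta/P-alpha
#' (frontal theta power over parietal alpha power). A zero denominator flags
#' that ratio missing.
#'
#' @param global named numeric vector of global-region band powers with at
#'   least `theta`, `alpha`, `beta`.
#' @param frontal_theta frontal theta band power.
#' @param parietal_alpha parietal alpha band power.
#' @return named numeric vector of 7 ratios.
#' @export
eeg_power_ratios <- function(global, frontal_theta, parietal_alpha) {
  th <- global[["theta"]]; al <- global[["alpha"]]; be <- global[["beta"]]
  safe <- function(num, den) if (is.finite(den) && den > 0) num / den else NA_real_
  c(beta_alpha = safe(be, al),
    alphatheta_beta = safe(al + th, be),
    theta_alpha = safe(th, al),
    theta_beta = safe(th, be),
    alphatheta_alphabeta = safe(al + th, al + be),
    beta_alphatheta = safe(be, al + th),
    Ftheta_Palpha = safe(frontal_theta, parietal_alpha))
}

#' Magnitude-squared coherence between all channel pairs, per band
#'
#' Welch cross-spectral coherence of the full-band channel signals over one
#' window, averaged over the in-band bins for each band. Requires at least 2
#' Welch segments; shorter windows flag coherence missing.
#'
#' @param xw numeric matrix (window samples x channels).
#' @param rate sampling rate in Hz.
#' @param spec a [welch_spec()] list.
#' @param scheme a [band_scheme()] list.
#' @return matrix of `choose(nch, 2)` rows (named `"A-B"`) x bands.
#' @export
eeg_coherence <- function(xw, rate, spec, scheme) {
  ch <- colnames(xw)
  pairs <- utils::combn(ch, 2L)
  bands <- names(scheme)
  out <- matrix(NA_real_, ncol(pairs), length(bands),
                dimnames = list(paste(pairs[1L, ], pairs[2L, ], sep = "-"), bands))
  ws <- lapply(ch, function(c1) welch_segments(xw[, c1], rate, spec))
  names(ws) <- ch
  if (nrow(ws[[1L]]$segs) < 2L) return(out)
  freq <- ws[[1L]]$freq
  auto <- lapply(ws, function(w) colMeans(abs(w$segs)^2))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    sxy <- colMeans(ws[[a]]$segs * Conj(ws[[b]]$segs))
    msc <- Mod(sxy)^2 / pmax(auto[[a]] * auto[[b]], .Machine$double.eps)
    for (bi in seq_along(bands)) {
      sel <- band_bins(freq, scheme[[bands[bi]]],
                       closed_upper = (bi == length(bands) || bands[bi] == "raw"))
      out[p, bi] <- mean(msc[sel])
    }
  }
  out
}

#' Phase locking value between channel phases
#'
#' PLV = |mean over samples of exp(i (phi_a - phi_b))| with instantaneous
#' phases from the analytic signal of the band-filtered channels.
#'
#' @param phases numeric matrix (samples x channels) of instantaneous phases.
#' @return named numeric vector over channel pairs `"A-B"`, values in [0, 1].
#' @export
plv_pairs <- function(phases) {
  ch <- colnames(phases)
  pairs <- utils::combn(ch, 2L)
  vapply(seq_len(ncol(pairs)), function(p) {
    dphi <- phases[, pairs[1L, p]] - phases[, pairs[2L, p]]
    dphi <- dphi[is.finite(dphi)]
    if (!length(dphi)) return(NA_real_)
    Mod(mean(exp(1i * dphi)))
  }, numeric(1)) |>
    setNames(paste(pairs[1L, ], pairs[2L, ], sep = "-"))
}
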