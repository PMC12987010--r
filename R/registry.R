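swf_feature_names <- function() c("avg", "var", "kut", "skw", "sampen", "ptp",
                                  "bpw", "pse")

swf_kind <- function(feature) {
  ifelse(feature %in% c("bpw", "pse"), "SwF-freq", "SwF-time")
}

swf_block <- function(domain, signals) {
  feats <- swf_feature_names()
  g <- expand.grid(feature = feats, signal = signals,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(domain = domain, signal = g$signal,
             band = ifelse(g$signal %in% c("raw", "LF", "HF", "SCL", "SCR"),
                           g$signal, "whole"),
             feature = g$feature, kind = swf_kind(g$feature),
             stringsAsFactors = FALSE)
}

wdf_block <- function(domain, signal, features, band = "whole") {
  data.frame(domain = domain, signal = signal, band = band, feature = features,
             kind = "WdF", stringsAsFactors = FALSE)
}

#' The full feature registry
#'
#' Enumerates every descriptor the extraction engine can produce. The
#' signal-wise template contributes 8 features (6 time + 2 frequency) per
#' source signal, uniformly: PPG 3 band signals + 12 WdFs; EDA 4 band
#' signals; EEG 30 region-band signals + 7 power ratios + 336 functional
#' brain network WdFs (6 bands x 28 channel pairs x {coherence, PLV}); SKT 1
#' signal; Eye 6 signals + 7 WdFs; HeadPose 8 signals; HeadIMU 6 signals;
#' plus 2 demographic variables. 828 descriptors in total, of which 583 are
#' EEG.
#'
#' @return data.frame with columns `id`, `domain`, `signal`, `band`,
#'   `feature`, `kind`; `id` unique.
#' @export
feature_registry <- function() {
  eeg_bands <- c("raw", names(band_scheme("EEG"))[-1L])
  eeg_signals <- as.vector(t(outer(eeg_bands, names(eeg_regions()), paste, sep = "_")))
  pairs <- utils::combn(eeg_regions()$global, 2L)
  pair_names <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
  fbn <- expand.grid(metric = c("coh", "plv"), pair = pair_names,
                     band = eeg_bands, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  reg <- rbind(
    swf_block("PPG", c("raw", "LF", "HF")),
    wdf_block("PPG", "Derived",
              c("HR", "IBI", "SDNN", "RMSSD", "SD1", "SD2", "SD1SD2",
                "CSI", "CVI", "CSICVI", "LFHF", "BR")),
    swf_block("EDA", c("raw", "SCL", "SCR", "LF")),
    {
      b <- swf_block("EEG", eeg_signals)
      b$band <- sub("_.*$", "", b$signal)
      b
    },
    wdf_block("EEG", "ratio",
              c("beta_alpha", "alphatheta_beta", "theta_alpha", "theta_beta",
                "alphatheta_alphabeta", "beta_alphatheta", "Ftheta_Palpha")),
    data.frame(domain = "EEG", signal = paste0("fbn_", fbn$band),
               band = fbn$band, feature = paste(fbn$pair, fbn$metric, sep = "_"),
               kind = "WdF", stringsAsFactors = FALSE),
    swf_block("SKT", "raw"),
    swf_block("Eye", c("closureAnd", "closureOr", "convDist",
                       "gazeYaw", "gazePitch", "gazeVel")),
    wdf_block("Eye", "Derived",
              c("blinkRate", "vergenceLoss", "saccadeRatio", "fixationRatio",
                "pathLength", "heatmapEntropy", "vor")),
    swf_block("HeadPose", c("posSway", "posHeave", "posSurge",
                            "rotPitch", "rotYaw", "rotRoll",
                            "dirYaw", "dirPitch")),
    swf_block("HeadIMU", c("accSway", "accHeave", "accSurge",
                           "gyrPitch", "gyrYaw", "gyrRoll")),
    data.frame(domain = "Demographic", signal = c("gender", "susceptibility"),
               band = "none", feature = c("gender", "susceptibility"),
               kind = "Demographic", stringsAsFactors = FALSE)
  )
  reg$id <- paste(reg$domain, reg$signal, reg$feature, sep = "_")
  demo <- reg$kind == "Demographic"
  reg$id[demo] <- paste0("Demographic_", reg$feature[demo])
  stopifnot(!anyDuplicated(reg$id))
  rownames(reg) <- NULL
  reg[, c("id", "domain", "signal", "band", "feature", "kind")]
}
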