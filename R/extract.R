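# Windowed feature extraction over preprocessed, grid-aligned streams. The
# engine walks the registry: only descriptors listed in `include` (or all,
# when NULL) are computed, so callers can restrict extraction to a feature
# subset without touching the heavy EEG connectivity or entropy paths.

#' Extract the windowed feature table of one session
#'
#' Applies the signal-wise template (6 time + 2 frequency features) uniformly
#' to every source signal of the available streams, plus the window-derived
#' features of each domain, over `floor(effective_length / 30)` aligned 30-s
#' windows. Fragment seams split windows into segments that are processed
#' separately and averaged.
#'
#' @param streams named list of preprocessed grid-aligned [sensor_stream()]s.
#' @param fms_reports data.frame of FMS reports (`time_s` on the effective
#'   timeline, `fms`), or `NULL`.
#' @param effective_length_s effective session length (seconds).
#' @param seams named list (per sensor) of discontinuity times, seconds.
#' @param include character vector of registry descriptor ids to compute
#'   (`NULL` = every descriptor whose domain has a stream available).
#' @param window_length_s window length (default 30 s).
#' @param demographics optional named numeric `c(gender, susceptibility)`
#'   encoded 0/1, emitted as constant per-window features.
#' @return list with `features` (long data.frame: `window`, `id`, `value`,
#'   `missing`) and `fms` (per-window time-weighted FMS, or `NULL`).
#' @export
extract_session_features <- function(streams, fms_reports, effective_length_s,
                                     seams = list(), include = NULL,
                                     window_length_s = 30,
                                     demographics = NULL) {
  acc_w <- list(); acc_id <- list(); acc_v <- list(); k <- 0L
  push <- function(w, ids, vals) {
    if (!length(ids)) return(invisible())
    k <<- k + 1L
    acc_w[[k]] <<- rep(w, length(ids)); acc_id[[k]] <<- ids
    acc_v[[k]] <<- as.numeric(vals)
    invisible()
  }
  want <- function(ids) if (is.null(include)) ids else ids[ids %in% include]
  wins_of <- function(sensor) {
    windowize(effective_length_s, window_length_s, seams[[sensor]] %||% numeric(0))
  }
  seg_list <- function(x, rate, win) {
    lapply(win$segments, function(sp) segment_slice(x, rate, sp))
  }
  time_feats <- c("avg", "var", "kut", "skw", "sampen", "ptp")

  do_time <- function(ids6, x, rate, wins, dec = 1L) {
    sel <- want(ids6)
    if (!length(sel)) return(invisible())
    need_se <- any(grepl("_sampen$", sel))
    for (w in seq_len(wins$n)) {
      v <- swf_time(seg_list(x, rate, wins$windows[[w]]),
                    sampen_rate = dec, sampen = need_se)
      names(v) <- ids6
      push(w, sel, v[sel])
    }
  }
  do_freq_scheme <- function(id_mat, xraw, rate, wins, spec, scheme) {
    sel <- want(as.vector(id_mat))
    if (!length(sel)) return(invisible())
    out_per_win <- vector("list", wins$n)
    for (w in seq_len(wins$n)) {
      m <- swf_freq(seg_list(xraw, rate, wins$windows[[w]]), rate, spec, scheme)
      v <- as.vector(m)
      names(v) <- as.vector(id_mat)
      push(w, sel, v[sel])
      out_per_win[[w]] <- m
    }
    invisible(out_per_win)
  }
  freq_ids <- function(domain, band_names, signal_suffix = NULL) {
    sig <- if (is.null(signal_suffix)) band_names else paste(band_names, signal_suffix, sep = "_")
    matrix(c(paste(domain, sig, "bpw", sep = "_"),
             paste(domain, sig, "pse", sep = "_")),
           ncol = 2L, dimnames = list(band_names, c("bpw", "pse")))
  }

  # ---- PPG / EDA: band-signal template + PPG WdFs -------------------------
  for (sensor in c("PPG", "EDA")) {
    st <- streams[[sensor]]
    if (is.null(st)) next
    wins <- wins_of(sensor)
    scheme <- band_scheme(sensor)
    spec <- welch_spec(sensor, st$rate)
    x <- st$x[, 1L]
    for (bd in names(scheme)) {
      ids6 <- paste(sensor, bd, time_feats, sep = "_")
      if (!length(want(ids6))) next
      xb <- if (bd == "raw") x else {
        b <- scheme[[bd]]
        bandpass(x, st$rate, b[1], min(b[2], 0.999 * st$rate / 2))
      }
      do_time(ids6, xb, st$rate, wins,
              dec = max(1L, as.integer(st$rate / 16))) # entropy at ~16 Hz
    }
    do_freq_scheme(freq_ids(sensor, names(scheme)), x, st$rate, wins, spec, scheme)
    if (sensor == "PPG") {
      wdf_ids <- paste("PPG_Derived",
                       c("HR", "IBI", "SDNN", "RMSSD", "SD1", "SD2", "SD1SD2",
                         "CSI", "CVI", "CSICVI", "LFHF", "BR"), sep = "_")
      sel <- want(wdf_ids)
      if (length(sel)) {
        b <- bandpass_preset("ppg_wdf")
        xw <- bandpass(x, st$rate, b[1], b[2])
        for (w in seq_len(wins$n)) {
          seg <- segment_slice(xw, st$rate,
                               c(wins$windows[[w]]$start, wins$windows[[w]]$end))
          v <- ppg_wdfs(seg, st$rate)
          names(v) <- wdf_ids
          push(w, sel, v[sel])
        }
      }
    }
  }

  # ---- EEG: 30 region-band signals, ratios, FBN ---------------------------
  st <- streams$EEG
  if (!is.null(st)) {
    wins <- wins_of("EEG")
    scheme <- band_scheme("EEG")
    spec <- welch_spec("EEG", st$rate)
    bands <- names(scheme)
    regions <- names(eeg_regions())
    rb_ids <- as.vector(outer(bands, regions, paste, sep = "_"))
    time_wanted <- want(as.vector(outer(paste0("EEG_", rb_ids), time_feats, paste, sep = "_")))
    freq_wanted <- want(as.vector(outer(paste0("EEG_", rb_ids), c("bpw", "pse"), paste, sep = "_")))
    ratio_ids <- paste0("EEG_ratio_",
                        c("beta_alpha", "alphatheta_beta", "theta_alpha",
                          "theta_beta", "alphatheta_alphabeta",
                          "beta_alphatheta", "Ftheta_Palpha"))
    ratio_wanted <- want(ratio_ids)
    pairs <- utils::combn(colnames(st$x), 2L)
    pair_names <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
    coh_ids <- lapply(bands, function(bd) paste0("EEG_fbn_", bd, "_", pair_names, "_coh"))
    plv_ids <- lapply(bands, function(bd) paste0("EEG_fbn_", bd, "_", pair_names, "_plv"))
    names(coh_ids) <- names(plv_ids) <- bands
    coh_wanted <- want(unlist(coh_ids))
    plv_wanted <- want(unlist(plv_ids))

    if (length(time_wanted)) {
      for (rg in regions) {
        rg_ids <- paste0("EEG_", bands, "_", rg)
        if (!length(want(as.vector(outer(rg_ids, time_feats, paste, sep = "_"))))) next
        xr <- rowMeans(st$x[, eeg_regions()[[rg]], drop = FALSE])
        for (bd in bands) {
          ids6 <- paste("EEG", paste(bd, rg, sep = "_"), time_feats, sep = "_")
          if (!length(want(ids6))) next
          xb <- if (bd == "raw") xr else {
            b <- scheme[[bd]]
            bandpass(xr, st$rate, b[1], min(b[2], 0.999 * st$rate / 2))
          }
          do_time(ids6, xb, st$rate, wins,
                  dec = max(1L, as.integer(st$rate / 125))) # entropy at 125 Hz
        }
      }
    }
    if (length(freq_wanted) || length(ratio_wanted)) {
      # per-region whole-band PSD partitioned into the 6 bands
      region_bp <- list()
      for (rg in regions) {
        xr <- rowMeans(st$x[, eeg_regions()[[rg]], drop = FALSE])
        idm <- freq_ids("EEG", bands, rg)
        bp <- matrix(NA_real_, wins$n, length(bands), dimnames = list(NULL, bands))
        for (w in seq_len(wins$n)) {
          m <- swf_freq(seg_list(xr, st$rate, wins$windows[[w]]), st$rate, spec, scheme)
          v <- as.vector(m); names(v) <- as.vector(idm)
          push(w, want(as.vector(idm)), v[want(as.vector(idm))])
          bp[w, ] <- m[, "bpw"]
        }
        region_bp[[rg]] <- bp
      }
      if (length(ratio_wanted)) {
        for (w in seq_len(wins$n)) {
          r <- eeg_power_ratios(region_bp$global[w, ],
                                region_bp$frontal[w, "theta"],
                                region_bp$parietal[w, "alpha"])
          names(r) <- ratio_ids
          push(w, ratio_wanted, r[ratio_wanted])
        }
      }
    }
    if (length(coh_wanted)) {
      for (w in seq_len(wins$n)) {
        win <- wins$windows[[w]]
        i0 <- floor(win$start * st$rate) + 1L
        i1 <- min(floor(win$end * st$rate), nrow(st$x))
        cohm <- eeg_coherence(st$x[i0:i1, , drop = FALSE], st$rate, spec, scheme)
        for (bd in bands) {
          ids <- coh_ids[[bd]]
          sel <- want(ids)
          if (length(sel)) {
            v <- cohm[, bd]; names(v) <- ids
            push(w, sel, v[sel])
          }
        }
      }
    }
    if (length(plv_wanted)) {
      for (bd in bands) {
        sel <- want(plv_ids[[bd]])
        if (!length(sel)) next
        b <- scheme[[bd]]
        phases <- apply(st$x, 2, function(ch) {
          y <- if (bd == "raw") ch else bandpass(ch, st$rate, b[1], min(b[2], 0.999 * st$rate / 2))
          hilbert_phase(y)
        })
        for (w in seq_len(wins$n)) {
          win <- wins$windows[[w]]
          i0 <- floor(win$start * st$rate) + 1L
          i1 <- min(floor(win$end * st$rate), nrow(phases))
          v <- plv_pairs(phases[i0:i1, , drop = FALSE])
          names(v) <- plv_ids[[bd]]
          push(w, sel, v[sel])
        }
      }
    }
  }

  # ---- SKT ----------------------------------------------------------------
  st <- streams$SKT
  if (!is.null(st)) {
    wins <- wins_of("SKT")
    do_time(paste("SKT_raw", time_feats, sep = "_"), st$x[, 1L], st$rate, wins)
    do_freq_scheme(freq_ids("SKT", "raw"), st$x[, 1L], st$rate, wins,
                   welch_spec("SKT", st$rate), NULL)
  }

  # ---- HeadPose / HeadIMU -------------------------------------------------
  st <- streams$HeadPose
  if (!is.null(st)) {
    wins <- wins_of("HeadPose")
    for (chn in c("posSway", "posHeave", "posSurge", "rotPitch", "rotYaw", "rotRoll")) {
      do_time(paste("HeadPose", chn, time_feats, sep = "_"), st$x[, chn], st$rate, wins)
      idm <- matrix(paste("HeadPose", chn, c("bpw", "pse"), sep = "_"), 1L, 2L,
                    dimnames = list("raw", c("bpw", "pse")))
      do_freq_scheme(idm, st$x[, chn], st$rate, wins, welch_spec("HeadPose", st$rate), NULL)
    }
    dir_ids <- c(outer(paste0("HeadPose_", c("dirYaw", "dirPitch")),
                       c(time_feats, "bpw", "pse"), paste, sep = "_"))
    if (length(want(dir_ids))) {
      rate <- st$rate
      spec <- welch_spec("HeadPose", rate)
      for (w in seq_len(wins$n)) {
        win <- wins$windows[[w]]
        i0 <- floor(win$start * rate) + 1L
        i1 <- min(floor(win$end * rate), nrow(st$x))
        hd <- head_direction_signals(st$x[i0:i1, c("rotPitch", "rotYaw", "rotRoll")])
        for (sig in c("dirYaw", "dirPitch")) {
          a <- if (sig == "dirYaw") hd$yaw else hd$pitch
          ids_t <- paste("HeadPose", sig, time_feats, sep = "_")
          sel <- want(ids_t)
          if (length(sel)) {
            v <- swf_time(list(a), sampen = any(grepl("_sampen$", sel)))
            names(v) <- ids_t
            push(w, sel, v[sel])
          }
          ids_f <- paste("HeadPose", sig, c("bpw", "pse"), sep = "_")
          self <- want(ids_f)
          if (length(self)) {
            m <- swf_freq(list(a), rate, spec, NULL)
            v <- as.vector(m); names(v) <- ids_f
            push(w, self, v[self])
          }
        }
      }
    }
  }
  st <- streams$HeadIMU
  if (!is.null(st)) {
    wins <- wins_of("HeadIMU")
    for (chn in colnames(st$x)) {
      do_time(paste("HeadIMU", chn, time_feats, sep = "_"), st$x[, chn], st$rate, wins)
      idm <- matrix(paste("HeadIMU", chn, c("bpw", "pse"), sep = "_"), 1L, 2L,
                    dimnames = list("raw", c("bpw", "pse")))
      do_freq_scheme(idm, st$x[, chn], st$rate, wins, welch_spec("HeadIMU", st$rate), NULL)
    }
  }

  # ---- Eye ----------------------------------------------------------------
  st <- streams$Eye
  if (!is.null(st)) {
    wins <- wins_of("Eye")
    rate <- st$rate
    spec <- welch_spec("Eye", rate)
    gx <- function(pfx) st$x[, paste0(pfx, c("x", "y", "z")), drop = FALSE]
    csl <- denoise_closure(eye_closure(gx("posL"), gx("posC")))
    csr <- denoise_closure(eye_closure(gx("posR"), gx("posC")))
    comb <- closure_combination(csl, csr)
    # grid interpolation denormalizes direction vectors slightly; the
    # renormalization inside convergence_distance is expected here
    conv <- suppressWarnings(
      convergence_distance(gx("posL"), gx("posR"), gx("dirL"), gx("dirR")))
    dc <- gx("dirC")
    dc_ok <- is.finite(dc[, 1L])
    ang <- gaze_angles(ifelse(is.finite(dc), dc, 1 / sqrt(3))) # placeholder rows
    ang$yaw[!dc_ok] <- NA_real_
    ang$pitch[!dc_ok] <- NA_real_
    gv_all <- gaze_velocity(dc, rate)$velocity
    src <- list(closureAnd = as.numeric(comb$and), closureOr = as.numeric(comb$or),
                convDist = conv, gazeYaw = ang$yaw, gazePitch = ang$pitch,
                gazeVel = gv_all)
    for (nm in names(src)) {
      do_time(paste("Eye", nm, time_feats, sep = "_"), src[[nm]], rate, wins)
      idm <- matrix(paste("Eye", nm, c("bpw", "pse"), sep = "_"), 1L, 2L,
                    dimnames = list("raw", c("bpw", "pse")))
      xf <- src[[nm]]
      if (anyNA(xf)) { # spectral template needs a gap-free series
        ok <- is.finite(xf)
        xf <- if (sum(ok) >= 2L) approx(which(ok), xf[ok], xout = seq_along(xf),
                                        rule = 2)$y else xf
      }
      do_freq_scheme(idm, xf, rate, wins, spec, NULL)
    }
    wdf_ids <- paste0("Eye_Derived_",
                      c("blinkRate", "vergenceLoss", "saccadeRatio",
                        "fixationRatio", "pathLength", "heatmapEntropy", "vor"))
    sel <- want(wdf_ids)
    if (length(sel)) {
      head_st <- streams$HeadPose
      for (w in seq_len(wins$n)) {
        win <- wins$windows[[w]]
        i0 <- floor(win$start * rate) + 1L
        i1 <- min(floor(win$end * rate), nrow(st$x))
        idxs <- i0:i1
        gvw <- gaze_velocity(dc[idxs, , drop = FALSE], rate)
        vor_v <- NA_real_
        if (!is.null(head_st) && head_st$rate == rate) {
          hd <- head_direction_signals(head_st$x[idxs, c("rotPitch", "rotYaw", "rotRoll")])
          hv <- gaze_velocity(hd$dir, rate)$velocity
          vor_v <- vor(gvw$velocity, hv)
        }
        v <- c(blink_rate(csl[idxs], csr[idxs], win$end - win$start),
               mean(!is.finite(conv[idxs])),
               gvw$saccade_ratio, gvw$fixation_ratio, gvw$path_length,
               if (any(is.finite(ang$yaw[idxs]) & is.finite(ang$pitch[idxs]))) {
                 heatmap_entropy(ang$yaw[idxs], ang$pitch[idxs])
               } else NA_real_,
               vor_v)
        names(v) <- wdf_ids
        push(w, sel, v[sel])
      }
    }
  }

  # ---- Demographics -------------------------------------------------------
  if (!is.null(demographics)) {
    ids <- paste0("Demographic_", c("gender", "susceptibility"))
    sel <- want(ids)
    if (length(sel)) {
      nwin <- floor(effective_length_s / window_length_s)
      v <- c(demographics[["gender"]], demographics[["susceptibility"]])
      names(v) <- ids
      for (w in seq_len(nwin)) push(w, sel, v[sel])
    }
  }

  features <- data.frame(window = unlist(acc_w), id = unlist(acc_id),
                         value = unlist(acc_v), stringsAsFactors = FALSE)
  features$missing <- !is.finite(features$value)
  fms <- NULL
  if (!is.null(fms_reports)) {
    nwin <- floor(effective_length_s / window_length_s)
    fms <- vapply(seq_len(nwin), function(w) {
      map_fms(fms_reports, (w - 1) * window_length_s, w * window_length_s)
    }, numeric(1))
  }
  list(features = features, fms = fms)
}
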