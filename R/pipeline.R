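#' End-to-end processing of one synthetic session
#'
#' Timeline reconstruction (merge, trim, grid alignment), per-sensor
#' preprocessing, and windowed feature extraction with the FMS reports
#' shifted onto the effective (trimmed) timeline.
#'
#' @param session a `session_record`.
#' @param include registry descriptor ids to compute (`NULL` = all available).
#' @param sensors sensor subset to reconstruct (`NULL` = all in the session).
#' @param trim_s edge trim (default 30 s).
#' @param window_length_s analysis window (default 30 s).
#' @param demographics optional named numeric `c(gender, susceptibility)`.
#' @return list with `features` (long df), `fms` (per window), `report`
#'   (reconstruction report).
#' @export
process_session <- function(session, include = NULL, sensors = NULL,
                            trim_s = 30, window_length_s = 30,
                            demographics = NULL) {
  if (!is.null(sensors)) {
    session$streams <- session$streams[intersect(names(session$streams), sensors)]
  }
  rec <- reconstruct_session(session, trim_s = trim_s)
  streams <- preprocess_session(rec$streams)
  eff <- session$session_length_s - 2 * trim_s
  seams <- lapply(names(session$streams), function(sn) {
    k <- length(session$streams[[sn]])
    if (k < 2L) return(numeric(0))
    # seam times on the effective timeline
    ends <- vapply(session$streams[[sn]][-k], function(f) max(f$t), numeric(1))
    starts <- vapply(session$streams[[sn]][-1L], function(f) min(f$t), numeric(1))
    s <- (ends + starts) / 2 - trim_s
    s[s > 0 & s < eff]
  })
  names(seams) <- names(session$streams)
  fms <- session$fms
  fms$time_s <- fms$time_s - trim_s
  res <- extract_session_features(streams, fms, eff, seams = seams,
                                  include = include,
                                  window_length_s = window_length_s,
                                  demographics = demographics)
  list(features = res$features, fms = res$fms, report = rec$report)
}

# Sensors required to compute a set of registry descriptors.
sensors_for <- function(include, registry = feature_registry()) {
  if (is.null(include)) return(NULL)
  dom <- unique(registry$domain[registry$id %in% include])
  sensors <- setdiff(dom, "Demographic")
  if ("Eye" %in% sensors) sensors <- union(sensors, "HeadPose") # VOR needs head
  sensors
}

#' Windowed feature table of a whole cohort
#'
#' Runs [process_session()] over every session and stacks the results into
#' the long feature table plus the per-window FMS targets; demographic
#' descriptors are derived from each participant's generated gender and MSSQ
#' scoring (merged normal/high susceptibility group).
#'
#' @param cohort a [generate_cohort()] result.
#' @param include registry ids to compute (`NULL` = all).
#' @param trim_s,window_length_s see [process_session()].
#' @return list with `features` (long df: participant, ms_type, window, id,
#'   value, missing) and `fms` (df: participant, ms_type, window, fms).
#' @export
cohort_feature_table <- function(cohort, include = NULL, trim_s = 30,
                                 window_length_s = 30) {
  sensors <- sensors_for(include)
  feats <- list(); targets <- list(); i <- 0L
  for (key in names(cohort$sessions)) {
    sess <- cohort$sessions[[key]]
    demo <- NULL
    need_demo <- is.null(include) || any(grepl("^Demographic_", include))
    if (need_demo) {
      ms <- score_mssq(sess$questionnaires$mssq$child, sess$questionnaires$mssq$adult)
      demo <- c(gender = as.numeric(sess$gender),
                susceptibility = as.numeric(ms$merged_group == "high"))
    }
    res <- process_session(sess, include = include, sensors = sensors,
                           trim_s = trim_s, window_length_s = window_length_s,
                           demographics = demo)
    i <- i + 1L
    f <- res$features
    f$participant <- sess$participant
    f$ms_type <- sess$ms_type
    feats[[i]] <- f
    targets[[i]] <- data.frame(participant = sess$participant,
                               ms_type = sess$ms_type,
                               window = seq_along(res$fms), fms = res$fms)
  }
  features <- do.call(rbind, feats)
  features$value[!is.finite(features$value)] <- NA_real_
  list(features = features[, c("participant", "ms_type", "window", "id",
                               "value", "missing")],
       fms = do.call(rbind, targets))
}

#' Screen every feature against an MSL measure with rmcorr
#'
#' Computes the repeated-measures correlation of each descriptor against the
#' per-window FMS (window basis) and tags effect-size tiers.
#'
#' @param tab a [cohort_feature_table()] result.
#' @param alpha significance gate for the tiers.
#' @return data.frame: id, r, df, p, tier.
#' @export
screen_features_fms <- function(tab, alpha = 0.05) {
  key <- function(d) paste(d$participant, d$ms_type, d$window, sep = "|")
  fms_by_key <- setNames(tab$fms$fms, key(tab$fms))
  rows <- lapply(split(tab$features, tab$features$id), function(d) {
    res <- rmcorr(d$value, fms_by_key[key(d)], d$participant)
    data.frame(id = d$id[1L], r = res$r, df = res$df, p = res$p,
               tier = sesoi_screen(res, alpha)$tier,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
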