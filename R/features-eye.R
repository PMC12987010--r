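#' Binary eye-closure signal
#'
#' A frame is classified closed (1) when the eye position is null (any
#' non-finite coordinate) or coincides with the HMD gaze origin to within
#' 1e-3 m in the L-infinity norm; open (0) otherwise.
#'
#' @param p_eye numeric matrix (frames x 3), left or right eye position (m);
#'   null frames as NA.
#' @param p_center numeric matrix (frames x 3), gaze-origin position.
#' @param tol closure tolerance in metres (default 1e-3).
#' @return integer vector of 0/1 closure states.
#' @export
eye_closure <- function(p_eye, p_center, tol = 1e-3) {
  isnull <- !is.finite(p_eye[, 1L]) | !is.finite(p_eye[, 2L]) | !is.finite(p_eye[, 3L])
  dist <- pmax(abs(p_eye[, 1L] - p_center[, 1L]),
               abs(p_eye[, 2L] - p_center[, 2L]),
               abs(p_eye[, 3L] - p_center[, 3L]))
  as.integer(isnull | (!is.na(dist) & dist < tol))
}

#' Suppress single-frame inversions in a binary closure signal
#'
#' Isolated ones (0-1-0) are suppressed to 0 and isolated zeros (1-0-1) to 1,
#' in left-to-right sweeps (ones rule then zeros rule), repeated until the
#' signal is a fixed point of both rules.
#'
#' @param b integer/logical vector of 0/1.
#' @return denoised 0/1 integer vector.
#' @export
denoise_closure <- function(b) {
  b <- as.integer(b)
  n <- length(b)
  if (n < 3L) return(b)
  repeat {
    changed <- FALSE
    for (i in 2:(n - 1L)) {
      if (b[i] == 1L && b[i - 1L] == 0L && b[i + 1L] == 0L) {
        b[i] <- 0L; changed <- TRUE
      }
    }
    for (i in 2:(n - 1L)) {
      if (b[i] == 0L && b[i - 1L] == 1L && b[i + 1L] == 1L) {
        b[i] <- 1L; changed <- TRUE
      }
    }
    if (!changed) return(b)
  }
}

#' Combine left/right closure signals
#'
#' Frame-by-frame logical AND (both eyes closed) and OR (at least one eye
#' closed); both become SwF source signals.
#'
#' @param cs_l,cs_r equal-length 0/1 vectors.
#' @return list with `and` and `or` integer vectors.
#' @export
closure_combination <- function(cs_l, cs_r) {
  if (length(cs_l) != length(cs_r)) stopf("closure signals differ in length")
  list(and = as.integer(cs_l & cs_r), or = as.integer(cs_l | cs_r))
}

#' Blink rate from denoised closure signals
#'
#' Counts 0-to-1 transitions per eye, scales to blinks per minute, and
#' averages the two eyes.
#'
#' @param cs_l,cs_r denoised 0/1 closure signals.
#' @param window_s window length in seconds.
#' @return blinks per minute.
#' @export
blink_rate <- function(cs_l, cs_r, window_s) {
  per_eye <- function(b) sum(diff(b) == 1L) * 60 / window_s
  (per_eye(as.integer(cs_l)) + per_eye(as.integer(cs_r))) / 2
}

#' Binocular convergence distance
#'
#' Minimum Euclidean distance between the closest points of the two gaze
#' lines: `|(P_L - P_R) . (D_L x D_R)| / ||D_L x D_R||`, NaN when the gaze
#' directions are virtually parallel (`||D_L x D_R|| < 1e-3`) or when a frame
#' is null. Direction vectors are normalized first (with a warning if they
#' deviate from unit norm).
#'
#' @param p_l,p_r eye positions (frames x 3, metres).
#' @param d_l,d_r gaze direction vectors (frames x 3).
#' @return numeric distance signal (m) with NaN at vergence-loss frames.
#' @export
convergence_distance <- function(p_l, p_r, d_l, d_r) {
  norm_rows <- function(d) {
    nrm <- sqrt(rowSums(d^2))
    if (any(abs(nrm - 1) > 1e-6, na.rm = TRUE)) {
      warning("non-unit gaze directions normalized", call. = FALSE)
    }
    d / nrm
  }
  d_l <- norm_rows(d_l)
  d_r <- norm_rows(d_r)
  cr <- cbind(d_l[, 2L] * d_r[, 3L] - d_l[, 3L] * d_r[, 2L],
              d_l[, 3L] * d_r[, 1L] - d_l[, 1L] * d_r[, 3L],
              d_l[, 1L] * d_r[, 2L] - d_l[, 2L] * d_r[, 1L])
  nrm <- sqrt(rowSums(cr^2))
  dp <- p_l - p_r
  d <- abs(rowSums(dp * cr)) / nrm
  d[!is.finite(nrm) | nrm < 1e-3] <- NaN
  d
}

#' Gaze angles from direction unit vectors
#'
#' `theta_yaw = 180/pi * atan2(g_x, g_z)` and `theta_pitch = 180/pi *
#' asin(clamp(g_y, -1, 1))`, in degrees; forward (0, 0, 1) maps to (0, 0).
#'
#' @param d numeric matrix (frames x 3) of approximately unit direction
#'   vectors; zero vectors are rejected.
#' @return list with `yaw` and `pitch` signals (degrees).
#' @export
gaze_angles <- function(d) {
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm[is.finite(nrm)] < 1e-9)) stopf("zero gaze direction vector")
  list(yaw = 180 / pi * atan2(d[, 1L], d[, 3L]),
       pitch = 180 / pi * asin(pmin(pmax(d[, 2L], -1), 1)))
}

#' Gaze heatmap entropy
#'
#' Shannon entropy (base 2) of the normalized 2-D histogram of gaze angles on
#' a 64 x 64 grid over [-90, 90] x [-90, 90] degrees; out-of-range samples
#' are clipped to the edge bins.
#'
#' @param yaw,pitch angle signals in degrees.
#' @return entropy in bits.
#' @export
heatmap_entropy <- function(yaw, pitch) {
  keep <- is.finite(yaw) & is.finite(pitch)
  yaw <- yaw[keep]; pitch <- pitch[keep]
  if (!length(yaw)) stopf("empty window")
  bin <- function(a) pmin(pmax(floor((a + 90) / 180 * 64), 0), 63)
  cell <- bin(yaw) * 64 + bin(pitch)
  p <- tabulate(cell + 1L, nbins = 4096)
  p <- p[p > 0] / length(cell)
  -sum(p * log2(p))
}

#' Angular gaze velocity and derived window features
#'
#' `v[k] = acos(clamp(D[k] . D[k-1])) * 180/pi * frame_rate` (degrees per
#' second). Frames with v > 100 deg/s are saccades (strict inequality), the
#' rest fixations; the path length is the cumulative per-frame angle in
#' degrees.
#'
#' @param d numeric matrix (frames x 3) of unit direction vectors.
#' @param frame_rate frames per second.
#' @return list with `velocity` (deg/s, NA at the first frame and around
#'   null frames), `saccade_ratio`, `fixation_ratio`, `path_length`.
#' @export
gaze_velocity <- function(d, frame_rate) {
  n <- nrow(d)
  if (n < 2L) stopf("need at least 2 frames")
  dot <- rowSums(d[-1L, , drop = FALSE] * d[-n, , drop = FALSE])
  step_deg <- acos(pmin(pmax(dot, -1), 1)) * 180 / pi
  v <- c(NA_real_, step_deg * frame_rate)
  fin <- is.finite(v)
  sr <- if (any(fin)) mean(v[fin] > 100) else NA_real_
  list(velocity = v, saccade_ratio = sr, fixation_ratio = 1 - sr,
       path_length = sum(step_deg[is.finite(step_deg)]))
}

#' Vestibulo-ocular reflex proxy
#'
#' Mean of gaze velocity over head velocity across frames, excluding frames
#' with head velocity below 1e-3 deg/s; missing when no frames remain.
#'
#' @param gaze_v,head_v velocity signals in deg/s.
#' @return mean ratio (NA = missing).
#' @export
vor <- function(gaze_v, head_v) {
  keep <- is.finite(gaze_v) & is.finite(head_v) & head_v >= 1e-3
  if (!any(keep)) return(NA_real_)
  mean(gaze_v[keep] / head_v[keep])
}
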