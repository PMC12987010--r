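#' Default sensor specifications
#'
#' Nominal sampling rates and channel layouts of the acquisition setup the
#' generator emulates: PPG and EDA at 128 Hz (EDA recorded as skin resistance
#' in kilo-ohm), 8-channel EEG at 500 Hz, skin temperature at 1 Hz, head pose
#' (position sway/heave/surge in metres, rotation pitch/yaw/roll in degrees)
#' at 30 Hz, a head-mounted IMU (3-axis acceleration + 3-axis angular
#' velocity) at 4 Hz, and eye tracking (left/right/center eye position and
#' gaze direction vectors) at 30 Hz.
#'
#' @return named list of `(name, rate, channels)` specs.
#' @export
default_sensor_specs <- function() {
  eeg_ch <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
  pose_ch <- c("posSway", "posHeave", "posSurge", "rotPitch", "rotYaw", "rotRoll")
  imu_ch <- c("accSway", "accHeave", "accSurge", "gyrPitch", "gyrYaw", "gyrRoll")
  eye_ch <- c(t(outer(c("posL", "posR", "posC", "dirL", "dirR", "dirC"),
                      c("x", "y", "z"), paste0)))
  list(
    PPG      = list(name = "PPG", rate = 128, channels = "ppg"),
    EDA      = list(name = "EDA", rate = 128, channels = "eda_kohm"),
    EEG      = list(name = "EEG", rate = 500, channels = eeg_ch),
    SKT      = list(name = "SKT", rate = 1, channels = "skt"),
    HeadPose = list(name = "HeadPose", rate = 30, channels = pose_ch),
    HeadIMU  = list(name = "HeadIMU", rate = 4, channels = imu_ch),
    Eye      = list(name = "Eye", rate = 30, channels = eye_ch)
  )
}

#' Default planted signal-to-MSL loadings
#'
#' Signed latent loadings for the feature families the generator can couple to
#' the latent motion-sickness trajectory. The default signs reproduce the
#' reported univariate directions: electrodermal amplitude decreases with MSL,
#' head pitch-rotation and surge-position energy increase, gaze-direction PSD
#' entropy increases, and EEG sample entropy decreases.
#'
#' @return named numeric vector of loadings.
#' @export
default_effect_sizes <- function() {
  c(eda_amplitude = -0.3,
    head_pitch_energy = 0.3,
    head_surge_energy = 0.3,
    eye_dir_psd_entropy = 0.3,
    eeg_sample_entropy = -0.3)
}

#' Synthetic cohort configuration
#'
#' @param n_participants number of participants.
#' @param ms_types ordered session types; each participant contributes one
#'   session per type.
#' @param session_length_s raw session length in seconds (default 1200; must
#'   exceed 60).
#' @param sensor_specs list of sensor specs as in [default_sensor_specs()]; a
#'   subset may be supplied to generate only some streams.
#' @param effect_sizes named map of feature-family loadings, see
#'   [default_effect_sizes()].
#' @param fragmentation_rate expected number of recording restarts per session.
#' @param restart_overlap_s seconds of re-recorded overlap at each restart
#'   (default 10).
#' @param jitter_chunks maximum per-second sample-count deviation, in chunks.
#' @param chunk_rate_hz delivery rate of acquisition chunks (15-20 Hz range;
#'   default 16).
#' @param seed master seed; fully determines the cohort.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 16,
                             ms_types = c("CMS", "VIMS", "CoMS"),
                             session_length_s = 1200,
                             sensor_specs = default_sensor_specs(),
                             effect_sizes = default_effect_sizes(),
                             fragmentation_rate = 0.5,
                             restart_overlap_s = 10,
                             jitter_chunks = 1,
                             chunk_rate_hz = 16,
                             seed = 1L) {
  if (!is_count(n_participants)) stopf("n_participants must be a positive integer")
  if (!is.numeric(session_length_s) || session_length_s <= 60) {
    stopf("session_length_s must exceed 60 s")
  }
  for (sp in sensor_specs) {
    if (!is.numeric(sp$rate) || sp$rate <= 0) {
      stopf("invalid sampling rate for sensor %s", sp$name %||% "?")
    }
  }
  if (fragmentation_rate < 0) stopf("fragmentation_rate must be non-negative")
  if (restart_overlap_s < 5) stopf("restart_overlap_s must be at least 5 s")
  if (jitter_chunks < 0) stopf("jitter_chunks must be non-negative")
  es <- default_effect_sizes()
  es[names(effect_sizes)] <- effect_sizes
  structure(list(n_participants = as.integer(n_participants),
                 ms_types = ms_types,
                 session_length_s = session_length_s,
                 sensor_specs = sensor_specs,
                 effect_sizes = es,
                 fragmentation_rate = fragmentation_rate,
                 restart_overlap_s = restart_overlap_s,
                 jitter_chunks = jitter_chunks,
                 chunk_rate_hz = chunk_rate_hz,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Counterbalancing design cells
#'
#' The 2 (VIMS display type) x 4 (driving-scenario version) x 2 (movie order)
#' design, 16 cells in total; participants are assigned cyclically by
#' enrollment order.
#'
#' @return data.frame with columns `cell`, `vims_type`, `scenario_version`,
#'   `movie_order`.
#' @export
counterbalance_cells <- function() {
  g <- expand.grid(movie_order = 1:2, scenario_version = 1:4,
                   vims_type = c("F-VIMS", "S-VIMS"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("vims_type", "scenario_version", "movie_order")]
  g$cell <- seq_len(nrow(g))
  g[, c("cell", "vims_type", "scenario_version", "movie_order")]
}
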