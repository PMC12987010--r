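gen_mssq_era <- function(susceptibility) {
  experienced <- runif(9) < 0.8
  freq <- ifelse(experienced,
                 pmin(pmax(round(1.5 * susceptibility + rnorm(9, sd = 0.8)), 0), 4),
                 NA_integer_)
  data.frame(type = paste0("type", 1:9), sickness = freq, experienced = experienced)
}

gen_ssq_items <- function(p) {
  pmin(pmax(rbinom(16, size = 3, prob = p), 0), 3)
}

gen_questionnaires <- function(susceptibility, latent) {
  z_end <- mean(tail(latent, 60))
  list(
    ssq_pre = gen_ssq_items(0.03),
    ssq_post = gen_ssq_items(min(0.08 + 0.12 * z_end, 0.8)),
    mssq = list(child = gen_mssq_era(susceptibility),
                adult = gen_mssq_era(susceptibility * 0.8)),
    ieq = pmin(pmax(round(rnorm(24, 3.5, 0.8)), 1), 5)
  )
}

#' Generate a synthetic multimodal cohort
#'
#' One session per participant x session type, with all configured streams at
#' their nominal rates, FMS reports every 30 s derived from a latent MSL
#' trajectory with quantization noise, questionnaires driven by a
#' per-participant susceptibility scalar, recording fragmentation with
#' overlap, and per-second chunk jitter. Participants are assigned cyclically
#' to the 16 counterbalancing cells (2 display types x 4 scenario versions x
#' 2 movie orders).
#'
#' @param config a [synthetic_config()].
#' @return list with `sessions` (list of `session_record`) and `truth`
#'   (latent trajectories, susceptibilities, planted loadings, assignment).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) stopf("config must be a synthetic_config")
  cells <- counterbalance_cells()
  pids <- sprintf("P%02d", seq_len(config$n_participants))
  assignment <- cells[(seq_along(pids) - 1L) %% nrow(cells) + 1L, ]
  assignment$participant <- pids
  susceptibility <- setNames(vapply(pids, function(p) {
    with_seed(derive_seed(config$seed, p, "susceptibility"),
              min(max(abs(rnorm(1, 1, 0.5)), 0.2), 2.5))
  }, numeric(1)), pids)
  # cohort-typical gender imbalance (~30% female), 1 = female
  assignment$gender <- vapply(pids, function(p) {
    with_seed(derive_seed(config$seed, p, "gender"), rbinom(1, 1, 0.3))
  }, integer(1))

  sessions <- list()
  latents <- list()
  for (p in pids) {
    for (ms in config$ms_types) {
      key <- paste(p, ms, sep = ".")
      latent <- generate_msl_trajectory(config$session_length_s,
                                        susceptibility[[p]], ms,
                                        derive_seed(config$seed, p, ms, "latent"))
      latents[[key]] <- latent
      fms <- fms_reports_from_latent(latent,
                                     seed = derive_seed(config$seed, p, ms, "fms"))
      streams <- generate_session_streams(config, latent, p, ms)
      ev <- with_seed(derive_seed(config$seed, p, ms, "frag"), {
        k <- rpois(1, config$fragmentation_rate)
        lo <- config$restart_overlap_s + 60
        hi <- config$session_length_s - 60
        if (k > 0 && hi > lo) sort(runif(k, lo, hi)) else numeric(0)
      })
      streams <- lapply(streams, function(s) {
        frs <- inject_fragmentation(s, ev, config$restart_overlap_s)
        lapply(seq_along(frs), function(i) {
          perturb_chunk_timing(frs[[i]], config$chunk_rate_hz,
                               config$jitter_chunks,
                               seed = derive_seed(config$seed, p, ms, s$sensor, i))
        })
      })
      quests <- with_seed(derive_seed(config$seed, p, ms, "quest"),
                          gen_questionnaires(susceptibility[[p]], latent))
      sessions[[key]] <- structure(
        list(participant = p, ms_type = ms,
             cell = assignment[assignment$participant == p,
                               c("cell", "vims_type", "scenario_version", "movie_order")],
             gender = assignment$gender[assignment$participant == p],
             susceptibility = susceptibility[[p]],
             streams = streams, fms = fms, questionnaires = quests,
             session_length_s = config$session_length_s),
        class = "session_record")
    }
  }
  truth <- structure(list(latent_msl = latents,
                          susceptibility = susceptibility,
                          planted_loadings = config$effect_sizes,
                          assignment = assignment),
                     class = "ground_truth")
  list(sessions = sessions, truth = truth)
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record %s/%s: %d stream(s), %d FMS reports>\n",
              x$participant, x$ms_type, length(x$streams), nrow(x$fms)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One directory per participant x session; each stream fragment as a CSV
#' (`timestamp_s` plus one column per channel), questionnaires, FMS reports
#' and ground truth as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$sessions)) {
    sess <- cohort$sessions[[key]]
    sdir <- file.path(dir, gsub("\\.", "_", key))
    dir.create(sdir, showWarnings = FALSE)
    for (sensor in names(sess$streams)) {
      for (i in seq_along(sess$streams[[sensor]])) {
        fr <- sess$streams[[sensor]][[i]]
        df <- data.frame(timestamp_s = fr$t, fr$x, check.names = FALSE)
        utils::write.csv(df, file.path(sdir, sprintf("%s_frag%02d.csv", sensor, i)),
                         row.names = FALSE)
      }
    }
    utils::write.csv(sess$fms, file.path(sdir, "fms.csv"), row.names = FALSE)
    jsonlite::write_json(sess$questionnaires, file.path(sdir, "questionnaires.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  jsonlite::write_json(list(latent_msl = cohort$truth$latent_msl,
                            susceptibility = as.list(cohort$truth$susceptibility),
                            planted_loadings = as.list(cohort$truth$planted_loadings)),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
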