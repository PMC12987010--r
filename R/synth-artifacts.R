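#' Split a stream into overlapping recording fragments
#'
#' Emulates recording restarts: at each event time the recording stops and is
#' restarted `overlap_s` seconds earlier, so consecutive fragments overlap and
#' their union covers the original span (e.g. a restart at t = 500 s with a
#' 10-s overlap yields fragments spanning 0-500 s and 490-1200 s).
#'
#' @param stream a [sensor_stream()].
#' @param events numeric vector of restart times (seconds), strictly inside
#'   the recorded span; may be empty.
#' @param overlap_s seconds re-recorded before each restart (>= 5).
#' @return list of `sensor_stream` fragments in chronological order.
#' @export
inject_fragmentation <- function(stream, events, overlap_s = 10) {
  if (overlap_s < 5) stopf("overlap_s must be at least 5 s")
  if (!length(events)) return(list(stream))
  events <- sort(as.numeric(events))
  span <- range(stream$t)
  if (any(events <= span[1] + overlap_s) || any(events >= span[2])) {
    stopf("fragmentation event outside session span")
  }
  starts <- c(span[1], events - overlap_s)
  ends <- c(events, span[2] + 1 / stream$rate)
  lapply(seq_along(starts), function(i) {
    stream_slice(stream, starts[i], ends[i])
  })
}

#' Perturb per-second chunk delivery of a stream
#'
#' Emulates the acquisition-side chunking artifact: samples arrive in chunks
#' at `chunk_rate_hz`, and scheduling latency moves boundary chunks into the
#' neighbouring one-second save block, so per-second stored counts deviate
#' from nominal by up to `max_dev_chunks` chunks. Recorded per-sample
#' timestamps carry only OS-scheduling-scale noise (`timing_noise_s`), and a
#' chunk may occasionally be lost entirely (`drop_prob` per chunk), producing
#' a genuine gap the grid correction has to interpolate. Total duration is
#' preserved; `max_dev_chunks = 0` is the identity.
#'
#' The per-second stored counts are attached as attribute `block_counts`.
#'
#' @param stream a [sensor_stream()].
#' @param chunk_rate_hz chunk delivery rate (default 16 Hz).
#' @param max_dev_chunks maximum per-second count deviation, in chunks.
#' @param timing_noise_s half-width of uniform per-sample timestamp noise.
#' @param drop_prob probability that a chunk is lost.
#' @param seed integer seed; output deterministic given the seed.
#' @return jittered `sensor_stream`.
#' @export
perturb_chunk_timing <- function(stream, chunk_rate_hz = 16, max_dev_chunks = 1,
                                 timing_noise_s = 3e-4, drop_prob = 0,
                                 seed = 1L) {
  if (max_dev_chunks < 0) stopf("max_dev_chunks must be non-negative")
  if (max_dev_chunks == 0) return(stream)
  n <- length(stream$t)
  cs <- max(1L, as.integer(round(stream$rate / chunk_rate_hz)))
  chunk_of <- (seq_len(n) - 1L) %/% cs
  n_chunks <- max(chunk_of) + 1L
  with_seed(seed, {
    latency <- runif(n_chunks, 0, max_dev_chunks / chunk_rate_hz)
    keep_chunk <- runif(n_chunks) >= drop_prob
    keep <- keep_chunk[chunk_of + 1L]
    t_rec <- stream$t + runif(n, -timing_noise_s, timing_noise_s)
    arrival <- stream$t[pmin((chunk_of + 1L) * cs, n)] + latency[chunk_of + 1L]
    block <- floor(arrival[keep])
    t_rec <- t_rec[keep]
    x <- stream$x[keep, , drop = FALSE]
    ord <- order(t_rec)
    out <- sensor_stream(stream$sensor, stream$rate, t_rec[ord],
                         x[ord, , drop = FALSE])
    attr(out, "block_counts") <- tabulate(as.integer(block) + 1L, max(block) + 1L)
    out
  })
}
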