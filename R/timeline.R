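#' Merge overlapping recording fragments into one continuous stream
#'
#' Fragments are ordered chronologically and merged pairwise left-to-right.
#' At each overlap the seam is placed at the overlap midpoint, so when the
#' overlap is at least 10 s, at least 5 s are discarded from the end of the
#' earlier fragment and from the start of the later one. A gap (negative
#' overlap) between consecutive fragments is a reconstruction error.
#'
#' @param fragments list of [sensor_stream()] fragments.
#' @return a single `sensor_stream` spanning the union of the fragments, with
#'   element `frag` recording the source fragment of every sample.
#' @export
merge_fragments <- function(fragments) {
  if (!length(fragments)) stopf("no fragments supplied")
  if (length(fragments) == 1L) {
    out <- fragments[[1L]]
    out$frag <- rep(1L, length(out$t))
    return(out)
  }
  starts <- vapply(fragments, function(f) min(f$t), numeric(1))
  ord <- order(starts)
  fragments <- fragments[ord]
  acc <- fragments[[1L]]
  acc$frag <- rep(1L, length(acc$t))
  for (i in seq_along(fragments)[-1L]) {
    nxt <- fragments[[i]]
    e_prev <- max(acc$t)
    s_next <- min(nxt$t)
    if (s_next > e_prev + 1.5 / acc$rate) {
      stopf("gap between fragments: [%.3f, %.3f] s uncovered", e_prev, s_next)
    }
    seam <- (e_prev + s_next) / 2
    keep_a <- acc$t < seam
    keep_b <- nxt$t >= seam
    frag <- c(acc$frag[keep_a], rep(i, sum(keep_b)))
    acc <- sensor_stream(acc$sensor, acc$rate,
                         c(acc$t[keep_a], nxt$t[keep_b]),
                         rbind(acc$x[keep_a, , drop = FALSE],
                               nxt$x[keep_b, , drop = FALSE]))
    acc$frag <- frag
  }
  acc
}

#' Trim session edges
#'
#' Removes `trim_s` seconds from the start and end of a stream (edge noise
#' from sensor attachment and session start/stop) and re-anchors timestamps
#' at zero; a 1200-s recording becomes the effective 1140-s segment.
#'
#' @param stream a [sensor_stream()].
#' @param trim_s seconds trimmed from each edge (default 30).
#' @return trimmed `sensor_stream`.
#' @export
trim_edges <- function(stream, trim_s = 30) {
  dur <- stream_duration(stream)
  if (dur < 2 * trim_s + 1 / stream$rate) {
    stopf("stream of %.1f s too short to trim %g s from each edge", dur, trim_s)
  }
  if (trim_s == 0) return(stream)
  t0 <- min(stream$t)
  keep <- stream$t >= t0 + trim_s & stream$t < t0 + dur - trim_s
  out <- sensor_stream(stream$sensor, stream$rate, stream$t[keep] - (t0 + trim_s),
                       stream$x[keep, , drop = FALSE])
  if (!is.null(stream$frag)) out$frag <- stream$frag[keep]
  out
}

#' Expected sample grid for a sensor
#'
#' The rate-exact uniform grid a reconstructed stream must land on:
#' `n_expected = rate x duration_s` indices at `t_i = i / rate`,
#' `i = 0 .. n_expected - 1` (e.g. 128 Hz x 1140 s = 145,920 samples).
#'
#' @param rate official sampling rate in Hz.
#' @param duration_s effective duration in seconds.
#' @return object of class `expected_grid` with fields `rate`, `duration_s`,
#'   `n_expected`, `times`.
#' @export
build_expected_grid <- function(rate, duration_s) {
  if (rate <= 0) stopf("rate must be positive")
  n <- rate * duration_s
  if (abs(n - round(n)) > 1e-9) {
    stopf("rate x duration (%g x %g) is not an integer sample count", rate, duration_s)
  }
  n <- as.integer(round(n))
  structure(list(rate = rate, duration_s = duration_s, n_expected = n,
                 times = (seq_len(n) - 1L) / rate),
            class = "expected_grid")
}

#' Align recorded samples to an expected grid
#'
#' Each recorded sample is mapped to its nearest grid index; when several
#' samples collide on one index the temporally closest wins (ties broken
#' toward the earlier sample). Empty interior indices are filled by
#' shape-preserving piecewise cubic Hermite interpolation over the observed
#' anchors; boundary gaps take the nearest observed value. Non-finite
#' observations (e.g. eye-closed null frames) are carried through as observed
#' values but never used as interpolation anchors.
#'
#' @param stream a [sensor_stream()] (possibly merged/trimmed).
#' @param grid an [build_expected_grid()] result.
#' @return object of class `reconstructed_stream`: `values` (n_expected x
#'   channels), `filled_mask` (TRUE where interpolated), `provenance`
#'   (fragment id per index, NA where interpolated), plus sensor identity.
#' @export
align_to_grid <- function(stream, grid) {
  n_obs <- length(stream$t)
  if (n_obs == 0L) stopf("empty input stream")
  if (n_obs > 1L && diff(range(stream$t)) == 0) stopf("all timestamps identical")
  tol <- 0.5 / grid$rate
  if (min(stream$t) < -tol || max(stream$t) > grid$duration_s + tol) {
    stopf("timestamps outside grid span")
  }
  idx <- pmin(pmax(round(stream$t * grid$rate), 0), grid$n_expected - 1L) + 1L
  dist <- abs(stream$t - (idx - 1L) / grid$rate)
  ord <- order(idx, dist, stream$t)
  first <- !duplicated(idx[ord])
  sel <- ord[first]

  n <- grid$n_expected
  nch <- ncol(stream$x)
  values <- matrix(NA_real_, n, nch, dimnames = list(NULL, colnames(stream$x)))
  values[idx[sel], ] <- stream$x[sel, , drop = FALSE]
  observed <- logical(n)
  observed[idx[sel]] <- TRUE
  provenance <- rep(NA_integer_, n)
  if (!is.null(stream$frag)) provenance[idx[sel]] <- stream$frag[sel]

  for (j in seq_len(nch)) {
    anchor <- which(observed & is.finite(values[, j]))
    fill <- which(!observed)
    if (!length(fill)) next
    if (length(anchor) == 0L) next
    if (length(anchor) == 1L) {
      values[fill, j] <- values[anchor, j]
      next
    }
    inner <- fill[fill > anchor[1L] & fill < anchor[length(anchor)]]
    if (length(inner)) {
      if (length(anchor) >= 3L) {
        values[inner, j] <- pracma::pchip(as.numeric(anchor), values[anchor, j],
                                          as.numeric(inner))
      } else {
        values[inner, j] <- approx(anchor, values[anchor, j], xout = inner)$y
      }
    }
    lo <- fill[fill < anchor[1L]]
    hi <- fill[fill > anchor[length(anchor)]]
    values[lo, j] <- values[anchor[1L], j]
    values[hi, j] <- values[anchor[length(anchor)], j]
  }
  structure(list(sensor = stream$sensor, rate = grid$rate, grid = grid,
                 values = values, filled_mask = !observed,
                 provenance = provenance),
            class = "reconstructed_stream")
}

#' @export
print.reconstructed_stream <- function(x, ...) {
  cat(sprintf("<reconstructed_stream %s: %d x %d on %g-Hz grid, %.2f%% interpolated>\n",
              x$sensor, nrow(x$values), ncol(x$values), x$rate,
              100 * mean(x$filled_mask)))
  invisible(x)
}

#' Convert a reconstructed stream back to a sensor stream
#' @param rec a `reconstructed_stream`.
#' @return a [sensor_stream()] on the grid timestamps.
#' @export
as_sensor_stream <- function(rec) {
  sensor_stream(rec$sensor, rec$rate, rec$grid$times, rec$values)
}

#' Reconstruct all streams of a session onto their expected grids
#'
#' Merges fragments, trims `trim_s` seconds from each edge, builds the
#' per-sensor expected grid over the effective duration, and aligns.
#'
#' @param session a `session_record` from [generate_cohort()].
#' @param trim_s edge trim in seconds (default 30).
#' @return list with `streams` (named list of grid-aligned [sensor_stream()]s)
#'   and `report` (per-sensor fill fraction and fragment count).
#' @export
reconstruct_session <- function(session, trim_s = 30) {
  eff <- session$session_length_s - 2 * trim_s
  out <- list()
  report <- list()
  for (sensor in names(session$streams)) {
    merged <- merge_fragments(session$streams[[sensor]])
    trimmed <- trim_edges(merged, trim_s)
    grid <- build_expected_grid(trimmed$rate, eff)
    rec <- align_to_grid(trimmed, grid)
    out[[sensor]] <- as_sensor_stream(rec)
    report[[sensor]] <- list(n_fragments = length(session$streams[[sensor]]),
                             fill_fraction = mean(rec$filled_mask),
                             n_expected = grid$n_expected)
  }
  list(streams = out, report = report)
}
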