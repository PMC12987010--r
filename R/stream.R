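#' Uniformly identified sensor stream
#'
#' A `sensor_stream` bundles one channel set of samples with its timestamps,
#' nominal rate and sensor identity. Timestamps are in seconds from session
#' start; `x` is an `n x channels` numeric matrix with named columns.
#'
#' @param sensor sensor name, e.g. `"EDA"`.
#' @param rate nominal sampling rate in Hz.
#' @param t numeric timestamps (seconds), strictly increasing.
#' @param x numeric vector or matrix of samples (rows = time).
#' @param channels optional channel names.
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(sensor, rate, t, x, channels = NULL) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (length(t) != nrow(x)) stopf("timestamps (%d) and samples (%d) differ", length(t), nrow(x))
  if (!is.null(channels)) colnames(x) <- channels
  if (is.null(colnames(x))) colnames(x) <- paste0("ch", seq_len(ncol(x)))
  structure(list(sensor = sensor, rate = rate, t = as.numeric(t), x = x),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream %s: %d ch x %d samples @ %g Hz, span [%.3f, %.3f] s>\n",
              x$sensor, ncol(x$x), nrow(x$x), x$rate,
              if (length(x$t)) min(x$t) else NA, if (length(x$t)) max(x$t) else NA))
  invisible(x)
}

stream_duration <- function(stream) {
  if (!length(stream$t)) return(0)
  diff(range(stream$t)) + 1 / stream$rate
}

stream_slice <- function(stream, from, to) {
  keep <- stream$t >= from & stream$t < to
  sensor_stream(stream$sensor, stream$rate, stream$t[keep],
                stream$x[keep, , drop = FALSE])
}
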