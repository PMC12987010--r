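#' @useDynLib mslquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd fft rnorm runif rpois rbinom pt p.adjust quantile
#'   median aov approx predict coef complete.cases setNames cor
#' @importFrom utils head tail
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a label
#'
#' Stable integer hashing of `(master, ...)` so that every stream, session and
#' participant draws from its own RNG stream while one master seed fully
#' determines the cohort. The result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the consumer, e.g.
#'   participant id, session name, sensor name.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- (h * 16777619) %% 2147483647
    h <- (h + b * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

# Linear convolution via power-of-two FFT (R's convolve uses the raw
# combined length, which can hit slow mixed-radix sizes).
fast_conv <- function(x, k) {
  n <- length(x) + length(k) - 1L
  m <- stats::nextn(n, 2)
  Re(fft(fft(c(x, numeric(m - length(x)))) *
         fft(c(k, numeric(m - length(k)))), inverse = TRUE) / m)[seq_len(n)]
}
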