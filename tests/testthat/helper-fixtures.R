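# Shared fixtures, built in code. Tiny cohorts keep the unit suite fast; the
# acceptance tests build their own study-sized cohorts.

tiny_config <- function(seed = 42L, sensors = c("EDA", "HeadPose", "SKT"),
                        n = 2L, len = 120, frag = 0, ...) {
  synthetic_config(n_participants = n, session_length_s = len,
                   sensor_specs = default_sensor_specs()[sensors],
                   fragmentation_rate = frag, seed = seed, ...)
}

uniform_stream <- function(rate, dur, f = function(t) sin(2 * pi * t),
                           sensor = "TEST") {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  sensor_stream(sensor, rate, t, f(t))
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Naive O(N^2) sample entropy by explicit template loops.
sampen_oracle <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  A <- 0L; B <- 0L
  for (i in 1:(n - m - 1)) {
    for (j in (i + 1):(n - m)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L) return(0)
  if (A == 0L) return(NA_real_)
  -log(A / B)
}

# Fixed-point oracle for closure denoising: repeatedly fix the first
# violating position (ones rule preferred), until no pattern remains.
denoise_oracle <- function(b) {
  b <- as.integer(b)
  n <- length(b)
  if (n < 3L) return(b)
  repeat {
    idx1 <- which(b[2:(n - 1)] == 1L & b[1:(n - 2)] == 0L & b[3:n] == 0L)
    if (length(idx1)) { b[idx1[1] + 1L] <- 0L; next }
    idx0 <- which(b[2:(n - 1)] == 0L & b[1:(n - 2)] == 1L & b[3:n] == 1L)
    if (length(idx0)) { b[idx0[1] + 1L] <- 1L; next }
    return(b)
  }
}

# Closest-distance between two 3-D lines by direct 2-parameter minimization.
skewdist_oracle <- function(pl, dl, pr, dr) {
  obj <- function(par) {
    sum((pl + par[1] * dl - pr - par[2] * dr)^2)
  }
  sqrt(optim(c(0, 0), obj, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))$value)
}

# rmcorr oracle: explicit ANCOVA design-matrix least squares.
rmcorr_oracle <- function(x, y, id) {
  id <- factor(id)
  fit_full <- lm(y ~ id + x)
  fit_null <- lm(y ~ id)
  ss_err <- sum(residuals(fit_full)^2)
  ss_eff <- sum(residuals(fit_null)^2) - ss_err
  r <- sign(coef(fit_full)[["x"]]) * sqrt(ss_eff / (ss_eff + ss_err))
  df <- length(y) - nlevels(id) - 1
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * pt(-abs(tval), df))
}
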