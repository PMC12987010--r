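#' Repeated-measures correlation
#'
#' The common within-participant association between two repeatedly measured
#' variables, from the analysis-of-covariance formulation: both variables are
#' centered within participant, the coefficient is the correlation of the
#' centered values with error degrees of freedom `df = N - k - 1` (N
#' observations, k participants), and the two-sided p-value comes from
#' `t = r sqrt(df / (1 - r^2))` on a central t distribution. Missing values
#' are deleted pairwise; participants with fewer than two complete
#' observations are excluded.
#'
#' @param x,y numeric vectors of paired observations.
#' @param participant factor or character vector of participant identifiers.
#' @return object of class `rmcorr_result`: `r`, `df`, `p`, `n_obs`,
#'   `n_participants`, `valid` (FALSE when df < 1 or a variable has no
#'   within-participant variance).
#' @export
rmcorr <- function(x, y, participant) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  participant <- factor(as.character(participant)[keep])
  counts <- table(participant)
  ok <- participant %in% names(counts)[counts >= 2L]
  x <- x[ok]; y <- y[ok]
  participant <- droplevels(participant[ok])
  n <- length(x)
  k <- nlevels(participant)
  invalid <- function() {
    structure(list(r = NA_real_, df = NA_real_, p = NA_real_, n_obs = n,
                   n_participants = k, valid = FALSE), class = "rmcorr_result")
  }
  if (n == 0L || k == 0L) return(invalid())
  df <- n - k - 1L
  if (df < 1L) return(invalid())
  xc <- x - ave(x, participant)
  yc <- y - ave(y, participant)
  ssx <- sum(xc^2); ssy <- sum(yc^2)
  if (ssx <= 0 || ssy <= 0) return(invalid())
  r <- sum(xc * yc) / sqrt(ssx * ssy)
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(tval), df)
  }
  structure(list(r = r, df = df, p = p, n_obs = n, n_participants = k,
                 valid = TRUE), class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  if (!x$valid) cat("<rmcorr: invalid (insufficient data)>\n")
  else cat(sprintf("rmcorr: r = %.3f, df = %d, p = %.3g (N = %d, k = %d)\n",
                   x$r, x$df, x$p, x$n_obs, x$n_participants))
  invisible(x)
}

#' Benjamini-Hochberg adjustment within named families
#'
#' Step-up false-discovery-rate adjustment applied independently within each
#' family of tests. The exploratory feature-MSL screen is deliberately left
#' unadjusted (use [sesoi_screen()] there); families are meant for the
#' confirmatory questionnaire analyses (e.g. the 16-test immersion x SSQ
#' family, the 6-test MSL inter-correlation family, per-dependent-variable
#' ANOVA families).
#'
#' @param p numeric p-values in [0, 1].
#' @param family vector of family labels, same length as `p` (default: one
#'   family).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, family = rep("all", length(p))) {
  if (!length(p)) stopf("empty p-value family")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  out <- numeric(length(p))
  for (f in unique(family)) {
    sel <- family == f
    out[sel] <- p.adjust(p[sel], method = "BH")
  }
  out
}

#' Effect-size tiers for screened correlations
#'
#' Tags each repeated-measures correlation with the highest smallest-effect-
#' size-of-interest tier it satisfies jointly with p < alpha: |r| > 0.20
#' (medium), |r| > 0.25 (conservative), |r| > 0.30 (large); strict
#' inequalities throughout.
#'
#' @param results list of `rmcorr_result` objects (or a single one).
#' @param alpha significance gate (default 0.05).
#' @return data.frame with `r`, `p`, `tier` (`"none"`, `"medium"`,
#'   `"conservative"`, `"large"`).
#' @export
sesoi_screen <- function(results, alpha = 0.05) {
  if (inherits(results, "rmcorr_result")) results <- list(results)
  thresholds <- c(medium = 0.20, conservative = 0.25, large = 0.30)
  rows <- lapply(results, function(res) {
    tier <- "none"
    if (res$valid && is.finite(res$p) && res$p < alpha) {
      for (nm in names(thresholds)) if (abs(res$r) > thresholds[[nm]]) tier <- nm
    }
    data.frame(r = res$r, p = res$p, tier = tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(results))) out$id <- names(results)
  out
}

#' Session-level feature means
#'
#' Collapses a long window-level feature table to per-session means over the
#' non-missing windows (the session-basis used when correlating against
#' post-minus-pre questionnaire change).
#'
#' @param features long data.frame with `participant`, `ms_type`, `id`,
#'   `value` columns (missing values as NA).
#' @return data.frame `participant`, `ms_type`, `id`, `value`.
#' @export
session_mean_features <- function(features) {
  agg <- stats::aggregate(value ~ participant + ms_type + id,
                          data = features, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  agg$value[!is.finite(agg$value)] <- NA_real_
  agg
}

#' Mixed / between-subjects ANOVA delegation
#'
#' Thin interface over established least-squares routines for the
#' questionnaire-level analyses of variance: fits `formula` with
#' `stats::aov` (sums of squares via `car::Anova` when a type other than I
#' is requested and the car package is available). This wrapper exists so
#' that the questionnaire analyses have a documented seam; it adds no
#' statistical behaviour of its own.
#'
#' @param formula model formula, e.g. `dv ~ ms_type * gender + Error(
#'   participant / ms_type)`.
#' @param data data.frame.
#' @param type sum-of-squares type: 1, 2 or 3.
#' @return the fitted aov (type 1) or car::Anova table.
#' @export
mixed_anova <- function(formula, data, type = 3) {
  fit <- aov(formula, data = data)
  if (type == 1) return(fit)
  if (!requireNamespace("car", quietly = TRUE)) {
    stopf("type %s sums of squares need the car package", type)
  }
  car::Anova(fit, type = type)
}
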