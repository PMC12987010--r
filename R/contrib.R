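#' Map registry domains to analysis domains
#'
#' The contribution analysis treats head pose and head IMU as one "Head"
#' domain; all other registry domains keep their names.
#'
#' @param domain character vector of registry domains.
#' @return character vector of analysis domains.
#' @export
analysis_domain <- function(domain) {
  ifelse(domain %in% c("HeadPose", "HeadIMU"), "Head", domain)
}

impute_median <- function(x) {
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (anyNA(v)) {
      med <- median(v, na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      v[!is.finite(v)] <- med
      x[, j] <- v
    }
  }
  x
}

#' Assemble the wide model matrix from a long feature table
#'
#' Pivots a long per-window feature table into rows = (participant, session,
#' window) and columns = descriptors; missing entries stay NA (imputed at fit
#' time).
#'
#' @param features long data.frame with `participant`, `ms_type`, `window`,
#'   `id`, `value`.
#' @param fms data.frame with `participant`, `ms_type`, `window`, `fms`.
#' @return list with `x` (matrix), `y` (FMS target), `participant`,
#'   `domain` (analysis domain per column).
#' @export
feature_matrix <- function(features, fms) {
  key <- function(d) paste(d$participant, d$ms_type, d$window, sep = "|")
  rows <- unique(key(fms))
  ids <- sort(unique(features$id))
  x <- matrix(NA_real_, length(rows), length(ids),
              dimnames = list(rows, ids))
  x[cbind(match(key(features), rows), match(features$id, ids))] <- features$value
  fk <- match(rows, key(fms))
  reg <- feature_registry()
  dom <- analysis_domain(reg$domain[match(ids, reg$id)])
  list(x = x, y = fms$fms[fk],
       participant = fms$participant[fk], domain = dom)
}

#' Fit the contribution model and report its fit metrics
#'
#' Median-imputes missing feature values, fits the additive boosting model
#' ([msl_ebm()]) with the explanatory-fit hyperparameters (seed 42,
#' interactions 0.9, validation ratio 0.2 by default), and computes in-sample
#' R2, PLCC and SRCC on the full data.
#'
#' @param x feature matrix (may contain NA).
#' @param y per-window FMS target.
#' @param seed,interactions,validation_ratio model hyperparameters.
#' @param ... further arguments to [msl_ebm()].
#' @return list with `model` (`msl_ebm`), `metrics` (named r2/plcc/srcc),
#'   `importance` (named, decreasing), `x` (imputed matrix).
#' @export
fit_ebm <- function(x, y, seed = 42L, interactions = 0.9,
                    validation_ratio = 0.2, ...) {
  if (!all(is.finite(y))) stopf("non-finite target values")
  xi <- impute_median(as.matrix(x))
  model <- msl_ebm(xi, y, interactions = interactions,
                   validation_ratio = validation_ratio, seed = seed, ...)
  metrics <- fit_metrics(predict(model), y)
  list(model = model, metrics = metrics,
       importance = ebm_importance(model, xi), x = xi)
}

#' Relative degradation rate of a fit metric
#'
#' `delta_m(%) = (m_full - m_abl) / m_full x 100`; positive = explanatory
#' power degraded by the ablation, negative = the fit improved.
#'
#' @param m_full metric(s) of the full model (non-zero).
#' @param m_abl metric(s) of the ablated/partial model.
#' @return degradation in percent, same shape as the inputs.
#' @export
degradation <- function(m_full, m_abl) {
  if (any(m_full == 0, na.rm = TRUE)) stopf("full-model metric is zero")
  (m_full - m_abl) / m_full * 100
}

refit_subset <- function(x, y, cols, full_metrics, ...) {
  if (!length(cols)) stopf("empty feature subset")
  fit <- fit_ebm(x[, cols, drop = FALSE], y, ...)
  list(metrics = fit$metrics, delta = degradation(full_metrics, fit$metrics))
}

#' Domain ablation study
#'
#' Refits the model once per analysis domain with that domain's columns
#' removed — same rows, same hyperparameters, same seed — and reports the
#' degradation triplet (R2, PLCC, SRCC) relative to the full model.
#'
#' @param x feature matrix; column domains from `domain`.
#' @param y target.
#' @param domain analysis domain per column (see [analysis_domain()]).
#' @param full_metrics metrics of the full fit (from [fit_ebm()]).
#' @param ... hyperparameters passed through.
#' @return named list per domain: `metrics`, `delta`.
#' @export
ablate_domains <- function(x, y, domain, full_metrics, ...) {
  out <- list()
  for (d in unique(domain)) {
    out[[d]] <- refit_subset(x, y, which(domain != d), full_metrics, ...)
  }
  out
}

#' Single-domain models
#'
#' Refits keeping only one domain's columns at a time; the complement of
#' [ablate_domains()] for judging standalone explanatory capacity.
#'
#' @inheritParams ablate_domains
#' @return named list per domain: `metrics`, `delta`.
#' @export
single_domain_eval <- function(x, y, domain, full_metrics, ...) {
  out <- list()
  for (d in unique(domain)) {
    out[[d]] <- refit_subset(x, y, which(domain == d), full_metrics, ...)
  }
  out
}

#' Lightweight sensor-combination models
#'
#' Refits on unions of domains. The default list is the four lightweight
#' (EEG-free) combinations built on the Head + PPG baseline: Head+PPG,
#' Head+PPG+EDA, Head+PPG+Eye, Head+PPG+EDA+Eye.
#'
#' @inheritParams ablate_domains
#' @param combos named list of domain-set character vectors.
#' @return named list per combination: `metrics`, `delta`.
#' @export
combo_eval <- function(x, y, domain, full_metrics,
                       combos = default_combos(), ...) {
  out <- list()
  for (nm in names(combos)) {
    out[[nm]] <- refit_subset(x, y, which(domain %in% combos[[nm]]),
                              full_metrics, ...)
  }
  out
}

#' @rdname combo_eval
#' @export
default_combos <- function() {
  list("Head+PPG" = c("Head", "PPG"),
       "Head+PPG+EDA" = c("Head", "PPG", "EDA"),
       "Head+PPG+Eye" = c("Head", "PPG", "Eye"),
       "Head+PPG+EDA+Eye" = c("Head", "PPG", "EDA", "Eye"))
}

#' Participant-wise cross-validated importances
#'
#' Partitions participants (never rows) into k folds, refits on each
#' training set and reports the mean and SD of the global importances across
#' folds.
#'
#' @param x feature matrix.
#' @param y target.
#' @param participant participant id per row.
#' @param k number of folds (k = number of participants gives
#'   leave-one-participant-out).
#' @param seed fold-assignment seed.
#' @param ... hyperparameters passed to [fit_ebm()].
#' @return list with `mean`, `sd` (named numeric over terms) and `folds`
#'   (participant -> fold).
#' @export
participant_cv <- function(x, y, participant, k = 10L, seed = 1L, ...) {
  parts <- unique(participant)
  if (k > length(parts)) stopf("k (%d) exceeds participant count (%d)", k, length(parts))
  fold <- with_seed(seed, {
    setNames(rep(seq_len(k), length.out = length(parts))[sample.int(length(parts))],
             parts)
  })
  imp <- list()
  for (f in seq_len(k)) {
    tr <- participant %in% names(fold)[fold != f]
    fit <- fit_ebm(x[tr, , drop = FALSE], y[tr], ...)
    imp[[f]] <- fit$importance
  }
  terms <- unique(unlist(lapply(imp, names)))
  m <- sapply(imp, function(v) v[terms])
  rownames(m) <- terms
  m[is.na(m)] <- 0
  list(mean = sort(rowMeans(m), decreasing = TRUE),
       sd = apply(m, 1, sd)[order(rowMeans(m), decreasing = TRUE)],
       folds = fold)
}

#' Full contribution report
#'
#' Fits the full model, then runs the domain ablation, single-domain and
#' lightweight-combination evaluations (and optionally participant-wise CV),
#' all on identical rows and hyperparameters.
#'
#' @param fm a [feature_matrix()] result.
#' @param cv_k folds for participant-wise CV (0 = skip).
#' @param ... hyperparameters passed to [fit_ebm()].
#' @return object of class `contribution_report`.
#' @export
contribution_report <- function(fm, cv_k = 0L, ...) {
  full <- fit_ebm(fm$x, fm$y, ...)
  rep <- list(
    full_model = full$metrics,
    importances = full$importance,
    ablations = ablate_domains(fm$x, fm$y, fm$domain, full$metrics, ...),
    single_domain = single_domain_eval(fm$x, fm$y, fm$domain, full$metrics, ...),
    combos = combo_eval(fm$x, fm$y, fm$domain, full$metrics, ...)
  )
  if (cv_k > 0) {
    rep$cv <- participant_cv(fm$x, fm$y, fm$participant, k = cv_k, ...)
  }
  structure(rep, class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("<contribution_report: full R2 = %.3f, %d domains ablated, %d combos>\n",
              x$full_model[["r2"]], length(x$ablations), length(x$combos)))
  invisible(x)
}
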