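#' Feature matrix container
#'
#' Bundles an LC-MS intensity matrix (features in rows, injections in
#' columns) with per-injection metadata. QC injections carry
#' `timepoint == "QC"` and no subject id.
#'
#' @param intensities Numeric matrix, non-negative, with feature ids as row
#'   names and injection ids as column names.
#' @param meta Data.frame with columns `injection_id`, `subject_id` (`NA` for
#'   QC), `timepoint` in `pre`/`post`/`QC`, `injection_order` (unique positive
#'   integers) and `period`.
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(intensities, meta) {
  stopifnot(is.matrix(intensities), is.data.frame(meta))
  req <- c("injection_id", "subject_id", "timepoint", "injection_order")
  if (!all(req %in% names(meta)))
    stop("meta must contain: ", paste(req, collapse = ", "))
  if (ncol(intensities) != nrow(meta) ||
      !identical(colnames(intensities), as.character(meta$injection_id)))
    stop("intensity columns and metadata rows must match injection ids")
  if (is.null(rownames(intensities)))
    stop("intensities must carry feature ids as row names")
  if (anyDuplicated(meta$injection_order) || any(meta$injection_order < 1))
    stop("injection_order must be unique positive integers")
  if (!all(meta$timepoint %in% c("pre", "post", "QC")))
    stop("timepoint must be one of pre, post, QC")
  structure(list(intensities = intensities, meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d injections (%d QC, %d study)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$meta$timepoint == "QC"), sum(x$meta$timepoint != "QC")))
  invisible(x)
}

qc_idx <- function(fm) which(fm$meta$timepoint == "QC")
study_idx <- function(fm) which(fm$meta$timepoint != "QC")

#' Per-feature relative standard deviation over QC injections
#'
#' RSD = 100 * sd / mean with the sample (n-1) standard deviation, computed
#' over the pooled-QC injections only.
#'
#' @param fm A [feature_matrix()] with at least two QC injections.
#' @return Named numeric vector, one RSD (percent) per feature; `NaN` for
#'   zero-mean features.
#' @export
qc_rsd <- function(fm) {
  qc <- fm$intensities[, qc_idx(fm), drop = FALSE]
  if (ncol(qc) < 2) stop("at least 2 QC injections required")
  m <- rowMeans(qc)
  s <- apply(qc, 1, stats::sd)
  100 * s / m
}

# smooth QC-anchored drift curve for one feature; returns multiplicative
# correction factors (mean one over QC injections) for every injection order
drift_curve <- function(qc_order, qc_y, all_order, method, span) {
  flat <- rep(1, length(all_order))
  if (all(qc_y == qc_y[1])) return(flat)   # constant QC -> nothing to correct
  fit_y <- switch(method,
    loess = {
      lw <- stats::lowess(qc_order, qc_y, f = span)
      stats::approx(lw$x, lw$y, xout = all_order, rule = 2)$y
    },
    `median-ratio` = {
      r <- qc_y / stats::median(qc_y)
      stats::approx(qc_order, r, xout = all_order, rule = 2)$y *
        stats::median(qc_y)
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("method 'rf' requires the randomForest package")
      rf <- randomForest::randomForest(data.frame(o = qc_order), qc_y,
                                       ntree = 100)
      as.numeric(stats::predict(rf, data.frame(o = all_order)))
    })
  if (any(!is.finite(fit_y)) || any(fit_y <= 0)) return(flat)
  qc_fit <- fit_y[match(qc_order, all_order)]
  fit_y / mean(qc_fit)
}

# leave-one-out CV selection of the lowess span on a subsample of features
cv_span <- function(fm, spans = c(0.5, 0.75, 1), n_sample = 50) {
  qi <- qc_idx(fm)
  ord <- fm$meta$injection_order
  feats <- seq_len(nrow(fm$intensities))
  if (length(feats) > n_sample)
    feats <- feats[round(seq(1, length(feats), length.out = n_sample))]
  err <- sapply(spans, function(f) {
    e <- 0
    for (i in feats) {
      y <- fm$intensities[i, qi]
      if (all(y == y[1]) || any(y <= 0)) next
      for (k in seq_along(qi)) {
        lw <- stats::lowess(ord[qi][-k], y[-k], f = f)
        pred <- stats::approx(lw$x, lw$y, xout = ord[qi][k], rule = 2)$y
        e <- e + (log(max(pred, 1e-12)) - log(y[k]))^2
      }
    }
    e
  })
  spans[which.min(err)]
}

#' QC-based signal drift correction
#'
#' Fits, per feature, a smooth curve to the pooled-QC intensities as a
#' function of injection order and divides every injection by it. The curve
#' is normalized to mean one over the QC injections, so per-feature QC levels
#' are preserved. The default `"loess"` method is a local linear smoother
#' ([stats::lowess]) whose span is chosen by leave-one-out cross-validation
#' on a subsample of features; `"median-ratio"` interpolates QC/median
#' ratios between bracketing QC injections; `"rf"` fits a random forest
#' regression on injection order (requires the randomForest package).
#' All-zero and constant-QC features pass through unchanged.
#'
#' @param fm A [feature_matrix()] with at least 5 QC injections spread across
#'   the run.
#' @param method `"loess"`, `"median-ratio"` or `"rf"`.
#' @param span Lowess span; `NULL` (default) selects it by cross-validation.
#' @return A drift-corrected [feature_matrix()].
#' @export
drift_correct <- function(fm, method = c("loess", "median-ratio", "rf"),
                          span = NULL) {
  method <- match.arg(method)
  qi <- qc_idx(fm)
  if (length(qi) < 5) stop("drift correction requires at least 5 QC injections")
  ord <- fm$meta$injection_order
  if (method == "loess" && is.null(span)) span <- cv_span(fm)
  out <- fm$intensities
  for (f in seq_len(nrow(out))) {
    y <- out[f, qi]
    if (all(out[f, ] == 0)) next
    curve <- drift_curve(ord[qi], y, ord, method, span)
    out[f, ] <- out[f, ] / curve
  }
  feature_matrix(out, fm$meta)
}

#' Replace zeros by half the smallest positive value
#'
#' Every zero cell is replaced by half of the smallest positive value of the
#' full original matrix (matrix-global, before any filtering); no other cell
#' is altered.
#'
#' @param fm A [feature_matrix()] with at least one positive value.
#' @return A [feature_matrix()] without zeros.
#' @export
impute_zeros <- function(fm) {
  x <- fm$intensities
  pos <- x[x > 0]
  if (length(pos) == 0) stop("matrix contains no positive values")
  x[x == 0] <- min(pos) / 2
  feature_matrix(x, fm$meta)
}

#' Remove the lowest features by interquartile range
#'
#' Features are ranked by their IQR across study (non-QC) injections and the
#' `floor(fraction * n)` lowest are removed; ties are broken by row order.
#'
#' @param fm A [feature_matrix()].
#' @param fraction Fraction of features to drop (default 0.10).
#' @return List with `matrix` (filtered [feature_matrix()]) and `removed`
#'   (dropped feature ids).
#' @export
iqr_filter <- function(fm, fraction = 0.10) {
  si <- study_idx(fm)
  iqr <- apply(fm$intensities[, si, drop = FALSE], 1, stats::IQR)
  k <- floor(fraction * nrow(fm$intensities))
  removed <- character(0)
  if (k > 0) {
    ord <- order(iqr)            # stable: ties keep row (feature id) order
    removed <- rownames(fm$intensities)[ord[seq_len(k)]]
  }
  keep <- !(rownames(fm$intensities) %in% removed)
  list(matrix = feature_matrix(fm$intensities[keep, , drop = FALSE], fm$meta),
       removed = removed)
}

#' Remove features with high QC relative standard deviation
#'
#' Features whose RSD over QC injections exceeds `threshold` percent are
#' removed; zero-mean QC features are removed and flagged separately.
#'
#' @param fm A [feature_matrix()] with at least 2 QC injections.
#' @param threshold RSD threshold in percent (default 20).
#' @return List with `matrix`, `removed` (ids) and `flagged_zero_mean`.
#' @export
rsd_filter <- function(fm, threshold = 20) {
  rsd <- qc_rsd(fm)
  zero_mean <- !is.finite(rsd)
  drop <- zero_mean | rsd > threshold
  keep <- !drop
  list(matrix = feature_matrix(fm$intensities[keep, , drop = FALSE], fm$meta),
       removed = rownames(fm$intensities)[drop],
       flagged_zero_mean = rownames(fm$intensities)[zero_mean])
}

#' Log10 transform and Pareto scale
#'
#' Each cell is log10-transformed, then each feature is centered and divided
#' by the square root of its standard deviation, both computed over study
#' (non-QC) injections. Features with zero spread are set to zero and
#' flagged. Input must be strictly positive (run [impute_zeros()] first);
#' the first offending cell is named otherwise.
#'
#' @param fm A strictly positive [feature_matrix()].
#' @return A [feature_matrix()] on the analysis scale, with attribute
#'   `"scaled" = TRUE` and attribute `"flagged_constant"` listing zero-spread
#'   features.
#' @export
transform_scale <- function(fm) {
  x <- fm$intensities
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at feature %s, injection %s",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  lx <- log10(x)
  si <- study_idx(fm)
  mu <- rowMeans(lx[, si, drop = FALSE])
  sdv <- apply(lx[, si, drop = FALSE], 1, stats::sd)
  flagged <- rownames(x)[sdv == 0]
  out <- sweep(lx, 1, mu, "-")
  scale_by <- ifelse(sdv == 0, 1, sqrt(sdv))
  out <- sweep(out, 1, scale_by, "/")
  out[sdv == 0, ] <- 0
  res <- feature_matrix(out, fm$meta)
  attr(res, "scaled") <- TRUE
  attr(res, "flagged_constant") <- flagged
  res
}

#' Full preprocessing chain
#'
#' Runs drift correction, half-minimum imputation, IQR filtering, QC-RSD
#' filtering and log + Pareto scaling, in that fixed order, and reports the
#' per-step bookkeeping. Refuses matrices that are already on the analysis
#' scale.
#'
#' @param fm A raw [feature_matrix()].
#' @param iqr_fraction Fraction dropped by [iqr_filter()].
#' @param rsd_threshold Percent threshold for [rsd_filter()].
#' @param drift_method,drift_span Passed to [drift_correct()].
#' @return List with `matrix` (analysis-scale [feature_matrix()]) and
#'   `report`: input/output feature counts per step, removed ids, and
#'   per-feature QC RSD before and after drift correction.
#' @export
preprocess <- function(fm, iqr_fraction = 0.10, rsd_threshold = 20,
                       drift_method = "loess", drift_span = NULL) {
  if (isTRUE(attr(fm, "scaled")))
    stop("matrix is already on the analysis scale; preprocessing is not idempotent")
  rsd_before <- qc_rsd(fm)
  corrected <- drift_correct(fm, method = drift_method, span = drift_span)
  rsd_after <- qc_rsd(corrected)
  imputed <- impute_zeros(corrected)
  iqr <- iqr_filter(imputed, iqr_fraction)
  rsd <- rsd_filter(iqr$matrix, rsd_threshold)
  scaled <- transform_scale(rsd$matrix)
  report <- list(
    n_input_features = nrow(fm$intensities),
    n_after_iqr = nrow(iqr$matrix$intensities),
    n_after_rsd = nrow(rsd$matrix$intensities),
    removed_iqr = iqr$removed,
    removed_rsd = rsd$removed,
    flagged_zero_mean = rsd$flagged_zero_mean,
    flagged_constant = attr(scaled, "flagged_constant"),
    qc_rsd_before = rsd_before,
    qc_rsd_after = rsd_after)
  stopifnot(report$n_input_features - length(report$removed_iqr) ==
              report$n_after_iqr,
            report$n_after_iqr - length(report$removed_rsd) ==
              report$n_after_rsd)
  list(matrix = scaled, report = report)
}
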