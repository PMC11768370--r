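#' Paired pre/post fit with subject-level covariates
#'
#' Blocking on subject is realized exactly by within-subject differencing:
#' for each subject with both timepoints, the per-feature difference
#' (post - pre) on the analysis scale is regressed on an intercept plus the
#' subject-level covariates. The intercept is the covariate-adjusted mean
#' paired difference. Subjects missing a timepoint are dropped with a
#' warning.
#'
#' @param fm An analysis-scale [feature_matrix()] (see [transform_scale()]).
#' @param traits Subject table carrying the covariate columns.
#' @param covariates Covariate column names (default sex, age, bmi, period).
#'   Use `character(0)` for an intercept-only fit.
#' @return List with `feature_id`, `estimate` (adjusted mean difference per
#'   feature), `s2` (residual variance), `df` (residual degrees of freedom),
#'   `stdev_unscaled` (unit standard error of the intercept) and `n_pairs`.
#' @export
paired_design_fit <- function(fm, traits,
                              covariates = c("sex", "age", "bmi", "period")) {
  meta <- fm$meta[fm$meta$timepoint != "QC", ]
  subs <- unique(meta$subject_id)
  have_both <- vapply(subs, function(s) {
    tp <- meta$timepoint[meta$subject_id == s]
    all(c("pre", "post") %in% tp)
  }, logical(1))
  if (any(!have_both))
    warning("dropping subjects without both timepoints: ",
            paste(subs[!have_both], collapse = ", "))
  subs <- subs[have_both]
  if (length(subs) < 3) stop("need at least 3 complete subject pairs")
  pre_col <- post_col <- integer(length(subs))
  for (i in seq_along(subs)) {
    pre_col[i] <- which(fm$meta$subject_id %in% subs[i] &
                          fm$meta$timepoint == "pre")[1]
    post_col[i] <- which(fm$meta$subject_id %in% subs[i] &
                           fm$meta$timepoint == "post")[1]
  }
  D <- fm$intensities[, post_col, drop = FALSE] -
       fm$intensities[, pre_col, drop = FALSE]   # features x subjects
  colnames(D) <- subs

  tr <- traits[match(subs, traits$subject_id), , drop = FALSE]
  if (length(covariates) > 0) {
    missing_cov <- setdiff(covariates, names(tr))
    if (length(missing_cov) > 0)
      stop("covariates not found in traits: ",
           paste(missing_cov, collapse = ", "))
    form <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
    X <- stats::model.matrix(form, data = tr)
    # center covariate columns so the intercept is the covariate-adjusted
    # mean paired difference (and orthogonal to centered covariates)
    if (ncol(X) > 1)
      X[, -1] <- sweep(X[, -1, drop = FALSE], 2,
                       colMeans(X[, -1, drop = FALSE]), "-")
  } else {
    X <- matrix(1, length(subs), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular covariate design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, t(D))
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1)
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  df <- length(subs) - ncol(X)
  s2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrX))
  list(feature_id = rownames(fm$intensities),
       estimate = as.numeric(coefs["(Intercept)", ]),
       s2 = as.numeric(s2), df = df,
       stdev_unscaled = sqrt(xtxinv[1, 1]),
       n_pairs = length(subs))
}

# Newton inversion of the trigamma function (for the variance-prior moment
# estimator).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks per-feature residual variances toward a common prior estimated by
#' closed-form method of moments on the log sample variances: with
#' `e = log s^2 - digamma(df/2) + log(df/2)`, the prior degrees of freedom
#' solve `trigamma(d0/2) = var(e) - trigamma(df/2)` and the prior variance is
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. Posterior variances are
#' `(d0 s0^2 + df s^2) / (d0 + df)`; moderated t-statistics use `d0 + df`
#' degrees of freedom. A non-positive moment estimate gives an infinite prior
#' (complete shrinkage); `prior_df = 0` forces ordinary t-statistics.
#'
#' @param fit Result of [paired_design_fit()] (at least 10 features unless
#'   `prior_df` is supplied).
#' @param prior_df Optional fixed prior degrees of freedom; `NULL` estimates
#'   them from the data.
#' @return Data.frame with `feature_id`, `estimate`, `t_mod`, `p`, `df_total`,
#'   `s2_post`; attributes `"d0"` and `"s0_2"` carry the prior.
#' @export
eb_moderate <- function(fit, prior_df = NULL) {
  s2 <- fit$s2
  d <- fit$df
  m <- length(s2)
  if (is.null(prior_df) && m < 10)
    stop("variance-prior estimation needs at least 10 features")
  if (all(s2 == 0)) {
    warning("all residual variances are zero; falling back to ordinary t")
    prior_df <- 0
  }
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s0_2 <- if (d0 > 0) mean(s2) else NA_real_
  } else {
    e <- log(pmax(s2, 1e-300)) - digamma(d / 2) + log(d / 2)
    evar <- mean((e - mean(e))^2) * m / (m - 1) - trigamma(d / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    }
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, m)
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  df_total <- d0 + d
  t_mod <- fit$estimate / (sqrt(s2_post) * fit$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(feature_id = fit$feature_id, estimate = fit$estimate,
                    t_mod = t_mod, p = p, df_total = df_total,
                    s2_post = s2_post, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` p-values are excluded from the ranking and
#' propagated as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (or `NA`).
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Select features at an FDR threshold
#'
#' @param results Data.frame with `feature_id` and `q` columns.
#' @param alpha FDR threshold (default 0.05).
#' @return Feature ids with `q <= alpha`, in the input row order.
#' @export
select_features <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) return(character(0))
  results$feature_id[!is.na(results$q) & results$q <= alpha]
}

#' Differential abundance between pre- and post-dose samples
#'
#' Convenience wrapper: paired covariate-adjusted fit, empirical-Bayes
#' moderation, BH adjustment and selection at `q <= alpha`.
#'
#' @inheritParams paired_design_fit
#' @inheritParams eb_moderate
#' @param alpha FDR threshold.
#' @return Data.frame with `feature_id`, `estimate`, `t_mod`, `p`, `q`,
#'   `selected`.
#' @export
diff_abundance <- function(fm, traits,
                           covariates = c("sex", "age", "bmi", "period"),
                           alpha = 0.05, prior_df = NULL) {
  fit <- paired_design_fit(fm, traits, covariates)
  res <- eb_moderate(fit, prior_df)
  res$q <- bh_adjust(res$p)
  res$selected <- !is.na(res$q) & res$q <= alpha
  res[, c("feature_id", "estimate", "t_mod", "p", "q", "selected")]
}
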