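#' Trapezoidal area under the concentration-time curve
#'
#' Integrates observed concentrations from time zero to the last observed
#' time. `NA` concentrations (the missing / below-quantification code) are
#' dropped; recorded zeros are kept as data. The default is the linear
#' trapezoid; `"linlog"` uses the log trapezoid on strictly decreasing
#' positive segments and the linear rule elsewhere.
#'
#' @param times Sampling times in hours (unique, non-negative, ascending).
#' @param conc Concentrations in ug/mL, same length; non-negative or `NA`.
#' @param method `"linear"` (default) or `"linlog"`.
#' @return AUC0-t in h*ug/mL.
#' @export
compute_auc <- function(times, conc, method = c("linear", "linlog")) {
  method <- match.arg(method)
  keep <- !is.na(conc)
  times <- times[keep]; conc <- conc[keep]
  validate_profile(times, conc, min_points = 2)
  n <- length(times)
  dt <- diff(times)
  c1 <- conc[-n]; c2 <- conc[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linlog") {
    lg <- c2 < c1 & c2 > 0 & c1 > 0
    seg[lg] <- dt[lg] * (c1[lg] - c2[lg]) / log(c1[lg] / c2[lg])
  }
  sum(seg)
}

validate_profile <- function(times, conc, min_points = 3) {
  if (length(times) != length(conc))
    stop("times and concentrations must have equal length")
  if (length(times) < min_points)
    stop(sprintf("profile needs at least %d points", min_points))
  if (any(is.na(times)) || any(times < 0) || anyDuplicated(times) ||
      is.unsorted(times, strictly = TRUE))
    stop("times must be unique, non-negative and ascending")
  if (any(conc < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  invisible(TRUE)
}

#' Estimate the terminal elimination rate constant
#'
#' Best-fit terminal log-linear regression in the style of standard
#' non-compartmental software: starting from the last three positive
#' concentrations strictly after Tmax and successively adding earlier points
#' (windows always end at the last positive observation and must be
#' contiguous), ordinary least squares of log concentration on time is fitted
#' in each window and the one with the best adjusted R-squared is kept (ties
#' broken toward more points). Anchoring at the last observation keeps the
#' search inside the terminal phase and avoids the variance-inflating
#' cherry-picking of short interior windows. The estimate is minus the
#' fitted slope; a best slope that is not negative leaves the rate constant
#' undefined.
#'
#' @param times,conc Profile as in [compute_auc()].
#' @return List with `kel` (1/h, `NA` when undefined), `n_terminal_points`
#'   and `terminal_r2` (adjusted R-squared of the selected fit).
#' @export
estimate_kel <- function(times, conc) {
  keep <- !is.na(conc)
  times <- times[keep]; conc <- conc[keep]
  validate_profile(times, conc, min_points = 3)
  imax <- which.max(conc)
  idx <- which(seq_along(conc) > imax & conc > 0)
  undefined <- list(kel = NA_real_, n_terminal_points = NA_integer_,
                    terminal_r2 = NA_real_)
  if (length(idx) < 3) return(undefined)
  last <- idx[length(idx)]
  best <- NULL
  for (i in seq_len(length(idx) - 2)) {
    w <- idx[i]:last
    if (!all(w %in% idx)) next       # interrupted by a zero
    x <- times[w]; y <- log(conc[w])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    nw <- length(w)
    adj <- 1 - (1 - r2) * (nw - 1) / (nw - 2)
    if (is.null(best) || adj > best$adj + 1e-12 ||
        (abs(adj - best$adj) <= 1e-12 && nw > best$n))
      best <- list(slope = slope, n = nw, adj = adj)
  }
  if (is.null(best) || best$slope >= 0) return(undefined)
  list(kel = unname(-best$slope), n_terminal_points = best$n,
       terminal_r2 = unname(best$adj))
}

#' Non-compartmental parameters for one profile
#'
#' @param times,conc Profile as in [compute_auc()].
#' @param auc_method AUC trapezoid rule, see [compute_auc()].
#' @return One-row data.frame: `auc0t`, `cmax`, `tmax`, `kel`, `t_half`
#'   (`ln 2 / kel`), `n_terminal_points`, `terminal_r2`. Undefined elimination
#'   propagates as `NA` in `kel`/`t_half`.
#' @export
nca_profile <- function(times, conc, auc_method = "linear") {
  keep <- !is.na(conc)
  t2 <- times[keep]; c2 <- conc[keep]
  validate_profile(t2, c2, min_points = 3)
  imax <- which.max(c2)
  kel <- estimate_kel(times, conc)
  data.frame(auc0t = compute_auc(times, conc, auc_method),
             cmax = c2[imax], tmax = t2[imax],
             kel = kel$kel,
             t_half = if (is.na(kel$kel)) NA_real_ else log(2) / kel$kel,
             n_terminal_points = kel$n_terminal_points,
             terminal_r2 = kel$terminal_r2)
}

#' Per-subject non-compartmental PK table
#'
#' @param profiles Data.frame with columns `subject_id`, `time_h`,
#'   `conc_ug_per_ml` (one row per observation).
#' @param auc_method AUC trapezoid rule, see [compute_auc()].
#' @return Data.frame with one row per subject and the [nca_profile()]
#'   columns.
#' @export
compute_pk_table <- function(profiles, auc_method = "linear") {
  stopifnot(all(c("subject_id", "time_h", "conc_ug_per_ml") %in%
                  names(profiles)))
  ids <- unique(profiles$subject_id)
  if (length(ids) < 1) stop("at least one profile required")
  rows <- lapply(ids, function(id) {
    p <- profiles[profiles$subject_id == id, ]
    p <- p[order(p$time_h), ]
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE),
          nca_profile(p$time_h, p$conc_ug_per_ml, auc_method))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of a PK table
#'
#' Arithmetic mean and standard deviation per parameter; subjects with an
#' undefined parameter are excluded pairwise.
#'
#' @param pk_table Result of [compute_pk_table()].
#' @return Data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_pk <- function(pk_table) {
  pars <- c("auc0t", "cmax", "tmax", "kel", "t_half")
  do.call(rbind, lapply(pars, function(p) {
    x <- pk_table[[p]]
    data.frame(parameter = p, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE), n = sum(!is.na(x)),
               stringsAsFactors = FALSE)
  }))
}
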