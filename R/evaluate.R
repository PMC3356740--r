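#' Correlation index
#'
#' Squared product-moment correlation between observed and estimated
#' radiation; invariant to linear rescaling of either argument.
#'
#' @param obs,est aligned numeric vectors; pairs with `NA` are dropped.
#' @return value in \[0, 1\].
#' @export
r_squared <- function(obs, est) {
  if (length(obs) != length(est)) stop("length mismatch")
  ok <- !is.na(obs) & !is.na(est)
  obs <- obs[ok]; est <- est[ok]
  if (length(obs) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(obs) == 0 || stats::sd(est) == 0)
    stop("zero variance in obs or est")
  stats::cor(obs, est)^2
}

#' Accuracy index
#'
#' Root mean square error sqrt(sum((obs - est)^2)/n), in the units of the
#' series (MJ m-2 d-1 for radiation).
#' @inheritParams r_squared
#' @return nonnegative RMSE.
#' @export
rmse <- function(obs, est) {
  if (length(obs) != length(est)) stop("length mismatch")
  ok <- !is.na(obs) & !is.na(est)
  if (!any(ok)) stop("no complete pairs")
  sqrt(mean((obs[ok] - est[ok])^2))
}

#' Mean relative error
#'
#' Mean of |est - obs| / obs, in percent. Records with nonpositive observed
#' values carry no relative information and are excluded (their count is
#' attached as attribute `n_excluded`).
#' @inheritParams r_squared
#' @return MRE in percent.
#' @export
mre <- function(obs, est) {
  if (length(obs) != length(est)) stop("length mismatch")
  ok <- !is.na(obs) & !is.na(est)
  excl <- sum(ok & obs <= 0)
  use <- ok & obs > 0
  if (!any(use)) stop("no usable records with positive obs")
  structure(100 * mean(abs(est[use] - obs[use]) / obs[use]),
            n_excluded = excl)
}

#' Interval specification for the pattern index
#'
#' @param by grouping variable: `"doy"` (calendar quarters of the DOY axis,
#'   boundaries 1-91, 92-182, 183-273, 274-end) or `"tmin"` (k equal-width
#'   bins over the observed minimum-temperature range).
#' @param k number of intervals (>= 2); fixed at 4 for `"doy"`.
#' @param min_count intervals with fewer days are left out of the pairwise
#'   maximum (default 1 for `"doy"`, 5 for `"tmin"`).
#' @return list of class `interval_spec`.
#' @export
interval_spec <- function(by = c("doy", "tmin"), k = 4L, min_count = NULL) {
  by <- match.arg(by)
  k <- as.integer(k)
  if (k < 2) stop("need k >= 2 intervals")
  if (is.null(min_count)) min_count <- if (by == "doy") 1L else 5L
  structure(list(by = by, k = k, min_count = as.integer(min_count)),
            class = "interval_spec")
}

# interval membership of each day under a spec
interval_index <- function(spec, doy = NULL, tmin = NULL) {
  if (spec$by == "doy") {
    if (is.null(doy)) stop("doy needed for DOY intervals")
    findInterval(doy, c(1, 92, 183, 274))
  } else {
    if (is.null(tmin)) stop("tmin needed for Tmin intervals")
    rng <- range(tmin, na.rm = TRUE)
    if (diff(rng) == 0) stop("tmin has zero range; cannot form intervals")
    brk <- seq(rng[1], rng[2], length.out = spec$k + 1)
    pmin(pmax(findInterval(tmin, brk, rightmost.closed = TRUE), 1L), spec$k)
  }
}

#' Pattern index of the residuals
#'
#' Groups the residuals est - obs into intervals (calendar quarters of the
#' year for PI_doy, equal-width bins of observed minimum temperature for
#' PI_Tmin) and returns the maximum absolute difference between the mean
#' residuals of any two eligible intervals. A small value means the
#' estimation error carries no systematic seasonal or temperature-dependent
#' component -- the property crop models care most about.
#'
#' @param obs,est aligned radiation vectors.
#' @param intervals an [interval_spec()].
#' @param doy,tmin grouping variables matching the spec.
#' @return pattern index in the units of the series.
#' @export
pattern_index <- function(obs, est, intervals, doy = NULL, tmin = NULL) {
  if (length(obs) != length(est)) stop("length mismatch")
  idx <- interval_index(intervals, doy = doy, tmin = tmin)
  ok <- !is.na(obs) & !is.na(est) & !is.na(idx)
  res <- est[ok] - obs[ok]
  idx <- idx[ok]
  cnt <- tapply(res, idx, length)
  mns <- tapply(res, idx, mean)
  mns <- mns[cnt >= intervals$min_count]
  if (length(mns) < 2)
    stop("fewer than 2 eligible intervals for the pattern index")
  max(abs(outer(mns, mns, "-")))
}

#' Full error-index report for one obs/est pairing
#'
#' Computes the three indicator families at once: correlation (R^2),
#' accuracy (RMSE, MRE) and pattern (PI_doy over the four calendar
#' quarters, PI_Tmin over four equal-width bins of observed minimum
#' temperature).
#'
#' @param obs,est aligned radiation vectors, MJ m-2 d-1.
#' @param doy day-of-year labels of the records.
#' @param tmin observed minimum temperatures of the records, degrees C.
#' @return list of class `error_indices` with elements `r2`, `rmse`,
#'   `pi_doy`, `pi_tmin`, `mre`, `n`.
#' @export
evaluate <- function(obs, est, doy, tmin) {
  ok <- !is.na(obs) & !is.na(est) & !is.na(doy) & !is.na(tmin)
  obs <- obs[ok]; est <- est[ok]; doy <- doy[ok]; tmin <- tmin[ok]
  structure(list(
    r2 = r_squared(obs, est),
    rmse = rmse(obs, est),
    pi_doy = pattern_index(obs, est, interval_spec("doy"), doy = doy),
    pi_tmin = pattern_index(obs, est, interval_spec("tmin"), tmin = tmin),
    mre = as.numeric(mre(obs, est)),
    n = length(obs)), class = "error_indices")
}

#' @export
print.error_indices <- function(x, ...) {
  cat(sprintf(
    "R2 = %.3f  RMSE = %.3f  PI_doy = %.3f  PI_Tmin = %.3f  MRE = %.2f%%  (n = %d)\n",
    x$r2, x$rmse, x$pi_doy, x$pi_tmin, x$mre, x$n))
  invisible(x)
}

#' Write a multi-model evaluation report
#'
#' One row per (site, model) with the full index set, in the layout of a
#' model-comparison table.
#'
#' @param rows list of lists with elements `site`, `model`, and an
#'   `error_indices` object under `indices`.
#' @param path output CSV path.
#' @return the report `data.frame`, invisibly.
#' @export
write_report <- function(rows, path) {
  df <- do.call(rbind, lapply(rows, function(r) {
    ix <- r$indices
    data.frame(site = r$site, model = r$model, r2 = ix$r2, rmse = ix$rmse,
               pi_doy = ix$pi_doy, pi_tmin = ix$pi_tmin, mre = ix$mre,
               n = ix$n)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
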