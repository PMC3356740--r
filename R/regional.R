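#' Clear-sky transmissivity from site metadata
#'
#' The cross-site regression of constant clear-sky transmissivity on the
#' average diurnal temperature range:
#' tau = 0.00591 * dt_avg + 0.6758 (r = 0.727).
#'
#' @param dt_avg average diurnal temperature range, degrees C.
#' @return dimensionless transmissivity.
#' @examples
#' regional_tau(12)  # 0.74672
#' @export
regional_tau <- function(dt_avg) {
  0.00591 * dt_avg + 0.6758
}

# one regionalization rule applied to a metadata record
apply_rule <- function(rule, metadata) {
  if (rule$type == "mean") rule$value
  else rule$slope * metadata[[rule$covariate]] + rule$intercept
}

#' Default regionalization rules for the 7-parameter variant
#'
#' The published rule set for the metadata-only model on the central US
#' plains: tau from the dt_avg regression; the Fcd asymptote a, scale b,
#' precipitation factor c and the leading Fs cosine coefficient d fixed at
#' their cross-site means (a = 0.476, b = 0.106, c = 2.25, d = -0.259,
#' their coefficients of variation being low); the remaining Fs
#' coefficients from linear regressions on dt_avg. An alternative
#' regression for the last Fs coefficient (slope -0.0036, intercept
#' 0.0755, r = -0.905) is carried as `g_alt` but unused by default.
#'
#' @return list of class `regional_rule`, one rule per parameter of the
#'   0-2-1-4 variant.
#' @export
regional_rules_default <- function() {
  lin <- function(cov, slope, intercept, r)
    list(type = "linear", covariate = cov, slope = slope,
         intercept = intercept, r = r)
  cst <- function(value) list(type = "mean", value = value)
  structure(list(
    tau = lin("dt_avg", 0.00591, 0.6758, 0.727),
    a = cst(0.476),
    b = cst(0.106),
    c = cst(2.25),
    d = cst(-0.259),
    e = lin("dt_avg", -0.00377, 0.0312, -0.816),
    f = lin("dt_avg", -0.00341, 0.0597, -0.815),
    g = lin("dt_avg", -0.00076, 0.0320, -0.400),
    g_alt = lin("dt_avg", -0.0036, 0.0755, -0.905)),
    class = "regional_rule")
}

#' Metadata-only parameters for the 7-parameter variant
#'
#' Builds a complete parameter set for the 0-2-1-4 variant from site
#' metadata alone -- zero parameters left for site-specific fitting -- so a
#' station without any radiation record can be served.
#'
#' @param metadata a [site_metadata()] with `dt_avg` present.
#' @param rules a [regional_rules_default()]-style rule set.
#' @param use_alt_g substitute the alternative regression for the last Fs
#'   coefficient.
#' @return a [parameter_set()] for [parse_variant()]`("0-2-1-4")`.
#' @export
regional_parameters <- function(metadata, rules = regional_rules_default(),
                                use_alt_g = FALSE) {
  if (is.na(metadata$dt_avg)) stop("metadata must carry dt_avg")
  need <- c("tau", "a", "b", "c", "d", "e", "f", "g")
  miss <- setdiff(need, names(rules))
  if (length(miss)) stop("rule set lacks parameter(s): ",
                         paste(miss, collapse = ", "))
  v <- vapply(need, function(p) apply_rule(rules[[p]], metadata), numeric(1))
  if (use_alt_g) v["g"] <- apply_rule(rules$g_alt, metadata)
  parameter_set(tau_coeffs = v[["tau"]],
                fcd_groups = list(all = c(f = v[["a"]], g = v[["b"]],
                                          n = 2.285)),
                q = v[["c"]],
                fs_coeffs = v[c("d", "e", "f", "g")])
}

# flatten a 0-2-1-4-shaped parameter set to the named scalar vector used
# by the rule builder
flatten_regional_params <- function(params) {
  fs <- params$fs_coeffs
  if (length(fs) != 4) stop("rule building needs 4 Fs coefficients")
  c(tau = unname(params$tau_coeffs[1]),
    a = unname(params$fcd_groups[[1]]["f"]),
    b = unname(params$fcd_groups[[1]]["g"]),
    c = unname(params$q),
    d = unname(fs[1]), e = unname(fs[2]), f = unname(fs[3]),
    g = unname(fs[4]))
}

#' Build regionalization rules from calibrated sites
#'
#' Given per-site calibrated parameter sets of the 7-parameter variant,
#' derives a metadata-only rule per parameter: parameters whose coefficient
#' of variation across sites is at most `cv_threshold` are fixed at their
#' mean; the rest get the best single-covariate linear regression (by |r|)
#' among latitude, altitude, t_avg, dt_avg and p_annual.
#'
#' @param sites list of `list(metadata = site_metadata, params =
#'   parameter_set)` entries, at least 3.
#' @param cv_threshold coefficient-of-variation cutoff for the mean rule.
#' @return list of class `regional_rule`.
#' @export
build_regional_rules <- function(sites, cv_threshold = 0.2) {
  if (length(sites) < 3) stop("need at least 3 calibrated sites")
  vals <- t(vapply(sites, function(s) flatten_regional_params(s$params),
                   numeric(8)))
  covs <- c("latitude", "altitude", "t_avg", "dt_avg", "p_annual")
  meta <- t(vapply(sites, function(s)
    vapply(covs, function(cv) as.numeric(s$metadata[[cv]]), numeric(1)),
    numeric(length(covs))))
  colnames(meta) <- covs
  rules <- list()
  for (p in colnames(vals)) {
    y <- vals[, p]
    m <- mean(y)
    cv <- if (abs(m) > 0) stats::sd(y) / abs(m) else Inf
    if (cv > cv_threshold) {
      best <- NULL
      for (cvn in covs) {
        x <- meta[, cvn]
        if (anyNA(x) || stats::sd(x) == 0) next
        r <- stats::cor(x, y)
        if (is.null(best) || abs(r) > abs(best$r)) {
          fit <- stats::lm(y ~ x)
          best <- list(type = "linear", covariate = cvn,
                       slope = unname(stats::coef(fit)[2]),
                       intercept = unname(stats::coef(fit)[1]), r = r)
        }
      }
      if (is.null(best)) stop("no usable covariate for parameter ", p)
      rules[[p]] <- best
    } else {
      rules[[p]] <- list(type = "mean", value = m)
    }
  }
  rules$g_alt <- rules$g
  class(rules) <- "regional_rule"
  rules
}
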