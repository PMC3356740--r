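#' Configuration of the synthetic weather generator
#'
#' Describes a virtual station: seasonal temperature cycles with AR(1)
#' day-to-day persistence, first-order Markov-chain precipitation
#' occurrence with exponential wet-day amounts, a wet-day reduction of the
#' diurnal range (the contrast the precipitation terms of the radiation
#' models exploit), and observed radiation generated from a known S-shape
#' variant plus multiplicative lognormal noise. Years are 365 days long by
#' default so DOY bookkeeping stays trivial; a leap-year calendar is
#' available.
#'
#' @param n_years number of simulated years (>= 1).
#' @param latitude site latitude, decimal degrees.
#' @param start_year first calendar year of the series.
#' @param tmin_mean,tmin_amp annual mean and amplitude of the minimum
#'   temperature sinusoid, degrees C (peak near midsummer).
#' @param dt_mean,dt_amp annual mean and amplitude of the dry-day diurnal
#'   temperature range, degrees C.
#' @param ar1,t_noise_sd AR(1) coefficient and innovation s.d. of the
#'   day-to-day temperature anomaly, degrees C.
#' @param dt_noise_sd s.d. of the day-to-day range noise, degrees C.
#' @param p_ww,p_dw Markov wet-after-wet and wet-after-dry probabilities.
#' @param prcp_scale mean wet-day precipitation amount (exponential), mm.
#' @param wet_dt_factor multiplier (< 1) applied to the diurnal range on
#'   wet days.
#' @param spec generating S-shape variant (a [variant_spec()] or notation).
#' @param true_params generating [parameter_set()]; `NULL` takes the
#'   default virtual-station truth: tau from [regional_tau()] at
#'   `dt_avg = dt_mean`, Fcd floor 0.476, scale 0.106 /degC, exponent
#'   2.285, a modest wet-day factor q = 0.2, no Fs term.
#' @param rs_noise_sd s.d. of the multiplicative lognormal radiation noise
#'   (0.05 is a typical 5 percent instrument/model scatter).
#' @param bias_coeffs optional Fs-style coefficients of a seasonal bias
#'   multiplied into the generated radiation.
#' @param clip lower/upper clip band for the generated radiation as
#'   fractions of Ra (default `c(0.03, 0.8)`, emulating pyranometer QC
#'   limits). Release the upper bound (`Inf`) when the generating
#'   parameters themselves are meant to exceed it, otherwise the clipped
#'   truth is unrecoverable by construction.
#' @param leap_years use the real calendar with leap days.
#' @param seed integer seed; every random draw derives from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 30L, latitude = 40, start_year = 1961L,
                             tmin_mean = 8, tmin_amp = 10,
                             dt_mean = 11, dt_amp = 3,
                             ar1 = 0.7, t_noise_sd = 2, dt_noise_sd = 1.5,
                             p_ww = 0.45, p_dw = 0.25, prcp_scale = 6,
                             wet_dt_factor = 0.75,
                             spec = "0-2-1-4", true_params = NULL,
                             rs_noise_sd = 0.05, bias_coeffs = NULL,
                             clip = c(0.03, 0.8),
                             leap_years = FALSE, seed = 1L) {
  stopifnot(n_years >= 1, p_ww >= 0, p_ww <= 1, p_dw >= 0, p_dw <= 1,
            tmin_amp >= 0, dt_amp >= 0, dt_mean > 0, prcp_scale > 0,
            wet_dt_factor > 0, wet_dt_factor <= 1, rs_noise_sd >= 0,
            length(clip) == 2, clip[1] >= 0, clip[2] > clip[1])
  if (is.character(spec)) spec <- parse_variant(spec)
  structure(list(n_years = as.integer(n_years), latitude = latitude,
                 start_year = as.integer(start_year),
                 tmin_mean = tmin_mean, tmin_amp = tmin_amp,
                 dt_mean = dt_mean, dt_amp = dt_amp, ar1 = ar1,
                 t_noise_sd = t_noise_sd, dt_noise_sd = dt_noise_sd,
                 p_ww = p_ww, p_dw = p_dw, prcp_scale = prcp_scale,
                 wet_dt_factor = wet_dt_factor, spec = spec,
                 true_params = true_params, rs_noise_sd = rs_noise_sd,
                 bias_coeffs = bias_coeffs, clip = clip,
                 leap_years = leap_years, seed = as.integer(seed)),
            class = "synthetic_config")
}

# run code with a local RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-year weather series
#'
#' Draws a daily series from the configured stochastic processes, then
#' generates observed radiation from the configured S-shape variant with
#' its true parameters, multiplies in lognormal noise (and the optional
#' seasonal bias), and clips the result to the configured band (default
#' \[0.03 Ra, 0.8 Ra\]). Fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `ws` (a [weather_series()]), `metadata` (the
#'   [site_metadata()] of the virtual site, `dt_avg` set to the configured
#'   dry-day mean range), `truth` (generating spec, parameter set, tau) and
#'   `config`.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- config$start_year + seq_len(config$n_years) - 1L
  ylen <- if (config$leap_years) ifelse(is_leap_year(years), 366L, 365L)
          else rep(365L, config$n_years)
  year <- rep(years, ylen)
  doy <- unlist(lapply(ylen, seq_len))
  n <- length(doy)
  phase <- 2 * pi * (doy - 196) / 365

  metadata <- site_metadata(latitude = config$latitude,
                            t_avg = config$tmin_mean + config$dt_mean / 2,
                            dt_avg = config$dt_mean,
                            p_annual = NA_real_)
  params <- config$true_params
  if (is.null(params))
    params <- parameter_set(
      tau_coeffs = regional_tau(metadata$dt_avg),
      fcd_groups = list(all = c(f = 0.476, g = 0.106, n = 2.285)),
      q = 0.2, fs_coeffs = numeric())

  out <- with_seed(config$seed, {
    anom <- numeric(n)
    innov <- stats::rnorm(n, 0, config$t_noise_sd)
    for (i in 2:n) anom[i] <- config$ar1 * anom[i - 1] + innov[i]
    anom[1] <- innov[1]
    tmin <- config$tmin_mean + config$tmin_amp * cos(phase) + anom

    wet <- integer(n)
    u <- stats::runif(n)
    wet[1] <- as.integer(u[1] < config$p_dw)
    for (i in 2:n)
      wet[i] <- as.integer(u[i] < if (wet[i - 1] == 1) config$p_ww
                                  else config$p_dw)
    prcp <- ifelse(wet == 1,
                   0.1 + stats::rexp(n, rate = 1 / config$prcp_scale), 0)

    dtr <- config$dt_mean + config$dt_amp * cos(phase) +
      stats::rnorm(n, 0, config$dt_noise_sd)
    dtr <- ifelse(wet == 1, dtr * config$wet_dt_factor, dtr)
    dtr <- pmax(dtr, 0.5)
    noise <- if (config$rs_noise_sd > 0)
      exp(stats::rnorm(n, 0, config$rs_noise_sd)) else rep(1, n)
    list(tmin = tmin, prcp = prcp, dtr = dtr, noise = noise)
  })

  ws <- weather_series(year = year, doy = doy,
                       tmax = out$tmin + out$dtr, tmin = out$tmin,
                       prcp = out$prcp)
  rs <- estimate_s_shape(ws, config$spec, params, metadata)
  rs <- rs * out$noise
  if (!is.null(config$bias_coeffs))
    rs <- rs * fs_series(config$bias_coeffs, doy)
  ra <- extraterrestrial_radiation(config$latitude, doy)
  ws$rs_obs <- pmin(pmax(rs, config$clip[1] * ra), config$clip[2] * ra)
  metadata$p_annual <- sum(ws$prcp) / config$n_years
  tau_true <- if (config$spec$tau_form == "from_metadata")
    regional_tau(metadata$dt_avg) else params$tau_coeffs[1]
  list(ws = ws, metadata = metadata,
       truth = list(spec = config$spec, params = params, tau = tau_true),
       config = config)
}

#' Multiply a known seasonal bias into observed radiation
#'
#' Applies the Fs-type Fourier series with the given coefficients to
#' `rs_obs`, emulating the site-specific annual bias pattern that stage 2
#' of the calibration is designed to remove.
#'
#' @param ws a [weather_series()] with `rs_obs`.
#' @param fs_coeffs Fs coefficients (length 2 or 4); all-zero leaves the
#'   series unchanged.
#' @return the modified series.
#' @export
inject_seasonal_bias <- function(ws, fs_coeffs) {
  if (all(is.na(ws$rs_obs))) stop("series has no observed radiation")
  fs <- fs_series(fs_coeffs, ws$doy)
  out <- ws$rs_obs * fs
  if (any(out <= 0, na.rm = TRUE))
    stop("bias coefficients drive observed radiation nonpositive")
  ws$rs_obs <- out
  ws
}

#' Parameter-recovery experiment
#'
#' Generates a series with known truth, calibrates the given variant on it,
#' and reports per-parameter relative errors plus the pattern index before
#' and after stage 2 -- the package's self-check that the double-step
#' calibration recovers what the generator put in.
#'
#' @param config a [synthetic_config()] (the generating side).
#' @param spec calibration variant; default the generating spec.
#' @param calib_config a [calibration_config()].
#' @return list with `truth`, `fitted` (a [calibration_result()]),
#'   and `report` (data.frame of true value, recovered value and relative
#'   error for the Fcd parameters, q and tau).
#' @export
recovery_experiment <- function(config, spec = NULL,
                                calib_config = calibration_config()) {
  sim <- generate_weather(config)
  if (is.null(spec)) spec <- config$spec
  if (is.character(spec)) spec <- parse_variant(spec)
  fit <- calibrate(sim$ws, spec, sim$metadata, calib_config)
  tp <- sim$truth$params
  fp <- fit$params
  tg <- tp$fcd_groups[[1]]; fg <- fp$fcd_groups[[1]]
  tau_hat <- if (spec$tau_form == "from_metadata")
    regional_tau(sim$metadata$dt_avg) else fp$tau_coeffs[1]
  rows <- data.frame(
    parameter = c("f", "g", "q", "tau"),
    true = c(tg[["f"]], tg[["g"]], tp$q, sim$truth$tau),
    recovered = c(fg[["f"]], fg[["g"]], fp$q, tau_hat))
  rows$rel_error <- (rows$recovered - rows$true) / rows$true
  list(truth = sim$truth, fitted = fit, report = rows,
       stage1_pi_doy = fit$stage1_indices$pi_doy,
       final_pi_doy = fit$final_indices$pi_doy)
}
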