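#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere daily shortwave radiation from the standard daily
#' astronomical formula (solar constant 0.0820 MJ m-2 min-1, inverse
#' relative Earth-Sun distance, solar declination, sunset hour angle).
#' This is the upper envelope Ra that every estimation formula scales.
#'
#' @param latitude decimal degrees, in \[-90, 90\].
#' @param doy day of year (1--366); vectors recycle against `latitude`.
#' @return Ra in MJ m-2 d-1; 0 during polar night.
#' @examples
#' extraterrestrial_radiation(-20, 246)  # ~32.2
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  if (any(latitude < -90 | latitude > 90))
    stop("latitude outside [-90, 90]")
  if (any(doy < 1 | doy > 366)) stop("doy outside 1..366")
  phi <- latitude * pi / 180
  x <- 2 * pi * doy / 365
  dr <- 1 + 0.033 * cos(x)
  delta <- 0.409 * sin(x - 1.39)
  cws <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(cws)
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(ra, 0)
}

#' Fourier-series clear-sky transmissivity
#'
#' tau(i) = a + b cos(2 pi i/365) + c sin(2 pi i/365)
#'        + d cos(4 pi i/365) + e sin(4 pi i/365),
#' tracking the annual course of clear-sky transmissivity. The period is
#' fixed at 365 days regardless of leap years (DOY 366 evaluates at i=366).
#' Values outside (0, 1) are physically meaningless; they are returned
#' unclamped with a warning so calibration diagnostics can see them.
#'
#' @param coeffs numeric vector of length 5 (2nd order), 3 (1st order) or
#'   1 (constant), in the order a, b, c, d, e.
#' @param doy day of year.
#' @return dimensionless transmissivity vector.
#' @export
fourier_tau <- function(coeffs, doy) {
  k <- length(coeffs)
  if (!k %in% c(1L, 3L, 5L))
    stop("tau coefficient vector must have length 1, 3 or 5")
  x <- 2 * pi * doy / 365
  tau <- rep_len(coeffs[1], length(doy))
  if (k >= 3) tau <- tau + coeffs[2] * cos(x) + coeffs[3] * sin(x)
  if (k == 5) tau <- tau + coeffs[4] * cos(2 * x) + coeffs[5] * sin(2 * x)
  if (any(tau <= 0 | tau >= 1))
    warning("transmissivity outside (0, 1) for some days")
  tau
}

#' S-shaped fraction-of-clear-day curves
#'
#' Map the diurnal temperature range to the fraction of clear day, the
#' cloudiness multiplier in \[f, 1). Both curves rise from f at zero range
#' toward 1 for large ranges and are monotone nondecreasing. The van
#' Genuchten form is Fcd = 1 - (1-f) / (1 + (g dT)^n)^m; the Brutsaert
#' form is its m = 1 special case with one parameter fewer.
#'
#' @param dt diurnal temperature range, degrees C (>= 0).
#' @param f value at dT = 0, in \[0, 1\] (radiation stays positive even on
#'   days with no temperature change).
#' @param g inverse temperature scale, 1/degC (> 0).
#' @param n,m shape exponents (> 0).
#' @return dimensionless Fcd vector.
#' @export
fcd_van_genuchten <- function(dt, f, g, n, m) {
  if (any(dt < 0)) stop("negative temperature range")
  stopifnot(f >= 0, f <= 1, g > 0, n > 0, m > 0)
  1 - (1 - f) / (1 + (g * dt)^n)^m
}

#' @rdname fcd_van_genuchten
#' @export
fcd_brutsaert <- function(dt, f, g, n) {
  if (any(dt < 0)) stop("negative temperature range")
  stopifnot(f >= 0, f <= 1, g > 0, n > 0)
  1 - (1 - f) / (1 + (g * dt)^n)
}

#' Seasonal bias-correction series
#'
#' Fs(i) = 1 + d cos(2 pi i/365) + e sin(2 pi i/365)
#'       \[+ f cos(4 pi i/365) + g sin(4 pi i/365)\]:
#' a Fourier series with its constant term fixed at 1, fitted in stage 2 of
#' the double-step calibration to the per-DOY mean observed/estimated ratio.
#'
#' @param coeffs numeric vector of length 0, 2 (order 1) or 4 (order 2).
#' @param doy day of year.
#' @return multiplicative correction, dimensionless.
#' @export
fs_series <- function(coeffs, doy) {
  k <- length(coeffs)
  if (!k %in% c(0L, 2L, 4L))
    stop("Fs coefficient vector must have length 0, 2 or 4")
  x <- 2 * pi * doy / 365
  fs <- rep_len(1, length(doy))
  if (k >= 2) fs <- fs + coeffs[1] * cos(x) + coeffs[2] * sin(x)
  if (k == 4) fs <- fs + coeffs[3] * cos(2 * x) + coeffs[4] * sin(2 * x)
  fs
}

# resolve per-day tau for a variant
resolve_tau <- function(spec, params, doy, metadata = NULL) {
  if (spec$tau_form == "from_metadata") {
    if (is.null(metadata) || is.na(metadata$dt_avg))
      stop("tau_form 'from_metadata' needs site metadata with dt_avg")
    rep_len(regional_tau(metadata$dt_avg), length(doy))
  } else {
    suppressWarnings(fourier_tau(params$tau_coeffs, doy))
  }
}

# per-day Fcd group label for a variant
fcd_group_of <- function(spec, doy, wet) {
  if (spec$seasonal_wetdry)
    paste(as.character(assign_season(doy)),
          ifelse(wet == 1, "wet", "dry"), sep = "_")
  else if (spec$wetdry_split) ifelse(wet == 1, "wet", "dry")
  else rep_len("all", length(doy))
}

# evaluate the Fcd curve of one group
eval_fcd <- function(spec, p, dt) {
  n <- if (!is.null(spec$n_fixed)) spec$n_fixed else p[["n"]]
  if (spec$fcd_form == "van_genuchten")
    fcd_van_genuchten(dt, p[["f"]], p[["g"]], n, p[["m"]])
  else
    fcd_brutsaert(dt, p[["f"]], p[["g"]], n)
}

#' Estimate daily radiation with an S-shape variant
#'
#' Evaluates Rs = Ra * tau * Fcd(dT) * (1 + q*R) * Fs(doy) day by day, with
#' the terms selected by the variant. Records lacking tmax, tmin or (when
#' the variant needs them) prcp are skipped and returned as `NA` with a
#' message.
#'
#' @param ws a [weather_series()].
#' @param spec a [variant_spec()] or notation string.
#' @param params a [parameter_set()] consistent with the variant.
#' @param metadata a [site_metadata()]; the latitude is always needed (for
#'   Ra) and `dt_avg` when the variant derives tau from metadata.
#' @param dt_mode diurnal-range convention passed to [delta_t()].
#' @param wet_threshold wet-day threshold, mm.
#' @return numeric vector of estimated Rs, MJ m-2 d-1.
#' @export
estimate_s_shape <- function(ws, spec, params, metadata,
                             dt_mode = c("smoothed", "raw"),
                             wet_threshold = 0.1) {
  if (is.character(spec)) spec <- parse_variant(spec)
  dt_mode <- match.arg(dt_mode)
  ra <- extraterrestrial_radiation(metadata$latitude, ws$doy)
  dt <- delta_t(ws, dt_mode)
  needs_wet <- spec$precip_factor || spec$wetdry_split
  wet <- classify_wet_dry(ifelse(is.na(ws$prcp) & !needs_wet, 0, ws$prcp),
                          wet_threshold)
  ok <- !is.na(ws$tmax) & !is.na(ws$tmin)
  if (needs_wet) ok <- ok & !is.na(wet)
  if (any(!ok))
    message(sum(!ok), " record(s) lack required weather fields; skipped")
  tau <- resolve_tau(spec, params, ws$doy, metadata)
  grp <- fcd_group_of(spec, ws$doy, wet)
  fcd <- rep(NA_real_, nrow(ws))
  for (g in unique(grp[ok])) {
    idx <- ok & grp == g
    pg <- params$fcd_groups[[g]]
    if (is.null(pg)) stop("no Fcd parameters for group '", g, "'")
    fcd[idx] <- eval_fcd(spec, pg, dt[idx])
  }
  rs <- ra * tau * fcd
  if (spec$precip_factor) rs <- rs * (1 + params$q * wet)
  if (spec$fs_order > 0) rs <- rs * fs_series(params$fs_coeffs, ws$doy)
  rs[!ok] <- NA_real_
  rs
}

#' Estimate daily radiation with a reference model
#'
#' The four comparison models:
#' \describe{
#' \item{DC (Donatelli-Campbell)}{Rs = Ra tau (1 - exp(-b 0.017
#'   exp(exp(-0.053 Ta)) exp(Tmin/c) dT^2)); temperature only.}
#' \item{DB (Donatelli-Bellocchi)}{adds a day-of-year modulation
#'   1 + b (sin(i c pi/180) + cos(i (1 - 1.9 frac(c) + 3.83 frac(c)^2)
#'   pi/180)) and divides dT^2 by the moving weekly range average.}
#' \item{HKS (Hunt-Kuchar-Swanton)}{Rs = a Ra dT^0.5 + b Tmax + c P +
#'   d P^2 + e; linear, not bounded above, can go negative.}
#' \item{LS (Liu-Scott)}{Rs = Ra a (1 - exp(-b dT^c)) (1 + d R(i-1) +
#'   e R(i) + f R(i+1)) + g, with occurrence flags of the neighbouring
#'   days; edge days reuse the nearest available flag.}
#' }
#' Estimates are returned as the formulas produce them: HKS/LS values may
#' be negative or exceed the physical ceiling (see
#' [apply_physical_bounds()]), and DC/DB tend to zero as dT does.
#'
#' @param ws a [weather_series()].
#' @param params a [reference_params()].
#' @param latitude site latitude, decimal degrees.
#' @param dt_mode diurnal-range convention for DC/DB/LS (HKS always uses
#'   the raw range, as its formulation states no smoothing).
#' @param wet_threshold wet-day threshold for the LS occurrence flags, mm.
#' @return numeric vector of estimated Rs, MJ m-2 d-1.
#' @export
estimate_reference <- function(ws, params, latitude,
                               dt_mode = c("smoothed", "raw"),
                               wet_threshold = 0.1) {
  stopifnot(inherits(params, "reference_params"))
  dt_mode <- match.arg(dt_mode)
  p <- params$params
  ra <- extraterrestrial_radiation(latitude, ws$doy)
  i <- ws$doy
  switch(params$model_id,
    DC = {
      dt <- delta_t(ws, dt_mode)
      ta <- (ws$tmax + ws$tmin) / 2
      ra * p["tau"] *
        (1 - exp(-p["b"] * 0.017 * exp(exp(-0.053 * ta)) *
                   exp(ws$tmin / p["c"]) * dt^2))
    },
    DB = {
      dt <- delta_t(ws, dt_mode)
      dtw <- pmax(weekly_delta_t(ws), 1e-6)
      fc <- p["c"] - floor(p["c"])
      season <- 1 + p["b"] *
        (sin(i * p["c"] * pi / 180) +
           cos(i * (1 - 1.9 * fc + 3.83 * fc^2) * pi / 180))
      ra * p["tau"] * season * (1 - exp(-p["d"] * dt^2 / dtw))
    },
    HKS = {
      dt <- delta_t(ws, "raw")
      p["a"] * ra * sqrt(dt) + p["b"] * ws$tmax +
        p["c"] * ws$prcp + p["d"] * ws$prcp^2 + p["e"]
    },
    LS = {
      dt <- delta_t(ws, dt_mode)
      r <- classify_wet_dry(ws$prcp, wet_threshold)
      n <- length(r)
      r_prev <- r[c(1L, seq_len(n - 1L))]
      r_next <- r[c(seq_len(n)[-1L], n)]
      ra * p["a"] * (1 - exp(-p["b"] * dt^p["c"])) *
        (1 + p["d"] * r_prev + p["e"] * r + p["f"] * r_next) + p["g"]
    },
    stop("unknown model_id"))
}

#' Clamp estimates to physical bounds
#'
#' Negative estimates are raised to zero and estimates above a configurable
#' fraction of the extraterrestrial radiation are lowered to that ceiling.
#' Off by default in the estimators so the pathologies of unbounded models
#' stay visible; the violation counts are the diagnostic of interest.
#'
#' @param rs_est estimated radiation vector.
#' @param ra matching extraterrestrial radiation vector.
#' @param cap_fraction ceiling as a fraction of Ra, in (0, 1\]; default 0.8,
#'   a conservative clear-sky transmissivity ceiling.
#' @return list with `rs` (clamped vector), `n_low` and `n_high`
#'   (violation counts).
#' @export
apply_physical_bounds <- function(rs_est, ra, cap_fraction = 0.8) {
  stopifnot(cap_fraction > 0, cap_fraction <= 1,
            length(rs_est) == length(ra))
  cap <- cap_fraction * ra
  n_low <- sum(rs_est < 0, na.rm = TRUE)
  n_high <- sum(rs_est > cap, na.rm = TRUE)
  list(rs = pmin(pmax(rs_est, 0), cap), n_low = n_low, n_high = n_high)
}
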