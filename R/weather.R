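#' Construct a daily weather series
#'
#' The universal input container of the package: one row per day, indexed by
#' calendar year and day of year (DOY). Temperatures are in degrees Celsius,
#' precipitation in mm, observed global radiation (optional) in MJ m-2 d-1.
#'
#' @param year integer vector of calendar years.
#' @param doy integer vector of days of year (1--366).
#' @param tmax,tmin daily maximum / minimum temperature, degrees C.
#' @param prcp daily precipitation, mm (>= 0). `NA` marks a missing record.
#' @param rs_obs observed daily global solar radiation, MJ m-2 d-1, or `NULL`
#'   when the site has no radiation record.
#' @param check if `TRUE` (default) validate all invariants; records with
#'   `tmax < tmin` raise an error.
#'
#' @return A `data.frame` of class `weather_series` with columns
#'   `year`, `doy`, `tmax`, `tmin`, `prcp`, `rs_obs`.
#'
#' @examples
#' ws <- weather_series(year = 2001, doy = 1:2, tmax = c(5, 6),
#'                      tmin = c(-2, 0), prcp = c(0, 1.2))
#' @export
weather_series <- function(year, doy, tmax, tmin, prcp,
                           rs_obs = NULL, check = TRUE) {
  n <- length(doy)
  year <- as.integer(rep_len(year, n))
  doy <- as.integer(doy)
  if (is.null(rs_obs)) rs_obs <- rep(NA_real_, n)
  ws <- data.frame(year = year, doy = doy,
                   tmax = as.numeric(tmax), tmin = as.numeric(tmin),
                   prcp = as.numeric(prcp), rs_obs = as.numeric(rs_obs))
  class(ws) <- c("weather_series", "data.frame")
  if (check) validate_weather_series(ws)
  ws
}

#' @rdname weather_series
#' @param ws a `weather_series`.
#' @export
validate_weather_series <- function(ws) {
  stopifnot(is.data.frame(ws), nrow(ws) > 0)
  req <- c("year", "doy", "tmax", "tmin", "prcp", "rs_obs")
  miss <- setdiff(req, names(ws))
  if (length(miss)) stop("weather series lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(ws$doy < 1 | ws$doy > 366)
  if (length(bad)) stop("doy out of 1..366 at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  ylen <- ifelse(is_leap_year(ws$year), 366L, 365L)
  bad <- which(ws$doy > ylen)
  if (length(bad)) stop("doy 366 in a non-leap year at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  key <- ws$year * 1000L + ws$doy
  if (anyDuplicated(key)) stop("duplicate (year, doy) records")
  if (is.unsorted(key, strictly = TRUE)) stop("records not in time order")
  ok <- stats::complete.cases(ws[, c("tmax", "tmin")])
  bad <- which(ok & ws$tmax < ws$tmin)
  if (length(bad)) stop("tmax < tmin at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(ws$prcp < 0, na.rm = TRUE)) stop("negative precipitation")
  if (any(ws$rs_obs < 0, na.rm = TRUE)) stop("negative observed radiation")
  invisible(ws)
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Site metadata record
#'
#' Geographical data and meteorological metadata of a station; enough to
#' drive the metadata-only regionalized model when no radiation record
#' exists. `dt_avg` is the long-term average diurnal temperature range,
#' the key covariate of the regionalization.
#'
#' @param latitude decimal degrees, in \[-90, 90\].
#' @param altitude station elevation, m.
#' @param t_avg average air temperature, degrees C.
#' @param dt_avg average diurnal temperature range, degrees C (> 0).
#' @param p_annual average annual precipitation sum, mm.
#' @return list of class `site_metadata`.
#' @export
site_metadata <- function(latitude, altitude = NA_real_, t_avg = NA_real_,
                          dt_avg = NA_real_, p_annual = NA_real_) {
  if (latitude < -90 || latitude > 90) stop("latitude outside [-90, 90]")
  if (!is.na(dt_avg) && dt_avg <= 0) stop("dt_avg must be > 0")
  structure(list(latitude = latitude, altitude = altitude, t_avg = t_avg,
                 dt_avg = dt_avg, p_annual = p_annual),
            class = "site_metadata")
}

#' Diurnal temperature range
#'
#' The primary radiation proxy. `raw` is Tmax - Tmin of the same day;
#' `smoothed` is the Bristow-Campbell convention
#' Tmax_i - (Tmin_i + Tmin_(i+1))/2, which damps the range on days followed
#' by a warm-air advection night. The last day has no following Tmin and
#' falls back to the raw range. Smoothed values are floored at zero (they
#' can come out slightly negative when the next night is much warmer).
#'
#' @param ws a `weather_series`.
#' @param mode `"smoothed"` (default) or `"raw"`.
#' @return numeric vector of per-day ranges, degrees C.
#' @export
delta_t <- function(ws, mode = c("smoothed", "raw")) {
  mode <- match.arg(mode)
  dt <- ws$tmax - ws$tmin
  if (mode == "smoothed") {
    n <- nrow(ws)
    if (n > 1) {
      nxt <- c(ws$tmin[-1], ws$tmin[n])
      dt <- ws$tmax - (ws$tmin + nxt) / 2
    }
    dt <- pmax(dt, 0)
  }
  dt
}

#' Moving weekly average of the diurnal temperature range
#'
#' Centered 7-day moving average of the raw range, as used by the
#' Donatelli-Bellocchi model denominator. Near the series edges the window
#' shrinks symmetrically so the output has the same length as the input.
#'
#' @inheritParams delta_t
#' @return numeric vector, same length as the series.
#' @export
weekly_delta_t <- function(ws) {
  dt <- ws$tmax - ws$tmin
  n <- length(dt)
  half <- pmin(3L, seq_len(n) - 1L, n - seq_len(n))
  vapply(seq_len(n), function(i) {
    w <- (i - half[i]):(i + half[i])
    mean(dt[w])
  }, numeric(1))
}

#' Precipitation occurrence flags
#'
#' @param prcp precipitation vector, mm.
#' @param threshold wet-day threshold, mm; a day is wet when
#'   `prcp >= threshold`. Default 0.1 mm.
#' @return integer vector of 0 (dry) / 1 (wet); `NA` prcp stays `NA`.
#' @export
classify_wet_dry <- function(prcp, threshold = 0.1) {
  if (any(prcp < 0, na.rm = TRUE)) stop("negative precipitation")
  as.integer(prcp >= threshold)
}

#' Meteorological season of a day of year
#'
#' Seasons follow meteorological months: DJF (Dec-Feb), MAM (Mar-May),
#' JJA (Jun-Aug), SON (Sep-Nov), assigned from the DOY of a 365/366-day
#' calendar.
#'
#' @param doy day of year.
#' @param year calendar year (leap handling); default a non-leap year.
#' @return factor with levels DJF, MAM, JJA, SON.
#' @export
assign_season <- function(doy, year = 2001L) {
  d <- as.Date(paste0(rep_len(year, length(doy)), "-01-01")) + (doy - 1)
  m <- as.integer(format(d, "%m"))
  s <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
         "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
  factor(s, levels = c("DJF", "MAM", "JJA", "SON"))
}
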