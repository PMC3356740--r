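#' Weather file dialect
#'
#' The canonical weather CSV: explicit header, year + DOY indexing (no
#' ambient date parsing), one missing-value sentinel that is never a legal
#' physical value.
#'
#' @param columns named character vector mapping the internal names
#'   `year`, `doy`, `tmax`, `tmin`, `prcp`, `srad` to file column names.
#' @param sentinel missing-value sentinel (default -99).
#' @param delimiter field delimiter.
#' @return list of class `weather_dialect`.
#' @export
weather_dialect <- function(columns = c(year = "year", doy = "doy",
                                        tmax = "tmax", tmin = "tmin",
                                        prcp = "prcp", srad = "srad"),
                            sentinel = -99, delimiter = ",") {
  need <- c("year", "doy", "tmax", "tmin", "prcp", "srad")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("dialect lacks columns: ",
                         paste(miss, collapse = ", "))
  structure(list(columns = columns, sentinel = sentinel,
                 delimiter = delimiter),
            class = "weather_dialect")
}

#' Read / write the weather CSV
#'
#' `read_weather` checks all series invariants and reports violations with
#' line numbers (header = line 1). Sentinel values become missing; records
#' with `tmax < tmin` are excluded with a warning by default or raise an
#' error with `tmax_lt_tmin = "error"`.
#'
#' @param path file path.
#' @param dialect a [weather_dialect()].
#' @param tmax_lt_tmin `"warn"` (exclude such records) or `"error"`.
#' @return `read_weather`: a [weather_series()]; `write_weather`: `path`,
#'   invisibly.
#' @export
read_weather <- function(path, dialect = weather_dialect(),
                         tmax_lt_tmin = c("warn", "error")) {
  tmax_lt_tmin <- match.arg(tmax_lt_tmin)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                          stringsAsFactors = FALSE)
  cols <- dialect$columns
  miss <- setdiff(unname(cols), names(df))
  if (length(miss)) stop("file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  pick <- function(k) {
    v <- as.numeric(df[[cols[[k]]]])
    v[!is.na(v) & v == dialect$sentinel] <- NA_real_
    v
  }
  year <- pick("year"); doy <- pick("doy")
  line <- seq_len(nrow(df)) + 1L
  if (anyNA(year) || anyNA(doy))
    stop("missing year/doy at line(s): ",
         paste(utils::head(line[is.na(year) | is.na(doy)], 5),
               collapse = ", "))
  key <- year * 1000 + doy
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate (year, doy) at line ", line[dup[1]])
  tmax <- pick("tmax"); tmin <- pick("tmin")
  bad <- which(!is.na(tmax) & !is.na(tmin) & tmax < tmin)
  if (length(bad)) {
    msg <- paste0("tmax < tmin at line(s): ",
                  paste(utils::head(line[bad], 5), collapse = ", "))
    if (tmax_lt_tmin == "error") stop(msg)
    warning(msg, "; record(s) excluded")
    tmax[bad] <- NA_real_; tmin[bad] <- NA_real_
  }
  weather_series(year = year, doy = doy, tmax = tmax, tmin = tmin,
                 prcp = pick("prcp"), rs_obs = pick("srad"))
}

#' @rdname read_weather
#' @param ws a [weather_series()].
#' @param digits decimal digits written (default 9: lossless for daily
#'   weather magnitudes).
#' @export
write_weather <- function(ws, path, dialect = weather_dialect(),
                          digits = 9) {
  cols <- dialect$columns
  fmt <- function(v) {
    out <- as.character(round(v, digits))
    out[is.na(v)] <- as.character(dialect$sentinel)
    out
  }
  df <- data.frame(ws$year, ws$doy, fmt(ws$tmax), fmt(ws$tmin),
                   fmt(ws$prcp), fmt(ws$rs_obs))
  names(df) <- unname(cols[c("year", "doy", "tmax", "tmin", "prcp", "srad")])
  utils::write.table(df, path, sep = dialect$delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an estimated-radiation CSV
#'
#' Carries the estimate together with the extraterrestrial radiation so
#' downstream clamping and audits are self-contained.
#'
#' @param ws the source [weather_series()].
#' @param rs_est estimated radiation vector aligned with `ws`.
#' @param ra extraterrestrial radiation vector aligned with `ws`.
#' @param path file path.
#' @return the written data.frame (`write_`), or a data.frame with columns
#'   `year`, `doy`, `rs_est`, `ra` (`read_`).
#' @export
write_estimates <- function(ws, rs_est, ra, path) {
  df <- data.frame(year = ws$year, doy = ws$doy,
                   rs_est = round(rs_est, 9), ra = round(ra, 9))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "doy", "rs_est")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("estimate file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}
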