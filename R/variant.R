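#' Specify a member of the S-shape model family
#'
#' The family is Rs = Ra * tau * Fcd * (1 + q*R)^[precip] * Fs^[order>0].
#' A variant fixes the functional form of each term:
#' the clear-sky transmissivity `tau` (2nd- or 1st-order Fourier series of
#' DOY, a constant, or estimated from site metadata), the fraction-of-clear-
#' day curve `Fcd` (4-parameter van Genuchten type or 3-parameter Brutsaert
#' type, optionally with the shape exponent n frozen), whether the
#' multiplicative wet-day factor (1 + q*R) is present, the order of the
#' seasonal bias-correction Fourier series `Fs`, and how the Fcd curve is
#' grouped (single fit, separate wet/dry fits, or the original
#' season-by-wet/dry scheme).
#'
#' @param tau_form one of `"fourier2"`, `"fourier1"`, `"constant"`,
#'   `"from_metadata"`.
#' @param fcd_form `"van_genuchten"` (f, g, n, m) or `"brutsaert"` (f, g, n).
#' @param n_fixed optional value at which the exponent n is frozen
#'   (e.g. 2.285); `NULL` fits n.
#' @param precip_factor include the (1 + q*R) precipitation-occurrence term?
#' @param fs_order 0 (no seasonal correction), 1 or 2 (Fourier order of Fs).
#' @param wetdry_split parameterize Fcd separately for wet and dry days?
#' @param seasonal_wetdry original scheme: Fcd per (season x wet/dry) group.
#'   Only valid with `precip_factor = FALSE` and `fs_order = 0`.
#' @param frozen character vector of parameter names held constant during
#'   calibration (e.g. `c("f", "g")`).
#' @return list of class `variant_spec`.
#' @seealso [parse_variant()] for the compact notation.
#' @export
variant_spec <- function(tau_form = c("fourier2", "fourier1", "constant",
                                      "from_metadata"),
                         fcd_form = c("brutsaert", "van_genuchten"),
                         n_fixed = NULL,
                         precip_factor = FALSE,
                         fs_order = 0L,
                         wetdry_split = FALSE,
                         seasonal_wetdry = FALSE,
                         frozen = character()) {
  tau_form <- match.arg(tau_form)
  fcd_form <- match.arg(fcd_form)
  fs_order <- as.integer(fs_order)
  stopifnot(fs_order %in% 0:2)
  if (!is.null(n_fixed)) stopifnot(is.numeric(n_fixed), n_fixed > 0)
  if (seasonal_wetdry && (precip_factor || fs_order != 0))
    stop("the seasonal wet/dry scheme excludes the precipitation factor ",
         "and the Fs correction")
  if (seasonal_wetdry) wetdry_split <- TRUE
  structure(list(tau_form = tau_form, fcd_form = fcd_form,
                 n_fixed = n_fixed, precip_factor = precip_factor,
                 fs_order = fs_order, wetdry_split = wetdry_split,
                 seasonal_wetdry = seasonal_wetdry,
                 frozen = as.character(frozen)),
            class = "variant_spec")
}

# canonical Table-style notations and their structure
.variant_table <- list(
  "5-44-4S" = list("fourier2", "van_genuchten", NULL, FALSE, 0L, TRUE, TRUE),
  "5-44-4"  = list("fourier2", "van_genuchten", NULL, FALSE, 2L, TRUE, FALSE),
  "3-44-4"  = list("fourier1", "van_genuchten", NULL, FALSE, 2L, TRUE, FALSE),
  "1-44-4"  = list("constant", "van_genuchten", NULL, FALSE, 2L, TRUE, FALSE),
  "1-33-4"  = list("constant", "brutsaert",     NULL, FALSE, 2L, TRUE, FALSE),
  "1-33-2"  = list("constant", "brutsaert",     NULL, FALSE, 1L, TRUE, FALSE),
  "0-33-4"  = list("from_metadata", "brutsaert", NULL, FALSE, 2L, TRUE, FALSE),
  "0-3-1-4" = list("from_metadata", "brutsaert", NULL, TRUE, 2L, FALSE, FALSE),
  "0-2-1-4" = list("from_metadata", "brutsaert", 2.285, TRUE, 2L, FALSE, FALSE)
)

#' Parse the compact variant notation
#'
#' Notation tokens are `tau`-form, `Fcd`-form (doubled digit = separate
#' wet/dry parameterization), optional precipitation term, and `Fs` order:
#' e.g. `"5-44-4S"` (original seasonal scheme), `"5-44-4"`, `"1-33-2"`,
#' `"0-3-1-4"`, `"0-2-1-4"` (the 7-parameter variant with n frozen at
#' 2.285). Compositional strings such as `"1-2-1-4"` (constant tau, frozen-n
#' Brutsaert curve, precipitation factor, 2nd-order Fs) are accepted too.
#' A leading `"S"` marker and a trailing `"*"` are tolerated.
#'
#' @param notation notation string.
#' @return a [variant_spec()].
#' @export
parse_variant <- function(notation) {
  stopifnot(is.character(notation), length(notation) == 1)
  raw <- notation
  s <- gsub("\\*$", "", trimws(notation))
  s <- sub("^S\\^?", "", s)
  if (s %in% names(.variant_table)) {
    a <- .variant_table[[s]]
    spec <- variant_spec(a[[1]], a[[2]], a[[3]], a[[4]], a[[5]], a[[6]], a[[7]])
    spec$notation <- s
    return(spec)
  }
  tok <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (!(length(tok) %in% 3:4))
    stop("unknown variant notation '", raw, "'; valid forms: ",
         paste(names(.variant_table), collapse = ", "),
         " or compositional tau-fcd[-1]-fs strings")
  tau <- switch(tok[1], "5" = "fourier2", "3" = "fourier1",
                "1" = "constant", "0" = "from_metadata",
                stop("unknown tau token '", tok[1], "' in '", raw, "'"))
  split <- nchar(tok[2]) == 2
  fdig <- substr(tok[2], 1, 1)
  if (split && substr(tok[2], 2, 2) != fdig)
    stop("malformed Fcd token '", tok[2], "' in '", raw, "'")
  fcd <- switch(fdig, "4" = "van_genuchten", "3" = "brutsaert",
                "2" = "brutsaert",
                stop("unknown Fcd token '", tok[2], "' in '", raw, "'"))
  n_fixed <- if (fdig == "2") 2.285 else NULL
  precip <- length(tok) == 4
  if (precip && tok[3] != "1")
    stop("third token of a 4-token notation must be '1' in '", raw, "'")
  last <- tok[length(tok)]
  seasonal <- grepl("S", last)
  last <- gsub("S", "", last)
  fs <- if (seasonal) 0L else switch(last, "4" = 2L, "2" = 1L, "0" = 0L,
              stop("unknown Fs token '", last, "' in '", raw, "'"))
  spec <- variant_spec(tau, fcd, n_fixed, precip, fs, split, seasonal)
  spec$notation <- variant_notation(spec)
  spec
}

#' Compact notation of a variant
#' @param spec a [variant_spec()].
#' @return notation string; inverse of [parse_variant()].
#' @export
variant_notation <- function(spec) {
  for (nm in names(.variant_table)) {
    a <- .variant_table[[nm]]
    same_n <- identical(is.null(a[[3]]), is.null(spec$n_fixed)) &&
      (is.null(a[[3]]) || isTRUE(all.equal(a[[3]], spec$n_fixed)))
    if (a[[1]] == spec$tau_form && a[[2]] == spec$fcd_form && same_n &&
        a[[4]] == spec$precip_factor && a[[5]] == spec$fs_order &&
        a[[6]] == spec$wetdry_split && a[[7]] == spec$seasonal_wetdry)
      return(nm)
  }
  t1 <- switch(spec$tau_form, fourier2 = "5", fourier1 = "3",
               constant = "1", from_metadata = "0")
  fdig <- if (!is.null(spec$n_fixed)) "2"
          else if (spec$fcd_form == "van_genuchten") "4" else "3"
  t2 <- if (spec$wetdry_split) paste0(fdig, fdig) else fdig
  t4 <- c("0", "2", "4")[spec$fs_order + 1L]
  if (spec$seasonal_wetdry) t4 <- paste0(t4, "S")
  if (spec$precip_factor) paste(t1, t2, "1", t4, sep = "-")
  else paste(t1, t2, t4, sep = "-")
}

#' Fcd parameter-group labels of a variant
#' @param spec a [variant_spec()].
#' @return character vector: `"all"`, `c("dry","wet")`, or the eight
#'   season-by-wet/dry labels.
#' @export
variant_groups <- function(spec) {
  if (spec$seasonal_wetdry)
    as.vector(outer(c("DJF", "MAM", "JJA", "SON"), c("dry", "wet"),
                    paste, sep = "_"))
  else if (spec$wetdry_split) c("dry", "wet")
  else "all"
}

#' Number of free parameters of a variant
#'
#' Counts the site-specific parameters determined by calibration: the tau
#' coefficients (5/3/1/0), the Fcd parameters per group (4 for the van
#' Genuchten curve, 3 for the Brutsaert curve, one fewer when n is frozen)
#' times the number of groups, the precipitation factor q, and the Fs
#' coefficients (0/2/4), minus any frozen parameters. The original seasonal
#' scheme has 5 + 8 x 4 = 37; the wet/dry + Fs scheme 17; the final
#' metadata-tau variant 7.
#'
#' @param spec a [variant_spec()] or notation string.
#' @return integer count.
#' @export
n_free_parameters <- function(spec) {
  if (is.character(spec)) spec <- parse_variant(spec)
  tau_n <- switch(spec$tau_form, fourier2 = 5L, fourier1 = 3L,
                  constant = 1L, from_metadata = 0L)
  per_group <- if (spec$fcd_form == "van_genuchten") 4L else 3L
  if (!is.null(spec$n_fixed)) per_group <- per_group - 1L
  ng <- length(variant_groups(spec))
  fs_n <- c(0L, 2L, 4L)[spec$fs_order + 1L]
  tau_n + per_group * ng + as.integer(spec$precip_factor) + fs_n -
    length(spec$frozen)
}
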