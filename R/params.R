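#' Site-specific parameter set of an S-shape variant
#'
#' Bundles every parameter a variant needs: the transmissivity coefficients
#' (five Fourier coefficients a..e, a single constant, or a value derived
#' from metadata), the Fcd curve parameters per calibration group
#' (f = value at zero temperature range, g = inverse temperature scale in
#' 1/degC, n = shape exponent, m = second shape exponent for the van
#' Genuchten form), the precipitation factor q, and the Fs seasonal
#' correction coefficients.
#'
#' @param tau_coeffs numeric vector: length 5 (`fourier2`), 3 (`fourier1`),
#'   1 (`constant` or resolved `from_metadata`).
#' @param fcd_groups named list, one numeric vector `c(f=, g=, n=, m=)`
#'   (m optional) per group label of the variant.
#' @param q precipitation factor (dimensionless), or `NA` when unused.
#' @param fs_coeffs Fs coefficients: length 0, 2 (`d`, `e`) or 4
#'   (`d`, `e`, `f`, `g`).
#' @param check validate invariants (0 <= f <= 1, g > 0, n > 0, m > 0).
#' @return list of class `parameter_set`.
#' @export
parameter_set <- function(tau_coeffs, fcd_groups, q = NA_real_,
                          fs_coeffs = numeric(), check = TRUE) {
  if (!is.list(fcd_groups) || is.null(names(fcd_groups)))
    stop("fcd_groups must be a named list of parameter vectors")
  fs_coeffs <- as.numeric(fs_coeffs)
  if (length(fs_coeffs))
    names(fs_coeffs) <- c("d", "e", "f", "g")[seq_along(fs_coeffs)]
  ps <- structure(list(tau_coeffs = as.numeric(tau_coeffs),
                       fcd_groups = lapply(fcd_groups, unlist),
                       q = as.numeric(q), fs_coeffs = fs_coeffs),
                  class = "parameter_set")
  if (check) {
    for (gname in names(ps$fcd_groups)) {
      p <- ps$fcd_groups[[gname]]
      if (!all(c("f", "g", "n") %in% names(p)))
        stop("Fcd group '", gname, "' must name f, g, n")
      if (p["f"] < 0 || p["f"] > 1) stop("f outside [0, 1] in '", gname, "'")
      if (p["g"] <= 0) stop("g must be > 0 in '", gname, "'")
      if (p["n"] <= 0) stop("n must be > 0 in '", gname, "'")
      if ("m" %in% names(p) && p["m"] <= 0)
        stop("m must be > 0 in '", gname, "'")
    }
    if (!length(fs_coeffs) %in% c(0L, 2L, 4L))
      stop("fs_coeffs must have length 0, 2 or 4")
  }
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("S-shape parameter set\n")
  cat("  tau coefficients:", paste(signif(x$tau_coeffs, 5), collapse = ", "),
      "\n")
  for (g in names(x$fcd_groups))
    cat("  Fcd[", g, "]: ",
        paste(names(x$fcd_groups[[g]]), signif(x$fcd_groups[[g]], 5),
              sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.na(x$q)) cat("  q:", signif(x$q, 5), "\n")
  if (length(x$fs_coeffs))
    cat("  Fs: ", paste(names(x$fs_coeffs), signif(x$fs_coeffs, 5),
                        sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write / read a parameter file
#'
#' Parameters travel as schema-versioned JSON carrying the variant notation,
#' the parameter values, provenance (`"calibrated"` or `"regional"`) and
#' optional site metadata and fit diagnostics, so an `estimate` run is fully
#' determined by the weather file and the parameter file.
#'
#' @param params a [parameter_set()].
#' @param spec the matching [variant_spec()] (or notation string).
#' @param path file path.
#' @param provenance `"calibrated"` or `"regional"`.
#' @param metadata optional [site_metadata()] stored alongside.
#' @param diagnostics optional list (iterations, convergence, seed, indices).
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   list with elements `spec`, `params`, `provenance`, `metadata`,
#'   `diagnostics`.
#' @export
write_params <- function(params, spec, path, provenance = "calibrated",
                         metadata = NULL, diagnostics = NULL) {
  if (is.character(spec)) spec <- parse_variant(spec)
  doc <- list(
    schema_version = 1L,
    notation = variant_notation(spec),
    n_fixed = spec$n_fixed,
    frozen = spec$frozen,
    provenance = provenance,
    metadata = if (!is.null(metadata))
      Filter(function(x) !is.na(x), unclass(metadata)),
    params = list(tau_coeffs = params$tau_coeffs,
                  fcd_groups = lapply(params$fcd_groups, as.list),
                  q = params$q,
                  fs_coeffs = as.list(params$fs_coeffs)),
    diagnostics = diagnostics)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported parameter file schema in ", path)
  spec <- parse_variant(doc$notation)
  if (length(doc$frozen)) spec$frozen <- unlist(doc$frozen)
  fcd <- lapply(doc$params$fcd_groups, function(g) unlist(g))
  ps <- parameter_set(unlist(doc$params$tau_coeffs), fcd,
                      q = if (is.null(doc$params$q)) NA_real_
                          else doc$params$q,
                      fs_coeffs = unlist(doc$params$fs_coeffs))
  md <- NULL
  if (!is.null(doc$metadata)) {
    m <- doc$metadata
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    md <- site_metadata(num(m$latitude), num(m$altitude), num(m$t_avg),
                        num(m$dt_avg), num(m$p_annual))
  }
  list(spec = spec, params = ps, provenance = doc$provenance,
       metadata = md, diagnostics = doc$diagnostics)
}

#' Reference-model parameter record
#'
#' @param model_id one of `"DC"`, `"DB"`, `"HKS"`, `"LS"`.
#' @param ... named parameters: DC needs tau, b, c; DB tau, b, c, d;
#'   HKS a..e; LS a..g. The DB seasonality parameter c must lie in
#'   (0, 0.5\] or (1, 1.5\]; DC/DB tau must lie in (0, 1).
#' @return list of class `reference_params`.
#' @export
reference_params <- function(model_id = c("DC", "DB", "HKS", "LS"), ...) {
  model_id <- match.arg(model_id)
  p <- c(...)
  need <- switch(model_id,
                 DC = c("tau", "b", "c"),
                 DB = c("tau", "b", "c", "d"),
                 HKS = c("a", "b", "c", "d", "e"),
                 LS = c("a", "b", "c", "d", "e", "f", "g"))
  miss <- setdiff(need, names(p))
  if (length(miss)) stop(model_id, " needs parameters: ",
                         paste(miss, collapse = ", "))
  p <- p[need]
  if (model_id %in% c("DC", "DB") && (p["tau"] <= 0 || p["tau"] >= 1))
    stop("tau must lie in (0, 1)")
  if (model_id == "DB") {
    cc <- p["c"]
    if (!((cc > 0 && cc <= 0.5) || (cc > 1 && cc <= 1.5)))
      stop("DB parameter c must lie in (0, 0.5] or (1, 1.5]")
  }
  structure(list(model_id = model_id, params = p),
            class = "reference_params")
}
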