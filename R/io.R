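titration_schema <- c("construct", "label", "replicate", "conc_nM",
                      "anisotropy")

#' Read titration curves from CSV
#'
#' Expects the titration schema: columns `construct`, `label`,
#' `replicate`, `conc_nM`, `anisotropy`, optional `d_total`. Schema
#' violations are reported with the offending column or row.
#'
#' @param path CSV file.
#' @return Tibble of titration rows.
#' @export
read_titrations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(titration_schema, names(df))
  if (base::length(missing)) {
    abort(paste0("titration CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "kb_schema_error")
  }
  if (!nrow(df)) abort("titration CSV has no data rows.",
                       class = "kb_schema_error")
  bad <- which(!is.finite(df$conc_nM) | df$conc_nM < 0 |
                 !is.finite(df$anisotropy))
  if (base::length(bad)) {
    abort(sprintf("invalid titration values at data row %d.", bad[1]),
          class = "kb_schema_error")
  }
  df
}

#' Write titration curves to CSV
#'
#' @param curves Titration tibble.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_titrations <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' Write a construct definition to a key-value config file
#'
#' Constructs round-trip through a small YAML document recording name,
#' length, footprint, site intervals and dissociation constants.
#'
#' @param construct A [dna_construct()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_construct <- function(construct, path) {
  stopifnot(inherits(construct, "dna_construct"))
  obj <- list(
    name = construct$name,
    length = construct$length,
    footprint = construct$footprint,
    specific_sites = lapply(construct$specific_sites, as.integer),
    kd_specific = construct$kd_specific,
    kd_nonspecific = if (is.finite(construct$kd_nonspecific))
      construct$kd_nonspecific else "Inf"
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a construct definition from a key-value config file
#'
#' @param path File written by [write_construct()].
#' @return A [dna_construct()].
#' @export
read_construct <- function(path) {
  obj <- yaml::read_yaml(path)
  req <- c("name", "length")
  missing <- setdiff(req, names(obj))
  if (base::length(missing)) {
    abort(paste0("construct config is missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "kb_schema_error")
  }
  kd_ns <- obj$kd_nonspecific %||% Inf
  if (identical(kd_ns, "Inf")) kd_ns <- Inf
  dna_construct(
    name = obj$name, length = obj$length,
    specific_sites = lapply(obj$specific_sites %||% list(), unlist),
    footprint = obj$footprint %||% 10L,
    kd_specific = unlist(obj$kd_specific %||% 1),
    kd_nonspecific = kd_ns
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
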