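# Config handling shared by the run_* entry points: a config is a named
# list or the path of a YAML file; required fields raise a usage error
# naming the field.
load_config <- function(config) {
  if (is.character(config) && base::length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.",
                              class = "kb_usage_error")
  config
}

require_fields <- function(config, fields) {
  missing <- fields[!fields %in% names(config)]
  if (base::length(missing)) {
    abort(paste0("config is missing required field(s): ",
                 paste(missing, collapse = ", ")),
          class = "kb_usage_error")
  }
}

write_manifest <- function(out_dir, kind, config, outputs, seed = NULL) {
  manifest <- list(
    kind = kind,
    package = "kappabind",
    version = as.character(utils::packageVersion("kappabind")),
    seed = seed,
    config = config,
    outputs = outputs
  )
  path <- file.path(out_dir, paste0(kind, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run a reproducible titration simulation from a config
#'
#' Config fields: `truth` (list with `kd1`, optional `kd2`, `omega`,
#' `amplitude`, `baseline`), `label`, `d_total`, optional `model`,
#' `conc_series` (list with `n`, `from`, `to`) and `noise` (`sigma`,
#' `seed`, `n_replicates`). Writes `titrations.csv` and a JSON manifest
#' recording the seed, package version and full config, sufficient to
#' reproduce the output byte for byte.
#'
#' @param config Named list or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Tibble of simulated curves, invisibly; files on disk.
#' @export
run_simulate <- function(config, out_dir = ".") {
  config <- load_config(config)
  require_fields(config, c("truth", "label", "d_total"))
  require_fields(config$truth, "kd1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- config$truth
  truth <- binding_params(
    kd1 = tr$kd1, kd2 = tr$kd2 %||% tr$kd1, omega = tr$omega %||% 1,
    amplitude = tr$amplitude %||% 0.1, baseline = tr$baseline %||% 0
  )
  cs <- config$conc_series
  conc <- if (is.null(cs)) default_conc_series() else
    default_conc_series(n = cs$n %||% 12, from = cs$from %||% 0.1,
                        to = cs$to %||% 2000, zero = cs$zero %||% TRUE)
  nz <- config$noise
  noise <- if (is.null(nz)) noise_model() else
    noise_model(sigma = nz$sigma %||% 0.003, seed = nz$seed %||% 1,
                n_replicates = nz$n_replicates %||% 3)
  curves <- generate_titration(
    truth, model = config$model, label = config$label,
    d_total = config$d_total, conc_series = conc, noise = noise,
    construct_name = config$construct %||% "synthetic"
  )
  csv <- file.path(out_dir, "titrations.csv")
  write_titrations(curves, csv)
  write_manifest(out_dir, "simulate", config, list(titrations = csv),
                 seed = noise$seed)
  invisible(curves)
}

#' Fit titration curves from a config
#'
#' Config fields: `input` (titration CSV path), `model` (one of
#' `"single_quadratic"`, `"single_hyperbolic"`, `"equal_kd"`,
#' `"distinct_kd"`, `"cooperative"`). Single-site models are fit per
#' replicate; two-site models are fit globally over each replicate's
#' forward/reverse pair. Per-replicate estimates, their mean +/- SEM
#' aggregate and a JSON fit report are written to `out_dir`.
#'
#' @param config Named list or YAML path.
#' @param out_dir Output directory.
#' @return A list with `per_replicate` and `aggregate` tibbles,
#'   invisibly; files on disk.
#' @export
run_fit <- function(config, out_dir = ".") {
  config <- load_config(config)
  require_fields(config, c("input", "model"))
  model <- config$model
  known <- c("single_quadratic", "single_hyperbolic", "equal_kd",
             "distinct_kd", "cooperative")
  if (!model %in% known) {
    abort(paste0("unknown model `", model, "`; expected one of: ",
                 paste(known, collapse = ", ")),
          class = "kb_usage_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- read_titrations(config$input)
  reps <- sort(unique(curves$replicate))
  fits <- lapply(reps, function(r) {
    cr <- curves[curves$replicate == r, ]
    if (startsWith(model, "single_")) {
      fit_single_site(cr, isotherm = sub("single_", "", model),
                      n_starts = config$n_starts %||% 5)
    } else {
      fit_global_two_site(cr, model = model,
                          n_starts = config$n_starts %||% 5)
    }
  })
  per_rep <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    dplyr::mutate(tidy(fits[[i]]), replicate = reps[i],
                  converged = fits[[i]]$converged)
  }))
  agg <- aggregate_replicates(per_rep)
  per_csv <- file.path(out_dir, "fit_per_replicate.csv")
  agg_csv <- file.path(out_dir, "fit_aggregate.csv")
  readr::write_csv(per_rep, per_csv)
  readr::write_csv(agg, agg_csv)
  report <- list(
    model = model,
    n_replicates = base::length(reps),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aggregate = agg
  )
  json <- file.path(out_dir, "fit_report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_manifest(out_dir, "fit", config,
                 list(per_replicate = per_csv, aggregate = agg_csv,
                      report = json))
  invisible(list(per_replicate = per_rep, aggregate = agg, fits = fits))
}

#' Predict EMSA band fractions from a config
#'
#' Config fields: `construct` (a construct config path, a name from
#' [kb_constructs()], or an inline list), optional `kd_specific`,
#' `kd_nonspecific`, `p_series`, `d_total`. Writes a CSV of predicted
#' fractions (columns `construct`, `p_total`, `n`, `fraction`).
#'
#' @param config Named list or YAML path.
#' @param out_dir Output directory.
#' @return The prediction tibble, invisibly; files on disk.
#' @export
run_emsa_predict <- function(config, out_dir = ".") {
  config <- load_config(config)
  require_fields(config, "construct")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cc <- config$construct
  construct <- if (inherits(cc, "dna_construct")) {
    cc
  } else if (is.character(cc) && file.exists(cc)) {
    read_construct(cc)
  } else if (is.character(cc)) {
    all <- kb_constructs(
      kd_specific = config$kd_specific %||% 1.7,
      kd_nonspecific = config$kd_nonspecific %||% Inf
    )
    if (!cc %in% names(all)) {
      abort(paste0("unknown construct `", cc, "`; expected one of: ",
                   paste(names(all), collapse = ", ")),
            class = "kb_usage_error")
    }
    all[[cc]]
  } else if (is.list(cc)) {
    dna_construct(cc$name %||% "config construct", cc$length,
                  lapply(cc$specific_sites %||% list(), unlist),
                  cc$footprint %||% 10,
                  unlist(cc$kd_specific %||% 1),
                  cc$kd_nonspecific %||% Inf)
  } else {
    abort("`construct` field not understood.", class = "kb_usage_error")
  }
  pred <- generate_emsa(
    construct,
    p_series = unlist(config$p_series %||%
                        c(0, 62.5, 125, 250, 500, 1000, 2000)),
    d_total = config$d_total %||% 250
  )
  csv <- file.path(out_dir, "emsa_predicted.csv")
  readr::write_csv(pred, csv)
  write_manifest(out_dir, "emsa_predict", config, list(predicted = csv))
  invisible(pred)
}
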