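# theta for the site a labeled strand reports on: forward -> site 1,
# reverse -> site 2 (binary 3-bp proximity rule on tandem constructs
# with 3 bp flanks).
label_site_index <- function(label) {
  switch(label,
         forward = 1L, hairpin = 1L, reverse = 2L,
         abort(paste0("unknown label `", label, "`")))
}

#' Global two-site fit across forward- and reverse-labeled titrations
#'
#' Fits all supplied curves simultaneously to the depletion-aware two-site
#' equilibrium model, sharing the thermodynamic parameters across curves
#' while giving every curve its own amplitude and baseline (labeling
#' efficiency varies between DNA preparations). The forward-labeled curves
#' read site-1 occupancy and the reverse-labeled curves site-2 occupancy.
#' Candidate models:
#' \describe{
#'   \item{`equal_kd`}{one shared Kd for both sites, `omega = 1`.}
#'   \item{`distinct_kd`}{independent `kd1`, `kd2`, `omega = 1`. With
#'     `kd2 > kd1` the site-2 curves become sigmoidal at protein
#'     concentrations spanning the site concentration, reproducing the
#'     preferential filling of the tighter site.}
#'   \item{`cooperative`}{one shared Kd plus a free cooperativity factor
#'     `omega`.}
#' }
#'
#' @param curves Data frame with columns `label` (`"forward"` /
#'   `"reverse"`), `conc_nM`, `anisotropy`, optionally `replicate` and
#'   `d_total` (nM, default 5). At least one forward and one reverse
#'   curve are required.
#' @param model One of `"equal_kd"`, `"distinct_kd"`, `"cooperative"`.
#' @param n_starts Multi-start count over initial Kd values. Default 5.
#' @return A `kb_fit` with terms `kd1`, `kd2`, `omega` and per-curve
#'   `amplitude.<id>` / `baseline.<id>`.
#' @export
fit_global_two_site <- function(curves,
                                model = c("equal_kd", "distinct_kd",
                                          "cooperative"),
                                n_starts = 5) {
  model <- match.arg(model)
  stopifnot(is.data.frame(curves),
            all(c("label", "conc_nM", "anisotropy") %in% names(curves)))
  curves <- tibble::as_tibble(curves)
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  if (!"d_total" %in% names(curves)) curves$d_total <- 5
  if (!any(curves$label == "forward") || !any(curves$label == "reverse")) {
    abort("need at least one forward- and one reverse-labeled curve.",
          class = "kb_input_error")
  }
  curves$curve_id <- paste(curves$label, curves$replicate, sep = ".")
  ids <- unique(curves$curve_id)
  n_curve <- base::length(ids)
  site_idx <- vapply(curves$label, label_site_index, integer(1))

  n_thermo <- switch(model, equal_kd = 1L, distinct_kd = 2L, cooperative = 2L)
  # par layout: thermo block, then (amplitude, baseline) per curve
  unpack <- function(par) {
    kd1 <- exp(par[1])
    kd2 <- switch(model,
                  equal_kd = kd1,
                  distinct_kd = exp(par[2]),
                  cooperative = kd1)
    omega <- if (model == "cooperative") exp(par[2]) else 1
    amps <- par[n_thermo + 2 * seq_len(n_curve) - 1]
    bases <- par[n_thermo + 2 * seq_len(n_curve)]
    list(kd1 = kd1, kd2 = kd2, omega = omega,
         amps = setNames(amps, ids), bases = setNames(bases, ids))
  }
  x <- curves$conc_nM
  d <- curves$d_total
  y <- curves$anisotropy
  id_of_row <- match(curves$curve_id, ids)
  residual_fn <- function(par) {
    pp <- unpack(par)
    st <- two_site_species(x, d, binding_params(pp$kd1, pp$kd2, pp$omega))
    theta <- ifelse(site_idx == 1L, st$theta_site1, st$theta_site2)
    y - (pp$bases[id_of_row] + pp$amps[id_of_row] * theta)
  }

  per_curve_init <- unlist(lapply(ids, function(id) {
    yy <- y[curves$curve_id == id]
    c(max(yy) - min(yy), min(yy))
  }))
  kd_starts <- default_kd_starts(x, n_starts)
  starts <- lapply(kd_starts, function(kd0) {
    thermo <- switch(model,
                     equal_kd = log(kd0),
                     distinct_kd = c(log(kd0), log(kd0 * 5)),
                     cooperative = c(log(kd0), 0))
    c(thermo, per_curve_init)
  })
  fit <- run_lm_multistart(residual_fn, starts)
  se <- lm_std_errors(fit)
  pp <- unpack(fit$par)

  thermo_terms <- switch(model,
                         equal_kd = "kd1",
                         distinct_kd = c("kd1", "kd2"),
                         cooperative = c("kd1", "omega"))
  thermo_est <- switch(model,
                       equal_kd = pp$kd1,
                       distinct_kd = c(pp$kd1, pp$kd2),
                       cooperative = c(pp$kd1, pp$omega))
  thermo_se <- thermo_est * se[seq_len(n_thermo)]  # delta method, log scale
  nuis <- tibble::tibble(
    term = as.vector(rbind(paste0("amplitude.", ids),
                           paste0("baseline.", ids))),
    estimate = fit$par[-seq_len(n_thermo)],
    std_error = se[-seq_len(n_thermo)]
  )
  params <- dplyr::bind_rows(
    tibble::tibble(term = thermo_terms, estimate = thermo_est,
                   std_error = thermo_se),
    nuis
  )
  amp_se <- se[n_thermo + 2 * seq_len(n_curve) - 1]
  amp_ok <- all(is.finite(amp_se)) &&
    all(pp$amps > 2 * amp_se)
  converged <- fit$info %in% 1:4 && amp_ok
  fitted <- y - fit$fvec
  new_kb_fit(params, paste0("two_site_", model), fit$deviance, converged,
             base::length(y), n_thermo + 2L * n_curve,
             curves, fitted,
             extra = list(two_site_model = model,
                          kd1 = pp$kd1, kd2 = pp$kd2, omega = pp$omega))
}
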