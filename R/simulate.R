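#' Default titration concentration series
#'
#' Twelve log-spaced protein concentrations plus a zero point, spanning
#' sub-Kd to saturating conditions for nanomolar binders.
#'
#' @param n Number of log-spaced points. Default 12.
#' @param from,to Range of the log-spaced part, nM. Defaults 0.1 and 2000.
#' @param zero Prepend a zero-protein point. Default TRUE.
#' @return Numeric vector of concentrations, nM.
#' @export
default_conc_series <- function(n = 12, from = 0.1, to = 2000, zero = TRUE) {
  stopifnot(from > 0, to > from, n >= 2)
  s <- exp(seq(log(from), log(to), length.out = n))
  if (zero) c(0, s) else s
}

#' Simulate replicate anisotropy titrations
#'
#' Generates titration curves from the equilibrium model evaluated at the
#' true parameters, plus i.i.d. Gaussian noise on the anisotropy scale.
#' Replicate `r` draws its noise under seed [replicate_seed()]`(seed, r)`,
#' so the whole data set is reproducible from the noise model alone.
#' The deterministic part is one of:
#' \describe{
#'   \item{`"quadratic"`}{single site with ligand depletion (specific
#'     hairpins at 5 nM labeled DNA).}
#'   \item{`"hyperbolic"`}{no-depletion Langmuir binding (weak nonspecific
#'     DNA).}
#'   \item{`"two_site"`}{the two-site depletion model read out through the
#'     labeled strand (`label` `"forward"` reports site 1, `"reverse"`
#'     site 2).}
#' }
#'
#' @param truth A [binding_params()] with the generating parameters.
#' @param model Signal model; default `"quadratic"`, or `"two_site"`
#'   automatically when `label` is `"forward"`/`"reverse"`.
#' @param label `"hairpin"` (default), `"forward"` or `"reverse"`.
#' @param d_total Labeled DNA concentration, nM. Default 5.
#' @param conc_series Protein concentrations, nM (>= 5 points).
#' @param noise A [noise_model()].
#' @param construct_name Identifier recorded in the output.
#' @return Tibble with columns `construct`, `label`, `replicate`,
#'   `conc_nM`, `anisotropy`, `d_total`.
#' @export
generate_titration <- function(truth,
                               model = NULL,
                               label = "hairpin",
                               d_total = 5,
                               conc_series = default_conc_series(),
                               noise = noise_model(),
                               construct_name = "synthetic") {
  stopifnot(inherits(truth, "binding_params"),
            inherits(noise, "noise_model"))
  if (base::length(conc_series) < 5) {
    abort("`conc_series` needs at least 5 points.")
  }
  if (is.null(model)) {
    model <- if (label %in% c("forward", "reverse")) "two_site" else
      "quadratic"
  }
  model <- match.arg(model, c("quadratic", "hyperbolic", "two_site"))
  theta <- switch(
    model,
    quadratic = single_site_complex(conc_series, d_total, truth$kd1) /
      d_total,
    hyperbolic = hyperbolic_fraction(conc_series, truth$kd1),
    two_site = {
      st <- two_site_species(conc_series, d_total, truth)
      if (label_site_index(label) == 1L) st$theta_site1 else st$theta_site2
    }
  )
  signal <- truth$baseline + truth$amplitude * theta
  dplyr::bind_rows(lapply(seq_len(noise$n_replicates), function(r) {
    eps <- if (noise$sigma > 0) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(replicate_seed(noise$seed, r))
      rnorm(base::length(signal), sd = noise$sigma)
    } else rep(0, base::length(signal))
    tibble::tibble(
      construct = construct_name, label = label, replicate = r,
      conc_nM = conc_series, anisotropy = signal + eps, d_total = d_total
    )
  }))
}

#' Simulate EMSA band fractions over a protein series
#'
#' Evaluates the lattice [species_distribution()] at each protein
#' concentration of a gel titration (default: the 0-2000 nM series at
#' 250 nM DNA) and optionally perturbs the band fractions with truncated
#' Gaussian noise, renormalizing each lane to sum to one.
#'
#' @param construct A [dna_construct()].
#' @param p_series Protein concentrations, nM.
#' @param d_total DNA concentration, nM. Default 250.
#' @param noise_sd_fraction SD of additive fractional noise. Default 0.
#' @param seed Seed for the noise draw. Default 1.
#' @return Tibble with columns `construct`, `p_total`, `d_total`, `n`,
#'   `fraction`.
#' @export
generate_emsa <- function(construct,
                          p_series = c(0, 62.5, 125, 250, 500, 1000, 2000),
                          d_total = 250, noise_sd_fraction = 0, seed = 1L) {
  dist <- species_distribution(construct, p_series, d_total)
  out <- dist |>
    dplyr::select("construct", "p_total", "d_total", "n",
                  fraction = "probability")
  if (noise_sd_fraction > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    out <- out |>
      dplyr::mutate(fraction = pmax(
        .data$fraction + rnorm(dplyr::n(), sd = noise_sd_fraction), 0)) |>
      dplyr::group_by(.data$p_total) |>
      dplyr::mutate(fraction = .data$fraction / sum(.data$fraction)) |>
      dplyr::ungroup()
  }
  out
}
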