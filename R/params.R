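#' Binding parameters for one- and two-site equilibrium models
#'
#' Bundles the thermodynamic and readout parameters of the dimer-DNA
#' binding models. Dissociation constants are in nM; `omega` is the
#' dimensionless cooperativity factor multiplying the statistical weight of
#' the doubly occupied state (`omega = 1`: independent sites, the
#' no-cooperativity case; `omega > 1`: positive cooperativity).
#' `amplitude` is the maximal anisotropy change at saturation of the
#' reported site(s) and `baseline` the anisotropy of free DNA, both in
#' dimensionless anisotropy units.
#'
#' @param kd1 Dissociation constant of site 1, nM (> 0).
#' @param kd2 Dissociation constant of site 2, nM (> 0). Defaults to `kd1`
#'   (the equal-affinity model). May be `Inf` to disable site 2.
#' @param omega Cooperativity factor (> 0). Default 1.
#' @param amplitude Maximum anisotropy change (>= 0).
#' @param baseline Anisotropy of unbound labeled DNA.
#' @return An object of class `binding_params`.
#' @examples
#' binding_params(kd1 = 1.7)
#' binding_params(kd1 = 1.7, kd2 = 10)
#' @export
binding_params <- function(kd1, kd2 = kd1, omega = 1, amplitude = 0.1,
                           baseline = 0) {
  stopifnot(is.numeric(kd1), length(kd1) == 1L,
            is.numeric(kd2), length(kd2) == 1L,
            is.numeric(omega), length(omega) == 1L)
  if (!is.finite(kd1) || kd1 <= 0) {
    abort("`kd1` must be a finite positive dissociation constant (nM).")
  }
  if (kd2 <= 0) abort("`kd2` must be positive (nM); use Inf for no site 2.")
  if (!is.finite(omega) || omega <= 0) abort("`omega` must be finite and > 0.")
  if (!is.finite(amplitude) || amplitude < 0) {
    abort("`amplitude` must be finite and >= 0.")
  }
  structure(
    list(kd1 = kd1, kd2 = kd2, omega = omega,
         amplitude = amplitude, baseline = baseline),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat("<binding_params>\n")
  cat(sprintf("  Kd site 1: %g nM\n", x$kd1))
  cat(sprintf("  Kd site 2: %g nM\n", x$kd2))
  cat(sprintf("  omega:     %g\n", x$omega))
  cat(sprintf("  amplitude: %g, baseline: %g\n", x$amplitude, x$baseline))
  invisible(x)
}

#' Fluorophore labeling configuration
#'
#' Describes where the fluorescein label sits on a DNA construct. The 5'
#' label of the forward strand maps to construct coordinate 1, the 5' label
#' of the reverse strand to the last bp of the construct; a hairpin label
#' also sits at coordinate 1. Anisotropy reports binding only at sites
#' whose nearest edge is within `proximity_cutoff` bp of the label
#' (the signal drops off sharply beyond ~3 bp).
#'
#' @param labeled_strand One of `"forward"`, `"reverse"`, `"hairpin"`.
#' @param fluorophore_position Optional explicit bp coordinate of the label
#'   in construct coordinates; derived from `labeled_strand` and the
#'   construct length when `NULL` (the default).
#' @param proximity_cutoff Maximum label-to-site-edge distance (bp) that
#'   still produces an anisotropy change. Default 3.
#' @return An object of class `label_config`.
#' @export
label_config <- function(labeled_strand = c("forward", "reverse", "hairpin"),
                         fluorophore_position = NULL,
                         proximity_cutoff = 3) {
  labeled_strand <- match.arg(labeled_strand)
  if (!is.numeric(proximity_cutoff) || length(proximity_cutoff) != 1L ||
      is.na(proximity_cutoff) || proximity_cutoff < 0) {
    abort("`proximity_cutoff` must be a single nonnegative number of bp.")
  }
  if (!is.null(fluorophore_position)) {
    stopifnot(is.numeric(fluorophore_position),
              length(fluorophore_position) == 1L,
              fluorophore_position >= 1)
  }
  structure(
    list(labeled_strand = labeled_strand,
         fluorophore_position = fluorophore_position,
         proximity_cutoff = proximity_cutoff),
    class = "label_config"
  )
}

#' Gaussian noise model for synthetic titrations
#'
#' @param sigma Anisotropy standard deviation per point. Default 0.003,
#'   chosen so that three-replicate SEMs match those typical of plate-reader
#'   anisotropy titrations.
#' @param seed Base integer seed; replicate `r` uses seed
#'   `seed * 100 + r` (see [replicate_seed()]).
#' @param n_replicates Number of independent replicates. Default 3.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.003, seed = 1L, n_replicates = 3L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(seed), length(seed) == 1L,
            is.numeric(n_replicates), n_replicates >= 1)
  structure(
    list(sigma = sigma, seed = as.integer(seed),
         n_replicates = as.integer(n_replicates)),
    class = "noise_model"
  )
}

#' Seed used for one synthetic replicate
#'
#' Replicate seeds are derived from the base seed by the fixed rule
#' `base_seed * 100 + replicate`, so distinct replicates draw independent
#' noise while the whole data set is reproducible from one integer.
#'
#' @param base_seed Integer base seed.
#' @param replicate Replicate index (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, replicate) {
  as.integer(base_seed) * 100L + as.integer(replicate)
}
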