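#' Steady-state anisotropy from polarized intensities
#'
#' Computes `r = (I_vv - G I_vh) / (I_vv + 2 G I_vh)` from the parallel
#' and perpendicular emission intensities and the instrument G-factor.
#' `printed_form = TRUE` switches the denominator to `I_vv - 2 G I_vh`,
#' a nonstandard variant retained for compatibility with legacy
#' spreadsheets; it diverges when `I_vv = 2 G I_vh` and is not recommended.
#'
#' @param i_parallel Parallel (V,V) intensity, counts (vectorized).
#' @param i_perpendicular Perpendicular (V,H) intensity, counts.
#' @param g_factor Instrument grating factor (> 0). Default 0.67.
#' @param printed_form Use the legacy minus-sign denominator. Default FALSE.
#' @return Anisotropy, in `(-0.5, 1]` for the standard form.
#' @examples
#' anisotropy_from_intensities(0.3, 0.2, 0.67) # ~0.292
#' @export
anisotropy_from_intensities <- function(i_parallel, i_perpendicular,
                                        g_factor = 0.67,
                                        printed_form = FALSE) {
  if (any(g_factor <= 0)) abort("`g_factor` must be > 0.")
  if (any(i_parallel < 0) || any(i_perpendicular < 0)) {
    abort("intensities must be nonnegative.")
  }
  if (any(i_parallel == 0 & i_perpendicular == 0)) {
    abort("total intensity is zero; anisotropy undefined.")
  }
  num <- i_parallel - g_factor * i_perpendicular
  den <- if (printed_form) {
    i_parallel - 2 * g_factor * i_perpendicular
  } else {
    i_parallel + 2 * g_factor * i_perpendicular
  }
  num / den
}

# bp distance from the label to the nearest edge of a site interval
# (0 when the label coordinate falls inside the interval).
label_site_distance <- function(position, site) {
  max(0, site[1] - position, position - site[2])
}

fluorophore_position <- function(construct, label) {
  if (!is.null(label$fluorophore_position)) {
    return(label$fluorophore_position)
  }
  switch(label$labeled_strand,
         forward = 1L,
         hairpin = 1L,
         reverse = construct$length)
}

#' Which sites a labeled construct reports on
#'
#' Binary proximity weights: a site contributes to the anisotropy change
#' (weight 1) when its nearest edge lies within `proximity_cutoff` bp of
#' the fluorophore, and not at all (weight 0) otherwise. With 3 bp flanks
#' this makes the forward-labeled strand report site 1 and the
#' reverse-labeled strand report site 2 of a tandem construct.
#'
#' @param construct A [dna_construct()].
#' @param label A [label_config()].
#' @return Numeric vector of 0/1 weights, one per specific site.
#' @export
site_weights <- function(construct, label) {
  stopifnot(inherits(construct, "dna_construct"),
            inherits(label, "label_config"))
  pos <- fluorophore_position(construct, label)
  if (pos < 1 || pos > construct$length) {
    abort("fluorophore position lies outside the construct.")
  }
  vapply(construct$specific_sites, function(s) {
    as.numeric(label_site_distance(pos, s) <= label$proximity_cutoff)
  }, numeric(1))
}

#' Predicted anisotropy from site occupancies
#'
#' Readout model `r = baseline + amplitude * sum(w_s theta_s) / sum(w_s)`:
#' the label reports the occupancy of its proximal site(s) only, scaled so
#' that saturation of the reported sites gives `baseline + amplitude`.
#' When no site carries weight the signal stays at baseline.
#'
#' @param theta Per-site occupancies in `[0, 1]` (matrix rows = states,
#'   columns = sites; or a vector for one state).
#' @param weights Per-site proximity weights (e.g. [site_weights()]).
#' @param params A [binding_params()] supplying amplitude and baseline.
#' @return Predicted anisotropy (one value per state).
#' @export
predicted_signal <- function(theta, weights, params) {
  stopifnot(inherits(params, "binding_params"))
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != base::length(weights)) {
    abort("`theta` and `weights` must cover the same sites.")
  }
  if (any(theta < -1e-12) || any(theta > 1 + 1e-12)) {
    abort("occupancies must lie in [0, 1].")
  }
  wsum <- sum(weights)
  frac <- if (wsum > 0) as.numeric(theta %*% weights) / wsum else
    rep(0, nrow(theta))
  params$baseline + params$amplitude * frac
}

#' Normalize a titration curve by its fitted amplitude
#'
#' Rescales observed anisotropies to `(y - baseline) / amplitude`, the
#' bound-fraction scale on which replicate experiments with different
#' labeling efficiencies can be averaged and plotted together.
#'
#' @param curve Data frame with an `anisotropy` column.
#' @param amplitude Fitted maximum anisotropy change (> 0).
#' @param baseline Fitted free-DNA anisotropy. Default 0.
#' @return The input as a tibble with an added `anisotropy_norm` column.
#' @export
normalize_curve <- function(curve, amplitude, baseline = 0) {
  stopifnot(is.data.frame(curve), "anisotropy" %in% names(curve))
  if (!is.numeric(amplitude) || amplitude <= 0) {
    abort("`amplitude` must be > 0.")
  }
  dplyr::mutate(tibble::as_tibble(curve),
                anisotropy_norm = (.data$anisotropy - baseline) / amplitude)
}

#' Undo [normalize_curve()]
#'
#' @param curve Data frame with `anisotropy_norm`.
#' @inheritParams normalize_curve
#' @return Tibble with `anisotropy` recomputed from the normalized values.
#' @export
denormalize_curve <- function(curve, amplitude, baseline = 0) {
  stopifnot(is.data.frame(curve), "anisotropy_norm" %in% names(curve))
  if (!is.numeric(amplitude) || amplitude <= 0) {
    abort("`amplitude` must be > 0.")
  }
  dplyr::mutate(tibble::as_tibble(curve),
                anisotropy = .data$anisotropy_norm * amplitude + baseline)
}
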