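#' Equilibrium complex concentration for a single binding site
#'
#' Solves the mass-balance quadratic for a bimolecular association
#' P + D <-> PD under ligand depletion and returns the complex
#' concentration. This is the physically valid (smaller) root of
#' `c^2 - (p + d + kd) c + p d = 0`, evaluated in the numerically stable
#' form `2 p d / (s + sqrt(s^2 - 4 p d))` with `s = p + d + kd`.
#'
#' @param p_total Total protein dimer concentration, nM (vectorized).
#' @param d_total Total DNA concentration, nM.
#' @param kd Dissociation constant, nM (> 0).
#' @return Complex concentration in nM, bounded by `min(p_total, d_total)`.
#' @examples
#' single_site_complex(10, 5, 5) # ~2.93 nM
#' @export
single_site_complex <- function(p_total, d_total, kd) {
  if (any(is.na(kd)) || any(kd <= 0)) abort("`kd` must be > 0.")
  if (any(p_total < 0) || any(d_total < 0)) {
    abort("concentrations must be nonnegative.")
  }
  s <- p_total + d_total + kd
  disc <- s^2 - 4 * p_total * d_total
  # disc >= kd^2 > 0 analytically; guard rounding
  disc[disc < 0] <- 0
  out <- 2 * p_total * d_total / (s + sqrt(disc))
  pmin(out, pmin(p_total, d_total))
}

#' Hyperbolic (no-depletion) bound fraction
#'
#' The Langmuir fraction `x / (x + kd)`, appropriate when the free ligand
#' concentration is well approximated by the total (weak binding relative
#' to the labeled-DNA concentration, e.g. nonspecific hairpin titrations).
#'
#' @param x Free (~total) protein concentration, nM (vectorized).
#' @param kd Dissociation constant, nM (> 0).
#' @return Bound fraction in `[0, 1)`.
#' @export
hyperbolic_fraction <- function(x, kd) {
  if (any(kd <= 0) || any(!is.finite(kd))) abort("`kd` must be finite and > 0.")
  if (any(x < 0)) abort("`x` must be nonnegative.")
  x / (x + kd)
}

# Free protein for the two-site model, one (p, d) pair.
#
# Conservation: P + d * (P/k1 + P/k2 + 2 w P^2/(k1 k2)) / Z(P) = p with
# Z(P) = 1 + P/k1 + P/k2 + w P^2/(k1 k2). Multiplying through by Z gives
# the cubic b P^3 + (a - b p + 2 d b) P^2 + (1 - a p + d a) P - p = 0 with
# a = 1/k1 + 1/k2, b = w/(k1 k2). The conservation function is strictly
# increasing in P, so exactly one root lies in [0, p]; polyroot locates it
# and a few Newton steps on the conservation function polish it to
# ~1e-12 relative.
two_site_free_protein_1 <- function(p, d, kd1, kd2, omega) {
  if (p == 0) return(0)
  a <- 1 / kd1 + if (is.finite(kd2)) 1 / kd2 else 0
  b <- if (is.finite(kd2)) omega / (kd1 * kd2) else 0
  if (d == 0 || a + b == 0) return(p)

  root <- NA_real_
  coefs <- c(-p, 1 - a * p + d * a, a - b * p + 2 * d * b, b)
  if (b == 0) coefs <- coefs[1:3]
  rts <- polyroot(coefs)
  real <- Re(rts)[abs(Im(rts)) <= 1e-8 * (abs(Re(rts)) + 1)]
  cand <- real[real >= -1e-9 * p & real <= p * (1 + 1e-9)]
  if (length(cand)) root <- min(max(min(cand), 0), p)

  conserv <- function(P) {
    z <- 1 + a * P + b * P^2
    nu <- (a * P + 2 * b * P^2) / z
    P + d * nu - p
  }
  if (is.na(root)) {
    root <- uniroot(conserv, c(0, p), tol = .Machine$double.eps^0.75 * max(1, p))$root
  }
  # Newton polish on the conservation function (monotone increasing)
  for (i in 1:4) {
    z <- 1 + a * root + b * root^2
    zp <- a + 2 * b * root
    nup <- ((a + 4 * b * root) * z - (a * root + 2 * b * root^2) * zp) / z^2
    f <- conserv(root)
    step <- f / (1 + d * nup)
    newr <- min(max(root - step, 0), p)
    if (abs(newr - root) <= 1e-15 * max(1, root)) { root <- newr; break }
    root <- newr
  }
  root
}

#' Equilibrium species for two discrete binding sites
#'
#' Solves the coupled equilibrium of a protein dimer P binding two discrete
#' sites on the same DNA molecule under ligand depletion. Occupancy species
#' are labeled by site pattern: `00` free DNA, `10` site 1 only, `01`
#' site 2 only, `11` both. Statistical weights relative to free DNA are
#' `P/kd1`, `P/kd2` and `omega * P^2/(kd1 kd2)`; the free protein
#' concentration is the unique root of total-protein conservation.
#'
#' @param p_total Total protein dimer, nM (vectorized).
#' @param d_total Total DNA, nM (scalar or vectorized like `p_total`).
#' @param params A [binding_params()] object.
#' @return A tibble of class `mixture_state` with one row per `p_total`:
#'   columns `p_total`, `d_total`, `free_protein`, species concentrations
#'   `d00`, `d10`, `d01`, `d11` (nM) and per-site occupancies
#'   `theta_site1`, `theta_site2`.
#' @examples
#' two_site_species(250, 250, binding_params(kd1 = 1.7))
#' @export
two_site_species <- function(p_total, d_total, params) {
  stopifnot(inherits(params, "binding_params"))
  if (any(p_total < 0) || any(d_total < 0)) {
    abort("concentrations must be nonnegative.")
  }
  n <- max(length(p_total), length(d_total))
  p_total <- rep_len(p_total, n)
  d_total <- rep_len(d_total, n)
  kd1 <- params$kd1; kd2 <- params$kd2; omega <- params$omega

  free <- vapply(seq_len(n), function(i) {
    two_site_free_protein_1(p_total[i], d_total[i], kd1, kd2, omega)
  }, numeric(1))

  w1 <- free / kd1
  w2 <- if (is.finite(kd2)) free / kd2 else rep(0, n)
  w12 <- omega * w1 * w2
  z <- 1 + w1 + w2 + w12
  d00 <- d_total / z
  out <- tibble::tibble(
    p_total = p_total, d_total = d_total, free_protein = free,
    d00 = d00, d10 = d00 * w1, d01 = d00 * w2, d11 = d00 * w12
  )
  out$theta_site1 <- ifelse(d_total > 0, (out$d10 + out$d11) / d_total, 0)
  out$theta_site2 <- ifelse(d_total > 0, (out$d01 + out$d11) / d_total, 0)
  class(out) <- c("mixture_state", class(out))
  out
}

#' Mass-balance residuals of a solved two-site state
#'
#' Returns the relative DNA and protein conservation errors of a
#' [two_site_species()] result, mainly for verification.
#'
#' @param state A `mixture_state` tibble.
#' @return A tibble with columns `dna_error` and `protein_error`
#'   (relative, per row).
#' @export
conservation_error <- function(state) {
  dna <- state$d00 + state$d10 + state$d01 + state$d11
  prot <- state$free_protein + state$d10 + state$d01 + 2 * state$d11
  tibble::tibble(
    dna_error = abs(dna - state$d_total) / pmax(state$d_total, .Machine$double.eps),
    protein_error = abs(prot - state$p_total) / pmax(state$p_total, .Machine$double.eps)
  )
}
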