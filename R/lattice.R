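# Per-placement binding weights (1/Kd) of a construct. A placement is
# specific only when exactly in register on a site interval; every other
# start position is nonspecific (weight 0 when kd_nonspecific = Inf).
placement_table <- function(construct) {
  L <- construct$length
  f <- construct$footprint
  if (L < f) {
    return(data.frame(start = integer(0), end = integer(0),
                      specific = logical(0), inv_kd = numeric(0)))
  }
  starts <- seq_len(L - f + 1L)
  ends <- starts + f - 1L
  specific <- rep(FALSE, base::length(starts))
  inv_kd <- rep(if (is.finite(construct$kd_nonspecific))
    1 / construct$kd_nonspecific else 0, base::length(starts))
  for (i in seq_along(construct$specific_sites)) {
    s <- construct$specific_sites[[i]]
    hit <- which(starts == s[1])
    if (base::length(hit)) {
      specific[hit] <- TRUE
      inv_kd[hit] <- 1 / construct$kd_specific[i]
    }
  }
  data.frame(start = starts, end = ends, specific = specific, inv_kd = inv_kd)
}

# Occupancy-resolved partition-function coefficients by transfer-matrix
# (sequential) recursion: Z[i] is the vector of coefficients a_n such that
# the partition function of the first i bp is sum_n a_n P^n. Runs in
# O(length * n_max) and is exact.
occupancy_coefficients <- function(construct) {
  L <- construct$length
  f <- construct$footprint
  nmax <- max_occupancy(L, f)
  pl <- placement_table(construct)
  # Z[[i + 1]] corresponds to lattice prefix of length i
  Z <- vector("list", L + 1L)
  Z[[1L]] <- c(1, rep(0, nmax))
  by_end <- split(pl, pl$end)
  for (i in seq_len(L)) {
    acc <- Z[[i]]
    rows <- by_end[[as.character(i)]]
    if (!is.null(rows)) {
      for (j in seq_len(nrow(rows))) {
        w <- rows$inv_kd[j]
        if (w > 0) {
          prev <- Z[[rows$start[j]]]
          # placing one dimer shifts the occupancy index by one
          acc <- acc + w * c(0, prev[seq_len(nmax)])
        }
      }
    }
    Z[[i + 1L]] <- acc
  }
  coefs <- Z[[L + 1L]]
  names(coefs) <- as.character(0:nmax)
  coefs
}

#' Enumerate all non-overlapping dimer placements on a construct
#'
#' Exhaustively lists every configuration (set of mutually non-overlapping
#' footprint placements) on a lattice, with its occupancy counts and
#' statistical-weight factor `prod(1/Kd)` over placed dimers (the full
#' weight of a configuration with `n` dimers at free protein `P` is
#' `P^n * weight_inv_kd`). Intended as the brute-force reference for the
#' transfer-matrix recursion; guarded to lattices of at most 200 bp.
#'
#' @param construct A [dna_construct()].
#' @param max_length Enumeration guard, bp. Default 200.
#' @return A tibble with one row per configuration: `config`, `n_bound`,
#'   `n_specific`, `n_nonspecific`, `starts` (list column of placement
#'   start positions) and `weight_inv_kd`.
#' @examples
#' enumerate_configurations(dna_construct("bare", 20, footprint = 10,
#'                                        kd_nonspecific = 100))
#' @export
enumerate_configurations <- function(construct, max_length = 200) {
  stopifnot(inherits(construct, "dna_construct"))
  if (construct$length > max_length) {
    abort(paste0("lattice of ", construct$length, " bp exceeds the ",
                 max_length, " bp enumeration guard; use the ",
                 "transfer-matrix path (species_distribution)."))
  }
  pl <- placement_table(construct)
  pl <- pl[pl$inv_kd > 0, , drop = FALSE]
  configs <- list(list(starts = integer(0), spec = 0L, nonspec = 0L,
                       w = 1))
  if (nrow(pl)) {
    recurse <- function(idx, min_start) {
      out <- list()
      for (k in seq(idx, nrow(pl))) {
        if (pl$start[k] < min_start) next
        base <- list(starts = pl$start[k],
                     spec = as.integer(pl$specific[k]),
                     nonspec = as.integer(!pl$specific[k]),
                     w = pl$inv_kd[k])
        out <- c(out, list(base))
        if (k < nrow(pl)) {
          for (sub in recurse(k + 1L, pl$end[k] + 1L)) {
            out <- c(out, list(list(
              starts = c(pl$start[k], sub$starts),
              spec = base$spec + sub$spec,
              nonspec = base$nonspec + sub$nonspec,
              w = base$w * sub$w
            )))
          }
        }
      }
      out
    }
    configs <- c(configs, recurse(1L, 1L))
  }
  tibble::tibble(
    config = seq_along(configs),
    n_bound = vapply(configs, function(x) x$spec + x$nonspec, integer(1)),
    n_specific = vapply(configs, function(x) x$spec, integer(1)),
    n_nonspecific = vapply(configs, function(x) x$nonspec, integer(1)),
    starts = lapply(configs, function(x) x$starts),
    weight_inv_kd = vapply(configs, function(x) x$w, numeric(1))
  )
}

# Mean occupancy per DNA and its derivative in P, from coefficients.
lattice_nu <- function(coefs, P) {
  n <- seq_along(coefs) - 1
  Pn <- outer(P, n, `^`)
  Zm <- Pn %*% coefs
  Nm <- Pn %*% (n * coefs)
  as.numeric(Nm / Zm)
}

lattice_probabilities <- function(coefs, P) {
  n <- seq_along(coefs) - 1
  terms <- unname(coefs) * P^n
  terms / sum(terms)
}

# Shared free-protein root for one or several DNA species competing for
# one protein pool: P + sum_j d_j * nu_j(P) = p_total. nu_j is strictly
# increasing, so the bracket [0, p_total] always contains the unique root.
solve_free_protein <- function(coef_list, d_totals, p_total) {
  if (p_total == 0) return(0)
  g <- function(P) {
    tot <- P
    for (j in seq_along(coef_list)) {
      if (d_totals[j] > 0) {
        tot <- tot + d_totals[j] * lattice_nu(coef_list[[j]], P)
      }
    }
    tot - p_total
  }
  r <- uniroot(g, c(0, p_total),
               tol = .Machine$double.eps^0.75 * max(1, p_total))
  root <- r$root
  # secant polish to push conservation to ~1e-12 relative
  for (i in 1:6) {
    fr <- g(root)
    if (abs(fr) <= 1e-13 * max(1, p_total)) break
    h <- max(abs(root), 1e-8) * 1e-7
    dfr <- (g(root + h) - fr) / h
    newr <- min(max(root - fr / dfr, 0), p_total)
    if (!is.finite(newr)) break
    root <- newr
  }
  root
}

#' Per-DNA occupancy distribution on a finite lattice
#'
#' Computes the probability that a DNA molecule carries n bound dimers
#' (n = 0 .. `max_occupancy`) at equilibrium, with the free protein
#' concentration solved self-consistently from total-protein conservation
#' over all DNA molecules. This formalizes EMSA band quantification: each
#' n corresponds to one gel band.
#'
#' @param construct A [dna_construct()].
#' @param p_total Total protein dimer, nM (vectorized: one distribution
#'   per concentration).
#' @param d_total Total DNA, nM.
#' @param method `"transfer"` (default, any length) or `"enumerate"`
#'   (brute force, <= 200 bp; reference path).
#' @return A tibble of class `species_distribution` with columns
#'   `p_total`, `n`, `probability`, `free_protein`, `mean_occupancy`.
#' @examples
#' hiv <- dna_construct("HIV-LTR", 33, list(c(3, 12), c(17, 26)),
#'                      kd_specific = 1.7)
#' species_distribution(hiv, p_total = 250, d_total = 250)
#' @export
species_distribution <- function(construct, p_total, d_total,
                                 method = c("transfer", "enumerate")) {
  stopifnot(inherits(construct, "dna_construct"))
  method <- match.arg(method)
  if (any(p_total < 0) || d_total < 0) abort("concentrations must be >= 0.")
  coefs <- if (method == "transfer") {
    occupancy_coefficients(construct)
  } else {
    cfg <- enumerate_configurations(construct)
    nmax <- max_occupancy(construct$length, construct$footprint)
    vapply(0:nmax, function(n) {
      sum(cfg$weight_inv_kd[cfg$n_bound == n])
    }, numeric(1))
  }
  res <- lapply(p_total, function(p) {
    P <- solve_free_protein(list(coefs), d_total, p)
    pr <- lattice_probabilities(coefs, P)
    tibble::tibble(
      p_total = p, n = seq_along(pr) - 1L, probability = pr,
      free_protein = P, mean_occupancy = sum((seq_along(pr) - 1) * pr)
    )
  })
  out <- dplyr::bind_rows(res)
  out$d_total <- d_total
  out$construct <- construct$name
  out <- out[, c("construct", "p_total", "d_total", "n", "probability",
                 "free_protein", "mean_occupancy")]
  class(out) <- c("species_distribution", class(out))
  out
}

#' Collapse high occupancies into a terminal band
#'
#' EMSA gels resolve discrete bands up to about three bound dimers, with
#' higher stoichiometries appearing as a smear. This regroups a
#' [species_distribution()] so that occupancies at or above `max_band`
#' are pooled into one `"max_band+"` bin.
#'
#' @param dist A `species_distribution` tibble.
#' @param max_band First pooled occupancy. Default 4 (bands 0-3 kept).
#' @return A tibble with `band` (character, e.g. `"4+"`) replacing `n`.
#' @export
collapse_bands <- function(dist, max_band = 4) {
  stopifnot(is.data.frame(dist), max_band >= 1)
  dist |>
    dplyr::mutate(band = ifelse(.data$n >= max_band,
                                paste0(max_band, "+"),
                                as.character(.data$n))) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("construct", "p_total", "d_total", "free_protein",
        "mean_occupancy", "band")))) |>
    dplyr::summarise(probability = sum(.data$probability),
                     .groups = "drop") |>
    dplyr::arrange(.data$p_total)
}

#' Simultaneous equilibrium of several DNA species sharing one protein pool
#'
#' Solves for the single free-protein concentration at which total-protein
#' conservation holds across all DNA species at once, then reports each
#' construct's occupancy distribution at that shared concentration. This
#' is the competition experiment: adding a specific hairpin competitor
#' strips dimers from a tandem promoter, while a weak nonspecific
#' competitor barely perturbs it.
#'
#' @param constructs List of [dna_construct()] objects.
#' @param d_totals Numeric vector of DNA concentrations, nM (recycled).
#' @param p_total Total protein dimer, nM (scalar).
#' @return A `species_distribution` tibble covering all constructs, all
#'   rows sharing one `free_protein` value.
#' @export
competition_distribution <- function(constructs, d_totals, p_total) {
  stopifnot(base::length(constructs) >= 1,
            all(vapply(constructs, inherits, logical(1), "dna_construct")))
  d_totals <- rep_len(d_totals, base::length(constructs))
  if (p_total < 0 || any(d_totals < 0)) abort("concentrations must be >= 0.")
  coef_list <- lapply(constructs, occupancy_coefficients)
  P <- solve_free_protein(coef_list, d_totals, p_total)
  out <- dplyr::bind_rows(lapply(seq_along(constructs), function(j) {
    pr <- lattice_probabilities(coef_list[[j]], P)
    tibble::tibble(
      construct = constructs[[j]]$name, p_total = p_total,
      d_total = d_totals[j], n = seq_along(pr) - 1L, probability = pr,
      free_protein = P,
      mean_occupancy = sum((seq_along(pr) - 1) * pr)
    )
  }))
  class(out) <- c("species_distribution", class(out))
  out
}
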