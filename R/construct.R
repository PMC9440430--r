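#' Define a DNA construct for the lattice binding model
#'
#' A construct is a finite one-dimensional lattice of `length` bp on which
#' protein dimers bind with a fixed footprint. Specific kappa-B sites are
#' 1-based inclusive bp intervals whose width equals the footprint; a dimer
#' placed exactly in register on such an interval binds with that site's
#' specific dissociation constant, every other (non-overlapping, fully
#' on-lattice) placement binds with the nonspecific constant.
#'
#' @param name Identifier.
#' @param length Lattice length, bp.
#' @param specific_sites List of `c(start, end)` 1-based inclusive
#'   intervals (may be empty). Sites must not overlap and must each span
#'   exactly `footprint` bp.
#' @param footprint bp occluded per bound dimer. Default 10.
#' @param kd_specific Per-site dissociation constant(s), nM; recycled to
#'   the number of sites.
#' @param kd_nonspecific Nonspecific dissociation constant, nM; `Inf`
#'   disables nonspecific binding.
#' @return An object of class `dna_construct`.
#' @examples
#' dna_construct("HIV-LTR", 33, list(c(3, 12), c(17, 26)), kd_specific = 1.7)
#' @export
dna_construct <- function(name, length, specific_sites = list(),
                          footprint = 10L, kd_specific = 1,
                          kd_nonspecific = Inf) {
  stopifnot(is.numeric(length), length >= 0, is.numeric(footprint))
  if (footprint < 1) abort("`footprint` must be >= 1 bp.")
  length <- as.integer(length)
  footprint <- as.integer(footprint)
  if (is.matrix(specific_sites)) {
    specific_sites <- split(specific_sites, seq_len(nrow(specific_sites)))
  }
  specific_sites <- lapply(specific_sites, function(s) as.integer(s[1:2]))
  for (s in specific_sites) {
    if (s[1] < 1 || s[2] > length || s[1] > s[2]) {
      abort("each site must satisfy 1 <= start <= end <= length.")
    }
    if (s[2] - s[1] + 1L != footprint) {
      abort("specific sites must span exactly `footprint` bp.")
    }
  }
  if (base::length(specific_sites) > 1L) {
    starts <- vapply(specific_sites, `[`, integer(1), 1L)
    ends <- vapply(specific_sites, `[`, integer(1), 2L)
    ord <- order(starts)
    specific_sites <- specific_sites[ord]
    if (any(starts[ord][-1] <= ends[ord][-base::length(ends)])) {
      abort("specific sites must not overlap.")
    }
  }
  kd_specific <- rep_len(kd_specific, max(base::length(specific_sites), 1L))
  if (base::length(specific_sites) == 0L) kd_specific <- numeric(0)
  if (any(kd_specific <= 0) || kd_nonspecific <= 0) {
    abort("dissociation constants must be > 0 (nM).")
  }
  structure(
    list(name = name, length = length, specific_sites = specific_sites,
         footprint = footprint, kd_specific = kd_specific,
         kd_nonspecific = kd_nonspecific),
    class = "dna_construct"
  )
}

#' @export
print.dna_construct <- function(x, ...) {
  cat(sprintf("<dna_construct> %s: %d bp, footprint %d bp\n",
              x$name, x$length, x$footprint))
  if (length(x$specific_sites)) {
    for (i in seq_along(x$specific_sites)) {
      s <- x$specific_sites[[i]]
      cat(sprintf("  site %d: %d-%d (Kd %g nM)\n", i, s[1], s[2],
                  x$kd_specific[i]))
    }
  } else cat("  no specific sites\n")
  cat(sprintf("  nonspecific Kd: %g nM\n", x$kd_nonspecific))
  invisible(x)
}

#' Maximum number of dimers a lattice can accommodate
#'
#' With hard-core exclusion and a fixed footprint, at most
#' `floor(length / footprint)` dimers fit on a lattice: 3 on the 33 bp
#' tandem segment, 2 on a 21 bp nonspecific stretch.
#'
#' @param length Lattice length, bp.
#' @param footprint bp per bound dimer (>= 1).
#' @return Integer dimer count.
#' @examples
#' max_occupancy(33, 10) # 3
#' @export
max_occupancy <- function(length, footprint = 10) {
  if (any(footprint < 1)) abort("`footprint` must be >= 1 bp.")
  if (any(length < 0)) abort("`length` must be >= 0 bp.")
  as.integer(length %/% footprint)
}

#' Longest contiguous nonspecific stretch of a construct
#'
#' Length in bp of the longest interval disjoint from all specific sites.
#' Stretches of at least one footprint can host extra dimers without
#' displacing a specifically bound one, which is what drives higher-order
#' complex formation on site-scrambled promoter segments.
#'
#' @param construct A [dna_construct()].
#' @return Integer bp length.
#' @export
longest_nonspecific_stretch <- function(construct) {
  stopifnot(inherits(construct, "dna_construct"))
  covered <- rep(FALSE, construct$length)
  for (s in construct$specific_sites) covered[s[1]:s[2]] <- TRUE
  if (!any(!covered)) return(0L)
  runs <- rle(covered)
  as.integer(max(runs$lengths[!runs$values]))
}
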