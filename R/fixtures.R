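#' Hairpin DNA sequences used in the binding assays
#'
#' The fluorescein-labeled hairpin oligonucleotides: five kappa-B promoter
#' sites (IFN-beta, urokinase, RANTES, HIV-LTR, and the two NFKBIA sites)
#' plus a random nonspecific control. Each hairpin folds into a duplex
#' stem carrying the site with a CCCCC loop treated as a non-binding
#' spacer.
#'
#' @return Tibble with columns `name`, `sequence`, `role`
#'   (`"specific"` / `"nonspecific"`), `stem_bp` (duplex stem length).
#' @export
kb_sequences <- function() {
  seqs <- tibble::tibble(
    name = c("IFN-beta", "UK", "RANTES", "HIV-LTR", "Random",
             "NFKBIA site 1", "NFKBIA site 2"),
    sequence = c(
      "GGGAAATTCCTCCCCCAGGAATTTCCC",
      "GGGAAAGTACTCCCCCAGTACTTTCCC",
      "GGGAGTTTCCTCCCCCAGGAAACTCCC",
      "GGGACTTTCCTCCCCCAGGAAAGTCCC",
      "GTAGACGTGCTCCCCCAGCACGTCTAC",
      "TGGAAATTCCCTCCCCCAGGGAATTTCCA",
      "AGAGAAATCCCTCCCCCAGGGATTTCTCT"
    ),
    role = c("specific", "specific", "specific", "specific",
             "nonspecific", "specific", "specific")
  )
  seqs$stem_bp <- (nchar(seqs$sequence) - 5L) %/% 2L
  seqs
}

#' Construct geometries for the lattice and titration models
#'
#' Returns the DNA constructs of the study as [dna_construct()] objects.
#' Two geometry families are provided, because the gel-shift segments and
#' the anisotropy duplexes differ:
#' \describe{
#'   \item{EMSA segments}{`hiv_ltr` (33 bp, two identical 10 bp sites
#'     separated by 4 bp, placed so that scrambling site 1 leaves a 16 bp
#'     and scrambling site 2 a 21 bp contiguous nonspecific stretch) and
#'     `nfkbia` (59 bp, two sites separated by 19 bp); each with
#'     `_site1_scrambled` / `_site2_scrambled` variants.}
#'   \item{Anisotropy duplexes}{`hiv_ltr_fa` (30 bp) and `nfkbia_fa`
#'     (45 bp), with exactly 3 bp flanking the tandem sites so a 5'
#'     fluorophore reports its proximal site only.}
#'   \item{Hairpins}{single-site stem constructs (`hairpin_specific`) and
#'     the site-free nonspecific stem (`hairpin_random`).}
#' }
#' The exact tandem duplex sequences are not bundled; geometry (printed
#' segment lengths, site separations and scramble stretch lengths) fully
#' determines the lattice model.
#'
#' @param kd_specific Default specific-site Kd, nM, applied to all sites
#'   unless overridden downstream. Default 1.7.
#' @param kd_nonspecific Default nonspecific Kd, nM. Default `Inf`
#'   (nonspecific binding off).
#' @param footprint bp per dimer. Default 10.
#' @return Named list of `dna_construct` objects.
#' @export
kb_constructs <- function(kd_specific = 1.7, kd_nonspecific = Inf,
                          footprint = 10) {
  f <- footprint
  list(
    hiv_ltr = dna_construct(
      "HIV-LTR", 33, list(c(3, 12), c(17, 26)), f,
      kd_specific, kd_nonspecific),
    hiv_ltr_site1_scrambled = dna_construct(
      "HIV-LTR site1 scrambled", 33, list(c(17, 26)), f,
      kd_specific, kd_nonspecific),
    hiv_ltr_site2_scrambled = dna_construct(
      "HIV-LTR site2 scrambled", 33, list(c(3, 12)), f,
      kd_specific, kd_nonspecific),
    nfkbia = dna_construct(
      "NFKBIA", 59, list(c(11, 20), c(40, 49)), f,
      kd_specific, kd_nonspecific),
    nfkbia_site1_scrambled = dna_construct(
      "NFKBIA site1 scrambled", 59, list(c(40, 49)), f,
      kd_specific, kd_nonspecific),
    nfkbia_site2_scrambled = dna_construct(
      "NFKBIA site2 scrambled", 59, list(c(11, 20)), f,
      kd_specific, kd_nonspecific),
    hiv_ltr_fa = dna_construct(
      "HIV-LTR anisotropy duplex", 30, list(c(4, 13), c(18, 27)), f,
      kd_specific, kd_nonspecific),
    nfkbia_fa = dna_construct(
      "NFKBIA anisotropy duplex", 45, list(c(4, 13), c(33, 42)), f,
      kd_specific, kd_nonspecific),
    hairpin_specific = dna_construct(
      "specific hairpin stem", 11, list(c(1, 10)), f,
      kd_specific, Inf),
    hairpin_random = dna_construct(
      "random hairpin stem", 11, list(), f,
      kd_specific = 1, kd_nonspecific = if (is.finite(kd_nonspecific))
        kd_nonspecific else 130)
  )
}

#' Export hairpin sequences as FASTA
#'
#' @param sequences Tibble from [kb_sequences()] (columns `name`,
#'   `sequence`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(sequences, path) {
  stopifnot(is.data.frame(sequences),
            all(c("name", "sequence") %in% names(sequences)))
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    abort("package `seqinr` is required for FASTA export.")
  }
  seqinr::write.fasta(
    sequences = as.list(tolower(sequences$sequence)),
    names = sequences$name, file.out = path
  )
  invisible(path)
}
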