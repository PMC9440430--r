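test_that("zero-noise titrations equal the model signal", {
  truth <- binding_params(2, amplitude = 0.1, baseline = 0.05)
  cur <- generate_titration(truth, d_total = 5,
                            noise = noise_model(0, n_replicates = 1))
  expected <- 0.05 + 0.1 * single_site_complex(cur$conc_nM, 5, 2) / 5
  expect_equal(cur$anisotropy, expected, tolerance = 1e-15)
})

test_that("generation is deterministic under a fixed seed", {
  truth <- binding_params(5, amplitude = 0.1)
  a <- generate_titration(truth, noise = noise_model(0.003, seed = 4))
  b <- generate_titration(truth, noise = noise_model(0.003, seed = 4))
  expect_identical(a, b)
  c <- generate_titration(truth, noise = noise_model(0.003, seed = 5))
  expect_false(identical(a$anisotropy, c$anisotropy))
  # replicates draw distinct noise via the documented seed rule
  expect_identical(replicate_seed(4, 2), 402L)
  a1 <- a$anisotropy[a$replicate == 1]
  a2 <- a$anisotropy[a$replicate == 2]
  expect_false(identical(a1, a2))
})

test_that("titration noise has the requested moments", {
  truth <- binding_params(10, amplitude = 0.1, baseline = 0.05)
  series <- rep(default_conc_series(), length.out = 1000)
  cur <- generate_titration(truth, d_total = 5, conc_series = series,
                            noise = noise_model(0.003, seed = 8,
                                                n_replicates = 1))
  clean <- 0.05 + 0.1 * single_site_complex(series, 5, 10) / 5
  resid <- cur$anisotropy - clean
  expect_lt(abs(mean(resid)), 3 * 0.003 / sqrt(1000))
  expect_equal(sd(resid), 0.003, tolerance = 0.1)
})

test_that("two-site generation reads the labeled site", {
  truth <- binding_params(1.7, 10, amplitude = 0.1, baseline = 0)
  fwd <- generate_titration(truth, label = "forward", d_total = 5,
                            noise = noise_model(0, n_replicates = 1))
  rev <- generate_titration(truth, label = "reverse", d_total = 5,
                            noise = noise_model(0, n_replicates = 1))
  st <- two_site_species(fwd$conc_nM, 5, truth)
  expect_equal(fwd$anisotropy, 0.1 * st$theta_site1, tolerance = 1e-12)
  expect_equal(rev$anisotropy, 0.1 * st$theta_site2, tolerance = 1e-12)
  # weaker site 2 gives the sigmoidal, right-shifted curve
  expect_true(all(rev$anisotropy <= fwd$anisotropy + 1e-12))
})

test_that("EMSA tables reproduce the lattice model and normalize", {
  con <- kb_constructs(kd_specific = 1.7, kd_nonspecific = Inf)$hiv_ltr
  tab <- generate_emsa(con)
  zero <- tab[tab$p_total == 0, ]
  expect_equal(zero$fraction[zero$n == 0], 1)
  expect_equal(sum(zero$fraction), 1)
  equi <- tab[tab$p_total == 250, ]
  expect_equal(equi$fraction[equi$n == 1] / equi$fraction[equi$n == 2], 2,
               tolerance = 0.05)
  sums <- tapply(tab$fraction, tab$p_total, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  noisy1 <- generate_emsa(con, noise_sd_fraction = 0.02, seed = 3)
  noisy2 <- generate_emsa(con, noise_sd_fraction = 0.02, seed = 3)
  expect_identical(noisy1, noisy2)
  sums_n <- tapply(noisy1$fraction, noisy1$p_total, sum)
  expect_true(all(abs(sums_n - 1) < 1e-9))
  expect_true(all(noisy1$fraction >= 0))
})

test_that("sequence fixtures carry the printed hairpins", {
  seqs <- kb_sequences()
  expect_identical(nrow(seqs), 7L)
  expect_identical(seqs$sequence[seqs$name == "Random"],
                   "GTAGACGTGCTCCCCCAGCACGTCTAC")
  expect_identical(seqs$sequence[seqs$name == "HIV-LTR"],
                   "GGGACTTTCCTCCCCCAGGAAAGTCCC")
  expect_true(all(nchar(seqs$sequence) %in% c(27L, 29L)))
  expect_true(all(seqs$stem_bp == (nchar(seqs$sequence) - 5) %/% 2))
})

test_that("construct fixtures honor the printed geometries", {
  cs <- kb_constructs()
  expect_identical(cs$hiv_ltr$length, 33L)
  expect_identical(cs$nfkbia$length, 59L)
  expect_identical(base::length(cs$hiv_ltr$specific_sites), 2L)
  gap_hiv <- cs$hiv_ltr$specific_sites[[2]][1] -
    cs$hiv_ltr$specific_sites[[1]][2] - 1L
  expect_identical(gap_hiv, 4L)
  gap_nf <- cs$nfkbia$specific_sites[[2]][1] -
    cs$nfkbia$specific_sites[[1]][2] - 1L
  expect_identical(gap_nf, 19L)
  expect_identical(cs$hiv_ltr_fa$length, 30L)
  expect_identical(cs$nfkbia_fa$length, 45L)
  # 3 bp flanks on the anisotropy duplexes
  expect_identical(cs$hiv_ltr_fa$specific_sites[[1]][1], 4L)
  expect_identical(cs$hiv_ltr_fa$length -
                     cs$hiv_ltr_fa$specific_sites[[2]][2], 3L)
})

test_that("fixture sequences export as FASTA", {
  path <- withr::local_tempfile(fileext = ".fasta")
  export_fasta(kb_sequences(), path)
  back <- seqinr::read.fasta(path, as.string = TRUE)
  expect_identical(base::length(back), 7L)
  expect_identical(toupper(as.character(back[["Random"]])),
                   "GTAGACGTGCTCCCCCAGCACGTCTAC")
})
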