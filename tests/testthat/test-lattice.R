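test_that("max occupancy is the footprint quotient", {
  expect_identical(max_occupancy(33, 10), 3L)
  expect_identical(max_occupancy(21, 10), 2L)
  expect_identical(max_occupancy(9, 10), 0L)
  expect_error(max_occupancy(33, 0), "footprint")
})

test_that("construct validation enforces site geometry", {
  expect_error(dna_construct("x", 20, list(c(0, 9))), "start")
  expect_error(dna_construct("x", 20, list(c(1, 9))), "footprint")
  expect_error(dna_construct("x", 30, list(c(1, 10), c(5, 14))), "overlap")
  expect_error(dna_construct("x", 20, kd_nonspecific = -1), "dissociation")
})

test_that("nonspecific stretch lengths reproduce the promoter geometries", {
  cs <- kb_constructs()
  expect_lt(longest_nonspecific_stretch(cs$hiv_ltr), 10)
  expect_identical(longest_nonspecific_stretch(cs$hiv_ltr_site1_scrambled), 16L)
  expect_identical(longest_nonspecific_stretch(cs$hiv_ltr_site2_scrambled), 21L)
  bare <- dna_construct("bare", 33)
  expect_identical(longest_nonspecific_stretch(bare), 33L)
})

test_that("configuration enumeration counts match exhaustive recursion", {
  one <- dna_construct("one", 10, footprint = 10, kd_nonspecific = 50)
  expect_identical(nrow(enumerate_configurations(one)), 2L)
  two <- dna_construct("two", 20, footprint = 10, kd_nonspecific = 50)
  cfg <- enumerate_configurations(two)
  # 1 empty + 11 single placements + 1 double (starts 1 and 11)
  expect_identical(nrow(cfg), 13L)
  expect_identical(sum(cfg$n_bound == 2), 1L)
  hiv <- kb_constructs(kd_nonspecific = 1500)$hiv_ltr
  expect_identical(max(enumerate_configurations(hiv)$n_bound), 3L)
  big <- dna_construct("big", 300, kd_nonspecific = 100)
  expect_error(enumerate_configurations(big), "transfer-matrix")
})

test_that("transfer matrix and enumeration agree on lattices up to 40 bp", {
  set.seed(7)
  for (i in 1:6) {
    L <- sample(10:40, 1)
    f <- sample(5:10, 1)
    n_sites <- sample(0:2, 1)
    sites <- list()
    if (n_sites >= 1 && L >= f) sites <- list(c(1L, f))
    if (n_sites == 2 && L >= 2 * f + 2) {
      sites <- c(sites, list(c(f + 3L, 2L * f + 2L)))
    }
    con <- dna_construct("rand", L, sites, f,
                         kd_specific = 10^runif(1, 0, 1),
                         kd_nonspecific = 10^runif(1, 1, 3))
    for (p in c(10, 200, 3000)) {
      a <- species_distribution(con, p, 100, method = "transfer")
      b <- species_distribution(con, p, 100, method = "enumerate")
      expect_rel_equal(a$probability + 1, b$probability + 1, 1e-8)
      expect_rel_equal(a$free_protein, b$free_protein, 1e-8)
    }
  }
})

test_that("lattice with two specific sites reduces to the two-site model", {
  con <- kb_constructs(kd_specific = 1.7, kd_nonspecific = Inf)$hiv_ltr
  for (p in c(50, 250, 900)) {
    d <- species_distribution(con, p, 250)
    st <- two_site_species(p, 250, binding_params(1.7))
    expect_rel_equal(d$probability[d$n == 0], st$d00 / 250, 1e-6)
    expect_rel_equal(d$probability[d$n == 1], (st$d10 + st$d01) / 250, 1e-6)
    expect_rel_equal(d$probability[d$n == 2], st$d11 / 250, 1e-6)
    expect_equal(d$probability[d$n == 3], 0)
  }
})

test_that("equimolar tandem lattice shows the 1:2:1 band pattern", {
  con <- kb_constructs(kd_specific = 1.7, kd_nonspecific = Inf)$hiv_ltr
  d <- species_distribution(con, 250, 250)
  p <- d$probability
  expect_equal(p[d$n == 1] / p[d$n == 2], 2, tolerance = 0.05)
  expect_equal(p[d$n == 0] / p[d$n == 2], 1, tolerance = 0.1)
})

test_that("distributions are normalized with free protein in range", {
  con <- kb_constructs(kd_specific = 2, kd_nonspecific = 300)$nfkbia
  d <- species_distribution(con, c(0, 125, 2000), 250)
  sums <- tapply(d$probability, d$p_total, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(d$free_protein >= 0 & d$free_protein <= d$p_total))
  expect_true(all(d$probability >= 0))
  expect_true(all(d$n <= max_occupancy(59, 10)))
})

test_that("weakening nonspecific binding lowers mean occupancy", {
  cons <- lapply(c(100, 1000, 1e4), function(kns) {
    kb_constructs(kd_specific = 1.7, kd_nonspecific = kns)$hiv_ltr
  })
  occ <- vapply(cons, function(cc) {
    species_distribution(cc, 2000, 250)$mean_occupancy[1]
  }, numeric(1))
  expect_true(all(diff(occ) < 0))
})

test_that("high-occupancy bands collapse into a terminal bin", {
  con <- kb_constructs(kd_specific = 1.7, kd_nonspecific = 150)$nfkbia
  d <- species_distribution(con, 2000, 250)
  b <- collapse_bands(d, max_band = 4)
  expect_setequal(b$band, c("0", "1", "2", "3", "4+"))
  expect_equal(sum(b$probability), 1, tolerance = 1e-9)
  expect_equal(b$probability[b$band == "4+"],
               sum(d$probability[d$n >= 4]), tolerance = 1e-12)
})

test_that("identical competitors split the pool symmetrically", {
  con <- kb_constructs(kd_specific = 1.7)$hiv_ltr
  cd <- competition_distribution(list(con, con), c(250, 250), 500)
  a <- cd$probability[seq_len(4)]
  b <- cd$probability[4 + seq_len(4)]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("a specific hairpin competes for protein; nonspecific barely", {
  hiv <- kb_constructs(kd_specific = 1.7, kd_nonspecific = Inf)$hiv_ltr
  specific_hp <- dna_construct("specific hairpin", 11, list(c(1, 10)),
                               kd_specific = 3, kd_nonspecific = Inf)
  nonspecific_hp <- dna_construct("random hairpin", 11, list(),
                                  kd_nonspecific = 130)
  alone <- species_distribution(hiv, 500, 250)
  with_spec <- competition_distribution(list(hiv, specific_hp),
                                        c(250, 250), 500)
  with_ns <- competition_distribution(list(hiv, nonspecific_hp),
                                      c(250, 250), 500)
  doubly <- function(d) d$probability[d$construct == "HIV-LTR" & d$n == 2]
  drop_spec <- doubly(alone) - doubly(with_spec)
  drop_ns <- doubly(alone) - doubly(with_ns)
  expect_lt(doubly(with_spec), doubly(alone))
  expect_gt(drop_spec, 3 * drop_ns)
})
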