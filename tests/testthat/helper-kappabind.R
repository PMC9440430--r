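# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# forward + reverse labeled curve set from one truth, distinct noise
# seeds per label so the two strands carry independent noise
make_two_label_curves <- function(truth, sigma = 0, seed_f = 1, seed_r = 2,
                                  n_replicates = 1, d_total = 5,
                                  conc_series = default_conc_series()) {
  dplyr::bind_rows(
    generate_titration(truth, label = "forward", d_total = d_total,
                       conc_series = conc_series,
                       noise = noise_model(sigma, seed_f, n_replicates)),
    generate_titration(truth, label = "reverse", d_total = d_total,
                       conc_series = conc_series,
                       noise = noise_model(sigma, seed_r, n_replicates))
  )
}

# independent oracle for the single-site mass balance: bounded root-find
# on c -> (p - c)(d - c)/c - kd, never the closed form under test
oracle_single_site <- function(p, d, kd) {
  if (p == 0 || d == 0) return(0)
  f <- function(cc) (p - cc) * (d - cc) - kd * cc
  upper <- min(p, d)
  cc <- stats::uniroot(f, c(0, upper), tol = 1e-14 * max(1, upper))$root
  # Newton polish: uniroot's stopping rule is loose for tiny roots
  for (i in 1:6) {
    fp <- -(d - cc) - (p - cc) - kd
    step <- f(cc) / fp
    if (!is.finite(step)) break
    cc <- min(max(cc - step, 0), upper)
    if (abs(step) <= 1e-16 * max(cc, 1e-300)) break
  }
  cc
}

# brute-force oracle for the two-site model: iteratively refined grid
# scan over free protein, independent of the cubic solver
oracle_two_site_free <- function(p, d, kd1, kd2, omega) {
  cons <- function(P) {
    z <- 1 + P / kd1 + P / kd2 + omega * P^2 / (kd1 * kd2)
    nbar <- (P / kd1 + P / kd2 + 2 * omega * P^2 / (kd1 * kd2)) / z
    abs(P + d * nbar - p)
  }
  lo <- 0; hi <- p
  for (round in 1:8) {
    grid <- seq(lo, hi, length.out = 2001)
    err <- vapply(grid, cons, numeric(1))
    i <- which.min(err)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
  }
  (lo + hi) / 2
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("relative difference within %g", tol))
}
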