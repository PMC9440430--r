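test_that("noise-free single-site curves are recovered exactly", {
  for (iso in c("quadratic", "hyperbolic")) {
    truth <- binding_params(2.2, amplitude = 0.1, baseline = 0.05)
    cur <- generate_titration(truth, model = iso, d_total = 5,
                              noise = noise_model(0, n_replicates = 1))
    fit <- fit_single_site(cur, isotherm = iso)
    est <- tidy(fit)
    expect_rel_equal(est$estimate[est$term == "kd"], 2.2, 1e-6)
    expect_rel_equal(est$estimate[est$term == "amplitude"], 0.1, 1e-6)
    expect_true(fit$converged)
    expect_lt(glance(fit)$rss, 1e-12)
  }
})

test_that("a flat titration is flagged unidentifiable", {
  cur <- tibble::tibble(conc_nM = default_conc_series(),
                        anisotropy = rep(0.05, 13))
  fit <- fit_single_site(cur)
  expect_false(fit$converged)
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "amplitude"]), 1e-3)
})

test_that("noisy nonspecific-hairpin titrations recover the weak Kd", {
  truth <- binding_params(130, amplitude = 0.1, baseline = 0.05)
  series <- default_conc_series(n = 12, from = 1, to = 1e4)
  cur <- generate_titration(truth, model = "hyperbolic", d_total = 5,
                            conc_series = series,
                            noise = noise_model(0.003, seed = 1,
                                                n_replicates = 3))
  kds <- vapply(1:3, function(r) {
    est <- tidy(fit_single_site(cur[cur$replicate == r, ], "hyperbolic"))
    est$estimate[est$term == "kd"]
  }, numeric(1))
  expect_rel_equal(mean(kds), 130, 0.15)
})

test_that("single-site Kd recovery has small median bias over many seeds", {
  truth <- binding_params(3, amplitude = 0.1, baseline = 0.05)
  rel_err <- vapply(1:100, function(s) {
    cur <- generate_titration(truth, d_total = 5,
                              noise = noise_model(0.003, seed = s,
                                                  n_replicates = 1))
    est <- tidy(fit_single_site(cur, n_starts = 3))
    est$estimate[est$term == "kd"] / 3 - 1
  }, numeric(1))
  expect_lt(abs(stats::median(rel_err)), 0.05)
})

test_that("fits are invariant to concentration-unit rescaling", {
  truth <- binding_params(40, amplitude = 0.1, baseline = 0.05)
  cur <- generate_titration(truth, d_total = 5,
                            noise = noise_model(0.002, seed = 9,
                                                n_replicates = 1))
  fit_nm <- fit_single_site(cur, d_total = 5)
  cur_um <- dplyr::mutate(cur, conc_nM = conc_nM / 1000)
  fit_um <- fit_single_site(cur_um, d_total = 5 / 1000)
  kd_nm <- tidy(fit_nm)$estimate[1]
  kd_um <- tidy(fit_um)$estimate[1]
  expect_rel_equal(kd_um * 1000, kd_nm, 1e-4)
})

test_that("noise-free global two-site fits recover the truth exactly", {
  for (model in c("equal_kd", "distinct_kd")) {
    truth <- if (model == "equal_kd") {
      binding_params(1.3, amplitude = 0.12, baseline = 0.06)
    } else {
      binding_params(1.7, 10, amplitude = 0.12, baseline = 0.06)
    }
    cv <- make_two_label_curves(truth)
    fit <- fit_global_two_site(cv, model)
    expect_rel_equal(fit$kd1, truth$kd1, 1e-6)
    expect_rel_equal(fit$kd2, truth$kd2, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("global fitting requires both labeling configurations", {
  truth <- binding_params(1.7, amplitude = 0.1, baseline = 0.05)
  fwd_only <- generate_titration(truth, label = "forward", d_total = 5,
                                 noise = noise_model(0, n_replicates = 1))
  expect_error(fit_global_two_site(fwd_only, "equal_kd"),
               class = "kb_input_error")
})

test_that("the equal-Kd constraint never beats distinct Kd on RSS", {
  for (s in 1:4) {
    truth <- binding_params(2, 8, amplitude = 0.12, baseline = 0.06)
    cv <- make_two_label_curves(truth, sigma = 0.003,
                                seed_f = 30 + s, seed_r = 60 + s)
    rss_eq <- fit_global_two_site(cv, "equal_kd")$rss
    rss_di <- fit_global_two_site(cv, "distinct_kd")$rss
    expect_gte(rss_eq, rss_di - 1e-12)
  }
})

test_that("model selection recovers each generating model from clean data", {
  equal_cv <- make_two_label_curves(
    binding_params(1.3, amplitude = 0.12, baseline = 0.06))
  expect_identical(select_model(equal_cv)$chosen, "equal_kd")
  distinct_cv <- make_two_label_curves(
    binding_params(1.7, 10, amplitude = 0.12, baseline = 0.06))
  expect_identical(select_model(distinct_cv)$chosen, "distinct_kd")
  # cooperativity is identifiable away from the titrating (depletion)
  # regime; omega = 5 at a 50 nM site
  coop_cv <- make_two_label_curves(
    binding_params(50, 50, omega = 5, amplitude = 0.12, baseline = 0.06))
  expect_identical(select_model(coop_cv)$chosen, "cooperative")
})

test_that("cooperative truths are selected at noise levels typical of plates", {
  hits <- vapply(1:10, function(s) {
    cv <- make_two_label_curves(
      binding_params(50, 50, omega = 5, amplitude = 0.12, baseline = 0.06),
      sigma = 0.003, seed_f = 300 + 2 * s, seed_r = 301 + 2 * s)
    identical(select_model(cv)$chosen, "cooperative")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("replicate aggregation gives mean and SEM with n-1 variance", {
  df <- tibble::tibble(term = "kd", estimate = c(1.0, 1.3, 1.6))
  agg <- aggregate_replicates(df)
  expect_equal(agg$mean, 1.3)
  expect_equal(agg$sem, 0.3 / sqrt(3), tolerance = 1e-12)
  same <- tibble::tibble(term = "kd", estimate = rep(2.5, 3))
  expect_equal(aggregate_replicates(same)$sem, 0)
  set.seed(11)
  x <- rnorm(7, 10, 2)
  agg2 <- aggregate_replicates(tibble::tibble(term = "kd", estimate = x))
  expect_equal(agg2$mean, sum(x) / 7, tolerance = 1e-12)
  expect_equal(agg2$sem, sqrt(sum((x - mean(x))^2) / 6) / sqrt(7),
               tolerance = 1e-12)
  expect_error(aggregate_replicates(list()), class = "kb_input_error")
})

test_that("group comparison matches Welch and permutation references", {
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  far <- compare_groups(c(1, 1.1, 0.9), c(100, 110, 90))
  expect_lt(far$p_value, 0.01)
  set.seed(3)
  a <- rnorm(6, 5, 1); b <- rnorm(6, 7, 1)
  welch <- compare_groups(a, b)
  perm <- compare_groups(a, b, method = "permutation", n_perm = 20000,
                         seed = 5)
  expect_equal(welch$p_value, t.test(a, b)$p.value, tolerance = 1e-12)
  expect_lt(abs(welch$p_value - perm$p_value),
            0.03 + 3 * sqrt(welch$p_value / 20000))
  expect_error(compare_groups(1, c(1, 2)), class = "kb_input_error")
})
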