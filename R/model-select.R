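# Small-sample-corrected Akaike information criterion for a least-squares
# fit; k counts the model parameters plus the residual variance.
aicc_from_rss <- function(rss, n, n_par) {
  k <- n_par + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(rss, .Machine$double.xmin) / n) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
}

#' Choose between equal-Kd, distinct-Kd and cooperative two-site models
#'
#' Fits each candidate globally with [fit_global_two_site()] and ranks
#' them by small-sample-corrected AIC; ties (within `tie_tol`) go to the
#' model with fewer parameters, so extra parameters must buy a real
#' improvement in fit.
#'
#' @param curves As in [fit_global_two_site()].
#' @param candidates Character vector of candidate models.
#' @param n_starts Multi-start count passed to the fitter.
#' @param tie_tol AICc difference treated as a tie. Default 1e-6.
#' @return A list of class `kb_model_selection`: `chosen` (model name),
#'   `scores` (tibble with `model`, `n_par`, `rss`, `aicc`,
#'   `delta_aicc`), `fits` (named list of `kb_fit`).
#' @export
select_model <- function(curves,
                         candidates = c("equal_kd", "distinct_kd",
                                        "cooperative"),
                         n_starts = 3, tie_tol = 1e-6) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  fits <- lapply(candidates, function(m) {
    fit_global_two_site(curves, model = m, n_starts = n_starts)
  })
  names(fits) <- candidates
  # Floor the RSS at the square of a tiny fraction of the data scale:
  # below that, differences between candidates are numerical noise, the
  # log-RSS term of AICc would amplify them arbitrarily, and the penalty
  # term (fewer parameters) should decide instead. Irrelevant whenever
  # residuals carry real measurement noise.
  n_obs <- fits[[1]]$n_obs
  rss_floor <- n_obs * (1e-7 * stats::sd(curves$anisotropy))^2
  scores <- tibble::tibble(
    model = candidates,
    n_par = vapply(fits, function(f) f$n_par, integer(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aicc = vapply(fits, function(f) {
      aicc_from_rss(max(f$rss, rss_floor), f$n_obs, f$n_par)
    }, numeric(1))
  )
  scores$delta_aicc <- scores$aicc - min(scores$aicc)
  near <- which(scores$delta_aicc <= tie_tol)
  chosen <- scores$model[near[which.min(scores$n_par[near])]]
  structure(list(chosen = chosen, scores = scores, fits = fits),
            class = "kb_model_selection")
}

#' @export
print.kb_model_selection <- function(x, ...) {
  cat("<kb_model_selection> chosen:", x$chosen, "\n")
  print(x$scores)
  invisible(x)
}

#' Aggregate per-replicate fits into mean and SEM per parameter
#'
#' Replicate experiments are fit independently and then summarized:
#' for each parameter the arithmetic mean and the standard error of the
#' mean (sample SD with n-1 denominator over sqrt(n)) across replicates,
#' matching the mean +/- SEM convention for reported Kd values.
#'
#' @param fits A list of `kb_fit` objects (>= 2), or a data frame with
#'   columns `term` and `estimate` (one row per replicate and term).
#' @return A tibble with `term`, `mean`, `sem`, `n_replicates`.
#' @export
aggregate_replicates <- function(fits) {
  if (is.data.frame(fits)) {
    est <- tibble::as_tibble(fits)
  } else {
    if (base::length(fits) < 2) {
      abort("need at least 2 replicate fits to aggregate.",
            class = "kb_input_error")
    }
    est <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
      dplyr::mutate(tidy(fits[[i]]), replicate = i)
    }))
  }
  stopifnot(all(c("term", "estimate") %in% names(est)))
  agg <- est |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      sem = sd(.data$estimate) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  # per-curve nuisance terms (amplitude.<id>, baseline.<id>) appear once
  # per replicate under distinct ids and cannot be averaged across
  # replicates; keep only terms observed in >= 2 replicates
  agg <- agg[agg$n_replicates >= 2, ]
  if (!nrow(agg)) {
    abort("no term has >= 2 replicate estimates.", class = "kb_input_error")
  }
  agg
}

#' Two-sample comparison of fitted Kd values
#'
#' Two-tailed Welch t-test on per-replicate Kd estimates (the mean +/- SEM
#' reporting style implies per-replicate values), with a permutation test
#' available as a distribution-free cross-check. Exactly identical groups
#' return p = 1 directly, since the t statistic is undefined at zero
#' pooled variance.
#'
#' @param kds_a,kds_b Numeric vectors of per-replicate estimates (>= 2
#'   each).
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm Permutation count. Default 10000.
#' @param seed Optional seed for the permutation draw.
#' @return A one-row tibble: `mean_a`, `mean_b`, `statistic`, `p_value`,
#'   `method`.
#' @export
compare_groups <- function(kds_a, kds_b,
                           method = c("welch", "permutation"),
                           n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  if (base::length(kds_a) < 2 || base::length(kds_b) < 2) {
    abort("each group needs at least 2 values.", class = "kb_input_error")
  }
  out <- tibble::tibble(mean_a = mean(kds_a), mean_b = mean(kds_b),
                        statistic = NA_real_, p_value = NA_real_,
                        method = method)
  all_equal <- isTRUE(all.equal(rep(mean(c(kds_a, kds_b)),
                                    base::length(c(kds_a, kds_b))),
                                c(kds_a, kds_b)))
  if (all_equal) {
    out$p_value <- 1
    out$statistic <- 0
    return(out)
  }
  if (method == "welch") {
    tt <- t.test(kds_a, kds_b, var.equal = FALSE)
    out$statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
  } else {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    pooled <- c(kds_a, kds_b)
    na <- base::length(kds_a)
    obs <- abs(mean(kds_a) - mean(kds_b))
    hits <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(base::length(pooled), na)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-15
    }, logical(1))
    out$statistic <- obs
    out$p_value <- (1 + sum(hits)) / (n_perm + 1)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
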