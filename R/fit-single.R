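# Internal constructor for fitted-model objects.
new_kb_fit <- function(params, model, rss, converged, n_obs, n_par,
                       data, fitted, extra = list()) {
  structure(
    c(list(params = params, model = model, rss = rss,
           converged = converged, n_obs = n_obs, n_par = n_par,
           data = data, fitted = fitted), extra),
    class = "kb_fit"
  )
}

#' @export
print.kb_fit <- function(x, ...) {
  cat(sprintf("<kb_fit> model: %s (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  n = %d points, RSS = %.4g\n", x$n_obs, x$rss))
  main <- x$params[!grepl("^(amplitude|baseline)", x$params$term), ]
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %s = %.4g +/- %.3g\n", main$term[i], main$estimate[i],
                main$std_error[i]))
  }
  invisible(x)
}

run_lm_multistart <- function(residual_fn, starts,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-10, ptol = 1e-10, maxiter = 500)) {
  best <- NULL
  for (par0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = residual_fn, control = control),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("all optimizer starts failed.", class = "kb_numeric_error")
  best
}

lm_std_errors <- function(fit) {
  dof <- max(base::length(fit$fvec) - base::length(fit$par), 1L)
  sigma2 <- fit$deviance / dof
  se <- tryCatch({
    cv <- sigma2 * solve(fit$hessian)
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) rep(NA_real_, base::length(fit$par)))
  se
}

default_kd_starts <- function(conc, n_starts) {
  pos <- conc[conc > 0]
  if (!base::length(pos)) pos <- 1
  exp(seq(log(min(pos) / 10), log(max(pos) * 10), length.out = n_starts))
}

#' Fit a single-site binding isotherm to a titration curve
#'
#' Least-squares estimation of Kd, amplitude and baseline from one
#' anisotropy titration. The `"quadratic"` isotherm accounts for ligand
#' depletion (labeled DNA comparable to Kd, the specific-hairpin regime);
#' the `"hyperbolic"` isotherm assumes free ~ total protein (the weak
#' nonspecific regime). Kd is optimized on the log scale from `n_starts`
#' log-spaced initial values spanning the concentration range, so the fit
#' cannot leave the positive axis and is robust to the starting guess.
#'
#' @param curve Data frame with columns `conc_nM` and `anisotropy`
#'   (>= 5 points); an optional `d_total` column or attribute supplies the
#'   labeled-DNA concentration.
#' @param isotherm `"quadratic"` (default) or `"hyperbolic"`.
#' @param d_total Labeled DNA concentration, nM. Default: `d_total` column
#'   if present, else 5 nM.
#' @param n_starts Number of multi-start Kd initial values. Default 5.
#' @return A `kb_fit` object; use [tidy()] / [glance()] to extract the
#'   parameter table and fit statistics. `converged` is `FALSE` when the
#'   optimizer failed or the amplitude is indistinguishable from zero
#'   (flat curve: Kd unidentifiable).
#' @examples
#' p <- binding_params(kd1 = 2.2, amplitude = 0.1, baseline = 0.05)
#' curve <- generate_titration(p, d_total = 5,
#'                             noise = noise_model(sigma = 0, n_replicates = 1))
#' tidy(fit_single_site(curve))
#' @export
fit_single_site <- function(curve, isotherm = c("quadratic", "hyperbolic"),
                            d_total = NULL, n_starts = 5) {
  isotherm <- match.arg(isotherm)
  stopifnot(is.data.frame(curve),
            all(c("conc_nM", "anisotropy") %in% names(curve)))
  x <- curve$conc_nM
  y <- curve$anisotropy
  if (base::length(x) < 5) abort("a titration needs at least 5 points.")
  if (any(x < 0)) abort("concentrations must be nonnegative.")
  if (is.null(d_total)) {
    d_total <- if ("d_total" %in% names(curve)) curve$d_total[1] else 5
  }

  frac_fn <- if (isotherm == "quadratic") {
    function(kd) single_site_complex(x, d_total, kd) / d_total
  } else {
    function(kd) hyperbolic_fraction(x, kd)
  }
  residual_fn <- function(par) {
    kd <- exp(par[1])
    y - (par[3] + par[2] * frac_fn(kd))
  }
  amp0 <- max(y) - min(y)
  base0 <- min(y)
  starts <- lapply(default_kd_starts(x, n_starts), function(kd0) {
    c(log(kd0), amp0, base0)
  })
  fit <- run_lm_multistart(residual_fn, starts)
  se <- lm_std_errors(fit)
  kd <- exp(fit$par[1])
  params <- tibble::tibble(
    term = c("kd", "amplitude", "baseline"),
    estimate = c(kd, fit$par[2], fit$par[3]),
    std_error = c(kd * se[1], se[2], se[3])
  )
  amp_ok <- is.finite(se[2]) && fit$par[2] > 2 * se[2]
  converged <- fit$info %in% 1:4 && amp_ok
  fitted <- y - fit$fvec
  new_kb_fit(params, paste0("single_", isotherm), fit$deviance, converged,
             base::length(y), 3L, tibble::as_tibble(curve), fitted,
             extra = list(isotherm = isotherm, d_total = d_total))
}
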