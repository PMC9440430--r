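#' Tidy a fitted binding model
#'
#' @param x A `kb_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`.
#' @exportS3Method generics::tidy
tidy.kb_fit <- function(x, ...) {
  x$params
}

#' One-row fit summary of a binding model
#'
#' @param x A `kb_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `rss`, `sigma` (residual SD), `aicc`,
#'   `n_obs`, `n_par`, `converged`.
#' @exportS3Method generics::glance
glance.kb_fit <- function(x, ...) {
  dof <- max(x$n_obs - x$n_par, 1L)
  tibble::tibble(
    model = x$model, rss = x$rss, sigma = sqrt(x$rss / dof),
    aicc = aicc_from_rss(x$rss, x$n_obs, x$n_par),
    n_obs = x$n_obs, n_par = x$n_par, converged = x$converged
  )
}

#' Augment titration data with fitted values and residuals
#'
#' @param x A `kb_fit`.
#' @param ... Unused.
#' @return The fit's data with `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.kb_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted,
                .resid = x$data$anisotropy - x$fitted)
}

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a Guinier fit
#'
#' @param x A `guinier_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`rg`, `i0`).
#' @exportS3Method generics::tidy
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "i0"),
                 estimate = c(x$rg, x$i0),
                 std_error = c(x$rg_se, x$i0_se))
}

#' One-row summary of a Guinier fit
#'
#' @param x A `guinier_fit`.
#' @param ... Unused.
#' @return Tibble with `rg`, `i0`, `q_min`, `q_max`, `q_max_rg`,
#'   `n_points`, `r_squared`.
#' @exportS3Method generics::glance
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, i0 = x$i0, q_min = x$q_min, q_max = x$q_max,
                 q_max_rg = x$q_max * x$rg, n_points = x$n_points,
                 r_squared = x$r_squared)
}
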