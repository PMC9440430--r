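#' Plot a fitted titration curve
#'
#' Data points with the fitted isotherm overlaid, protein concentration on
#' a log axis (zero points shown at the axis minimum).
#'
#' @param object A `kb_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kb_fit <- function(object, ...) {
  df <- augment(object)
  pos <- df$conc_nM[df$conc_nM > 0]
  floor_x <- if (base::length(pos)) min(pos) / 3 else 0.01
  df$conc_plot <- pmax(df$conc_nM, floor_x)
  if (!"label" %in% names(df)) df$label <- "curve"
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df$curve <- interaction(df$label, df$replicate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_plot,
                                   colour = .data$label)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$anisotropy)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted,
                                    group = .data$curve)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (nM)", y = "anisotropy",
                  colour = "label",
                  title = paste("model:", object$model))
}

#' Plot predicted EMSA species distributions
#'
#' Band fractions (probability of n bound dimers) against total protein,
#' one line per stoichiometry, faceted by construct when several are
#' present.
#'
#' @param object A `species_distribution` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.species_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$n <- factor(df$n)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$p_total,
                                        y = .data$probability,
                                        colour = .data$n,
                                        group = .data$n)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "total protein (nM)", y = "fraction of DNA",
                  colour = "dimers bound")
  if (base::length(unique(df$construct)) > 1) {
    p <- p + ggplot2::facet_wrap(~construct)
  }
  p
}

#' Guinier plot with the fitted window
#'
#' `ln I` against `q^2` for the fitted points, with the Guinier line.
#'
#' @param object A `guinier_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.guinier_fit <- function(object, ...) {
  df <- object$window
  df$q2 <- df$q^2
  df$lnI <- log(df$intensity)
  slope <- -object$rg^2 / 3
  inter <- log(object$i0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q2, y = .data$lnI)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = slope, intercept = inter,
                         colour = "steelblue") +
    ggplot2::labs(x = expression(q^2 ~ (ring(A)^-2)), y = "ln I(q)",
                  title = sprintf("Guinier: Rg = %.1f A", object$rg))
}

#' Kratky plot of one or more profiles
#'
#' @param profiles Named list of profiles (or a single profile).
#' @return A ggplot of `q^2 I(q)` vs `q`.
#' @export
plot_kratky <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  df <- dplyr::bind_rows(lapply(names(profiles), function(nm) {
    dplyr::mutate(kratky(profiles[[nm]]), profile = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$kratky,
                                   colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression(q^2 * I(q)))
}
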