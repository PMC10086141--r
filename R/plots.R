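# ggplot2 visualisations: forest plots for estimator suites and grids,
# instrument scatter with fitted IVW/Egger lines, leave-one-out forest.

#' Forest plot of an estimator suite
#'
#' @param object An `mr_analysis`.
#' @param exponentiate Plot odds ratios (default) or log-scale effects.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_analysis <- function(object, exponentiate = TRUE, ...) {
  est <- dplyr::filter(object$estimates, .data$method != "egger_intercept")
  if (exponentiate) {
    est <- dplyr::mutate(est, mid = .data$or, lo = .data$or_low,
                         hi = .data$or_high)
    xlab <- "Odds ratio (95% CI)"
    refline <- 1
  } else {
    est <- dplyr::mutate(est, mid = .data$b, lo = .data$ci_low,
                         hi = .data$ci_high)
    xlab <- "Effect (log odds, 95% CI)"
    refline <- 0
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$mid, y = .data$method)) +
    ggplot2::geom_vline(xintercept = refline, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of a grid's headline estimates
#'
#' @param object An `mr_grid`.
#' @param ... Unused.
#' @return A ggplot faceted by outcome.
#' @export
autoplot.mr_grid <- function(object, ...) {
  fam <- dplyr::filter(object$family, .data$status == "ok")
  fam <- dplyr::mutate(fam, or = exp(.data$b))
  ggplot2::ggplot(fam, ggplot2::aes(x = .data$or, y = .data$exposure,
                                    colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome)) +
    ggplot2::labs(x = "Headline IVW odds ratio", y = NULL,
                  colour = "FDR class") +
    ggplot2::theme_minimal()
}

#' Scatter plot of instruments with fitted causal slopes
#'
#' SNP-outcome against SNP-exposure effects with error bars and the IVW
#' (through the origin) and MR-Egger (with intercept) fits.
#'
#' @param dat Harmonized panel.
#' @return A ggplot.
#' @export
plot_mr_scatter <- function(dat) {
  dat <- tibble::as_tibble(dat)
  s <- ifelse(dat$beta_x < 0, -1, 1)
  dat <- dplyr::mutate(dat, bx = s * .data$beta_x, by = s * .data$beta_y)
  ivw <- mr_ivw(dat, "mre")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_y,
                                        ymax = .data$by + .data$se_y),
                           width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$se_x,
                                         xmax = .data$bx + .data$se_x),
                            height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$b, colour = "steelblue") +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (nrow(dat) >= 3) {
    eg <- mr_egger(dat)
    p <- p + ggplot2::geom_abline(
      intercept = eg$b[eg$method == "egger_intercept"],
      slope = eg$b[eg$method == "egger_slope"], colour = "firebrick",
      linetype = "dashed"
    )
  }
  p
}

#' Leave-one-out forest plot
#'
#' @param loo Tibble from [mr_leave_one_out()].
#' @return A ggplot.
#' @export
plot_leave_one_out <- function(loo) {
  loo <- dplyr::mutate(loo, snp = factor(.data$snp,
                                         levels = rev(unique(.data$snp))))
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$b, y = .data$snp,
                                    colour = .data$influential)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "IVW estimate omitting SNP (95% CI)", y = NULL,
                  colour = "influential") +
    ggplot2::theme_minimal()
}
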