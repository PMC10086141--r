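# Two-step mediation decomposition: indirect effect by the product of
# coefficients, Sobel's test, and the proportion mediated on the log-odds
# scale.

#' Two-step MR mediation decomposition
#'
#' Combines the univariable exposure-to-mediator effect (`beta1`) with the
#' multivariable-MR conditional effects of the mediator (`beta2`) and the
#' exposure (`beta3`, the direct effect) on the outcome:
#' indirect = `beta1 * beta2`, total = `beta3 + beta1 * beta2`, proportion
#' mediated = indirect / total (log-odds scale). The Sobel standard error
#' uses the first-order delta form
#' `sqrt(beta2^2 se1^2 + beta1^2 se2^2)` (no `se1^2 se2^2` term), giving
#' `z = indirect / se_indirect` with a two-sided normal p-value.
#'
#' @param beta1,se1 Exposure-to-mediator effect and SE (univariable IVW).
#' @param beta2,se2 Mediator-to-outcome effect adjusted for the exposure
#'   (MVMR) and SE.
#' @param beta3,se3 Direct exposure-to-outcome effect adjusted for the
#'   mediator (MVMR) and SE.
#' @return Object of class `mediation_decomposition`; [tidy()] returns a
#'   one-row tibble with log-scale and odds-ratio-scale renderings.
#' @export
two_step_mediation <- function(beta1, se1, beta2, se2, beta3, se3) {
  stopifnot(is.finite(beta1), is.finite(beta2), is.finite(beta3),
            se1 > 0, se2 > 0, se3 > 0)
  indirect <- beta1 * beta2
  total <- beta3 + indirect
  se_indirect <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  se_total <- sqrt(se3^2 + se_indirect^2)  # cross-sample independence assumed
  prop <- proportion_mediated(indirect, beta3)
  sobel_z <- if (se_indirect > 0) indirect / se_indirect else 0
  structure(list(
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    beta3 = beta3, se3 = se3,
    indirect = indirect, se_indirect = se_indirect,
    direct = beta3, total = total, se_total = se_total,
    proportion_mediated = prop,
    sobel_z = sobel_z, sobel_p = p_normal(sobel_z, 1),
    k_mediators = 1L
  ), class = "mediation_decomposition")
}

#' Proportion mediated (E%)
#'
#' Aggregates one or more indirect paths: `sum(indirects) /
#' (beta3 + sum(indirects))`, the ratio of the summed log-odds indirect
#' effects to the total effect. Returns `NA` with a warning when the
#' denominator is zero.
#'
#' @param indirects Numeric vector of per-mediator indirect effects
#'   (`beta1_k * beta2_k`).
#' @param beta3 Direct effect.
#' @return Fraction of the total effect that is mediated.
#' @export
proportion_mediated <- function(indirects, beta3) {
  total <- beta3 + sum(indirects)
  if (total == 0) {
    rlang::warn("total effect is zero; proportion mediated undefined")
    return(NA_real_)
  }
  sum(indirects) / total
}

#' @export
print.mediation_decomposition <- function(x, ...) {
  cat("<mediation_decomposition>\n")
  cat(sprintf("  indirect  = %.4f (OR %.2f, 95%% CI %.2f-%.2f)\n",
              x$indirect, exp(x$indirect),
              exp(x$indirect - 1.96 * x$se_indirect),
              exp(x$indirect + 1.96 * x$se_indirect)))
  cat(sprintf("  direct    = %.4f (OR %.2f)\n", x$direct, exp(x$direct)))
  cat(sprintf("  total     = %.4f (OR %.2f)\n", x$total, exp(x$total)))
  cat(sprintf("  proportion mediated = %s\n",
              ifelse(is.na(x$proportion_mediated), "undefined",
                     sprintf("%.1f%%", 100 * x$proportion_mediated))))
  cat(sprintf("  Sobel z = %.2f, p = %.3g\n", x$sobel_z, x$sobel_p))
  invisible(x)
}

#' @export
tidy.mediation_decomposition <- function(x, ...) {
  tibble::tibble(
    beta1 = x$beta1, se1 = x$se1, beta2 = x$beta2, se2 = x$se2,
    beta3 = x$beta3, se3 = x$se3,
    indirect = x$indirect, se_indirect = x$se_indirect,
    direct = x$direct, total = x$total, se_total = x$se_total,
    or_indirect = exp(x$indirect),
    or_indirect_low = exp(x$indirect - .z95 * x$se_indirect),
    or_indirect_high = exp(x$indirect + .z95 * x$se_indirect),
    or_direct = exp(x$direct),
    or_direct_low = exp(x$direct - .z95 * x$se3),
    or_direct_high = exp(x$direct + .z95 * x$se3),
    or_total = exp(x$total),
    proportion_mediated = x$proportion_mediated,
    sobel_z = x$sobel_z, sobel_p = x$sobel_p
  )
}
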