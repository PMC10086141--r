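# Multivariable MR: joint weighted regression of SNP-outcome effects on
# several SNP-exposure effect vectors, giving conditional (direct) effects.

#' Assemble a multivariable MR panel from two instrument sets
#'
#' Takes the union of the exposure and mediator instrument lists, looks up
#' each SNP's association with all three traits in the full summary sets,
#' harmonizes everything to the exposure's effect-allele frame, and
#' re-clumps the union (ordered by the smaller of the exposure and mediator
#' p-values) so retained SNPs are mutually independent — an assumption of
#' the weighted normal equations. SNPs missing any of the three associations
#' are dropped with an audit reason.
#'
#' @param exposure_iv,mediator_iv Post-clumping instrument tibbles.
#' @param exposure_full,mediator_full,outcome Full summary-statistics tibbles
#'   supplying cross-trait effects at every instrument.
#' @param ld,r2_max,window_kb Clumping parameters, as in
#'   [clump_instruments()].
#' @inheritParams align_pair
#' @return Harmonized panel with `beta_x`, `se_x`, `beta_m`, `se_m`,
#'   `beta_y`, `se_y`; audit as attribute `audit`.
#' @export
assemble_mvmr_panel <- function(exposure_iv, mediator_iv, exposure_full,
                                mediator_full, outcome, ld = NULL,
                                r2_max = 0.01, window_kb = 5000,
                                freq_band = 0.45, resolve_palindromes = TRUE) {
  ids <- union(exposure_iv$snp, mediator_iv$snp)
  ex <- exposure_full[match(ids, exposure_full$snp), , drop = FALSE]
  missing_ex <- ids[is.na(ex$snp)]
  ex <- ex[!is.na(ex$snp), , drop = FALSE]
  if (nrow(ex) == 0L) {
    mrm_abort("no union SNPs found in the exposure summary set",
              "mrm_analysis_error")
  }
  panel <- harmonise(ex, outcome, mediator = mediator_full,
                     freq_band = freq_band,
                     resolve_palindromes = resolve_palindromes)
  audit <- harmonization_audit(panel)
  if (length(missing_ex)) {
    audit <- dplyr::bind_rows(
      audit,
      tibble::tibble(snp = missing_ex, action = "excluded",
                     reason = "missing in exposure", eaf_x = NA_real_,
                     eaf_y = NA_real_, note = NA_character_)
    )
  }
  # re-clump the union on the instrument's own source p-value
  panel$pval <- pmin(panel$pval_x, panel$pval_m, na.rm = TRUE)
  kept <- clump_instruments(panel, ld = ld, r2_max = r2_max,
                            window_kb = window_kb)
  dropped <- setdiff(panel$snp, kept$snp)
  if (length(dropped)) {
    audit$action[audit$snp %in% dropped] <- "excluded"
    audit$reason[audit$snp %in% dropped] <- "removed by union re-clumping"
  }
  kept$pval <- NULL
  if (nrow(kept) < 3L) {
    mrm_abort("fewer than 3 SNPs survive MVMR panel assembly",
              "mrm_analysis_error")
  }
  attr(kept, "audit") <- audit
  kept
}

#' Multivariable IVW regression
#'
#' Weighted (`1/se_y^2`) regression of `beta_y` on the SNP-exposure effect
#' columns with no intercept. Standard errors come from the weighted normal
#' equations with the multiplicative dispersion factor `max(1, residual sd)`
#' (no underdispersion benefit). Columns that are identically zero are
#' dropped (their coefficient is reported as `NA`), which makes the
#' reduction to univariable IVW exact; genuinely collinear designs raise an
#' error carrying the condition number.
#'
#' @param panel Panel from [assemble_mvmr_panel()] (or any tibble with the
#'   required columns).
#' @param exposures Suffixes of the effect columns forming the design,
#'   default `c("x", "m")` for `beta_x` + `beta_m`.
#' @param labels Human-readable exposure labels (defaults to the suffixes).
#' @return Object of class `mvmr_fit`; [tidy()] returns per-exposure
#'   conditional effects, [glance()] the fit summary.
#' @export
mvmr_ivw <- function(panel, exposures = c("x", "m"), labels = exposures) {
  panel <- tibble::as_tibble(panel)
  cols <- paste0("beta_", exposures)
  if (!all(c(cols, "beta_y", "se_y") %in% names(panel))) {
    mrm_abort(paste0("mvmr_ivw requires columns ",
                     paste(c(cols, "beta_y", "se_y"), collapse = ", ")),
              "mrm_usage_error")
  }
  X <- as.matrix(panel[cols])
  colnames(X) <- labels
  y <- panel$beta_y
  w <- 1 / panel$se_y^2
  n <- nrow(X)

  zero <- apply(X, 2, function(v) all(v == 0))
  if (any(zero)) {
    rlang::inform(paste0("dropping all-zero exposure column(s): ",
                         paste(labels[zero], collapse = ", ")))
  }
  Xk <- X[, !zero, drop = FALSE]
  k <- ncol(Xk)
  if (k == 0L) mrm_abort("all exposure columns are zero", "mrm_input_error")
  if (n < k + 1L) {
    mrm_abort("MVMR needs at least one more SNP than exposures",
              "mrm_insufficient_instruments")
  }
  Xw <- sqrt(w) * Xk
  cn <- kappa(Xw, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8) {
    mrm_abort(sprintf(
      "singular or near-singular MVMR design (condition number %.3g): exposure effect vectors are collinear",
      cn), "mrm_numerical_error")
  }
  xtwx <- crossprod(Xw)
  xtwy <- crossprod(Xk, w * y)
  coef <- drop(solve(xtwx, xtwy))
  r <- y - drop(Xk %*% coef)
  sigma <- sqrt(sum(w * r^2) / (n - k))
  scale <- max(1, sigma)
  se <- sqrt(diag(solve(xtwx))) * scale

  b_full <- se_full <- rep(NA_real_, ncol(X))
  b_full[!zero] <- coef
  se_full[!zero] <- se
  est <- tibble::tibble(
    exposure = labels, n_snp = n, b = b_full, se = se_full,
    ci_low = b_full - .z95 * se_full, ci_high = b_full + .z95 * se_full,
    pval = p_normal(b_full, se_full),
    or = exp(b_full), or_low = exp(b_full - .z95 * se_full),
    or_high = exp(b_full + .z95 * se_full)
  )
  structure(list(estimates = est, n_snp = n, sigma = sigma,
                 condition_number = cn, dropped = labels[zero]),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("<mvmr_fit> %d SNPs, residual sd %.3f\n", x$n_snp, x$sigma))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.mvmr_fit <- function(x, ...) x$estimates

#' @export
glance.mvmr_fit <- function(x, ...) {
  tibble::tibble(n_snp = x$n_snp, sigma = x$sigma,
                 condition_number = x$condition_number)
}
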