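# Univariable MR estimator suite: Wald ratio, IVW (fixed / multiplicative
# random effects), MR-Egger, weighted median, weighted mode, Cochran's Q,
# I2-GX, leave-one-out. All estimators consume a harmonized panel (columns
# beta_x, se_x, beta_y, se_y) and return one row per estimate in a common
# layout; confidence intervals are normal-theory (beta +/- 1.96 * se).

.z95 <- 1.96

new_mr_estimate <- function(method, b, se, n_snp, df = NULL) {
  pval <- if (is.null(df)) p_normal(b, se) else 2 * stats::pt(-abs(b / se), df = df)
  tibble::tibble(
    method = method, n_snp = n_snp, b = b, se = se,
    ci_low = b - .z95 * se, ci_high = b + .z95 * se, pval = pval,
    or = exp(b), or_low = exp(b - .z95 * se), or_high = exp(b + .z95 * se)
  )
}

.check_panel <- function(dat, min_snp, what, hint = NULL) {
  need <- c("beta_x", "beta_y", "se_y")
  if (!all(need %in% names(dat))) {
    mrm_abort(paste0(what, " requires columns ", paste(need, collapse = ", ")),
              "mrm_usage_error")
  }
  if (nrow(dat) < min_snp) {
    mrm_abort(paste0(what, " needs at least ", min_snp, " instruments",
                     if (!is.null(hint)) paste0("; ", hint)),
              "mrm_insufficient_instruments")
  }
  invisible(dat)
}

#' Wald ratio (single-instrument) estimate
#'
#' `beta_y / beta_x` with first-order delta-method standard error
#' `|se_y / beta_x|`; the degenerate case every multi-SNP estimator reduces
#' to.
#'
#' @param dat One-row harmonized panel.
#' @return One-row estimate tibble.
#' @export
mr_wald_ratio <- function(dat) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 1, "wald ratio")
  if (nrow(dat) != 1L) {
    mrm_abort("wald ratio is a single-instrument estimator", "mrm_usage_error")
  }
  if (dat$beta_x == 0) {
    mrm_abort("degenerate instrument: beta_x = 0", "mrm_input_error")
  }
  new_mr_estimate("wald_ratio", dat$beta_y / dat$beta_x,
                  abs(dat$se_y / dat$beta_x), 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of `beta_y` on `beta_x` through the origin with
#' weights `1/se_y^2` (equivalently the inverse-variance-weighted average of
#' Wald ratios with weights `beta_x^2/se_y^2`). The fixed-effects (`fe`) and
#' multiplicative-random-effects (`mre`) models share the point estimate;
#' `mre` scales the standard error by `max(1, sqrt(Q/(n-1)))`, so it never
#' benefits from underdispersion.
#'
#' @param dat Harmonized panel (>= 2 SNPs).
#' @param mode `"mre"` (default) or `"fe"`.
#' @return One-row estimate tibble; Cochran's Q is attached as attribute
#'   `q`.
#' @export
mr_ivw <- function(dat, mode = c("mre", "fe")) {
  mode <- match.arg(mode)
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 2, "ivw", hint = "use mr_wald_ratio() for a single SNP")
  w <- 1 / dat$se_y^2
  sxx <- sum(w * dat$beta_x^2)
  b <- sum(w * dat$beta_x * dat$beta_y) / sxx
  se_fe <- sqrt(1 / sxx)
  q <- sum(w * (dat$beta_y - b * dat$beta_x)^2)
  se <- if (mode == "mre") se_fe * max(1, sqrt(q / (nrow(dat) - 1))) else se_fe
  out <- new_mr_estimate(paste0("ivw_", mode), b, se, nrow(dat))
  attr(out, "q") <- q
  out
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta_ref)^2` with `w_j = beta_x^2/se_y^2`,
#' compared to a chi-square with `n_snp - 1` degrees of freedom. The
#' between-SNP heterogeneity flag fires at p < 0.1.
#'
#' @param dat Harmonized panel (>= 2 SNPs).
#' @param beta_ref Reference slope; defaults to the IVW point estimate.
#' @return One-row tibble `q`, `df`, `p_q`, `heterogeneity`.
#' @export
mr_cochran_q <- function(dat, beta_ref = NULL) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 2, "cochran_q")
  if (is.null(beta_ref)) beta_ref <- mr_ivw(dat, "fe")$b
  w <- dat$beta_x^2 / dat$se_y^2
  q <- sum(w * (dat$beta_y / dat$beta_x - beta_ref)^2)
  df <- nrow(dat) - 1L
  p <- stats::pchisq(q, df = df, lower.tail = FALSE)
  tibble::tibble(q = q, df = df, p_q = p, heterogeneity = p < 0.1)
}

#' I2-GX regression-dilution statistic
#'
#' Quantifies attenuation of the MR-Egger slope from measurement error in
#' the SNP-exposure estimates: the I-squared of the `beta_x` values weighted
#' by `1/se_x^2`, as a percentage (floored at 0). Values near 100 indicate
#' dilution does not materially affect the Egger analysis.
#'
#' @param dat Harmonized panel with `se_x`.
#' @return I2-GX in percent.
#' @export
i2_gx <- function(dat) {
  dat <- tibble::as_tibble(dat)
  w <- 1 / dat$se_x^2
  bbar <- sum(w * abs(dat$beta_x)) / sum(w)
  q_gx <- sum(w * (abs(dat$beta_x) - bbar)^2)
  max(0, (q_gx - (nrow(dat) - 1)) / q_gx) * 100
}

#' MR-Egger regression
#'
#' Weighted (`1/se_y^2`) regression of `beta_y` on `beta_x` with an
#' intercept, after orienting every instrument to `beta_x >= 0`. A non-zero
#' intercept indicates directional horizontal pleiotropy (tested at p < 0.05
#' downstream). Standard errors carry the multiplicative dispersion factor
#' `max(1, residual sd)`; p-values use the t distribution with `n - 2`
#' degrees of freedom (regression convention); confidence intervals remain
#' normal-theory.
#'
#' @param dat Harmonized panel (>= 3 SNPs, with `se_x` for I2-GX).
#' @return Two-row estimate tibble (`egger_slope`, `egger_intercept`) with
#'   attributes `i2_gx` and `sigma` (residual sd).
#' @export
mr_egger <- function(dat) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 3, "mr_egger")
  s <- ifelse(dat$beta_x < 0, -1, 1)
  bx <- s * dat$beta_x
  by <- s * dat$beta_y
  w <- 1 / dat$se_y^2
  n <- length(bx)
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0 || !is.finite(det)) {
    mrm_abort("degenerate design in MR-Egger (no spread in beta_x)",
              "mrm_numerical_error")
  }
  a <- (swxx * swy - swx * swxy) / det   # intercept
  b <- (sw * swxy - swx * swy) / det     # slope
  r <- by - a - b * bx
  sigma <- sqrt(sum(w * r^2) / (n - 2))
  scale <- max(1, sigma)
  se_a <- sqrt(swxx / det) * scale
  se_b <- sqrt(sw / det) * scale
  out <- dplyr::bind_rows(
    new_mr_estimate("egger_slope", b, se_b, n, df = n - 2),
    new_mr_estimate("egger_intercept", a, se_a, n, df = n - 2)
  )
  attr(out, "i2_gx") <- if ("se_x" %in% names(dat)) i2_gx(dat) else NA_real_
  attr(out, "sigma") <- sigma
  out
}

# weighted-median point estimate: linear interpolation of the weighted
# empirical CDF (standardised cumulative weight (cum - w/2)/sum) at 0.5
.wmedian <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- (cumsum(w) - w / 2)
  if (length(r) == 1L) return(r)
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# weighted-mode point estimate: argmax of the weight-normalised Gaussian
# kernel density of the ratio estimates over a 512-point grid
.wmode <- function(r, w, phi = 1) {
  w <- w / sum(w)
  n <- length(r)
  h <- phi * 0.9 * min(stats::sd(r), stats::mad(r)) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) h <- phi * 0.9 * stats::sd(r) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(r[1])  # all ratios identical
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, mean = r, sd = h)),
                 numeric(1))
  grid[which.max(dens)]  # first maximum = smallest value on ties
}

# parametric bootstrap SE: redraw each beta_x, beta_y from
# Normal(observed, se) and recompute the statistic
.boot_se <- function(dat, statfun, n_boot, seed) {
  n <- nrow(dat)
  withr::with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, dat$beta_x, dat$se_x)
      by <- stats::rnorm(n, dat$beta_y, dat$se_y)
      statfun(bx, by)
    }, numeric(1))
  })
  stats::sd(reps)
}

#' Weighted-median estimate
#'
#' Median of the per-SNP Wald ratios under inverse-variance weights
#' `beta_x^2/se_y^2`, by linear interpolation of the weighted empirical CDF
#' at 0.5; consistent when instruments carrying at least half the weight are
#' valid. The standard error is a seeded parametric bootstrap.
#'
#' @param dat Harmonized panel (>= 3 SNPs, with `se_x` for the bootstrap).
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Bootstrap seed.
#' @return One-row estimate tibble.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = 20230328) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 3, "weighted median")
  r <- dat$beta_y / dat$beta_x
  w <- dat$beta_x^2 / dat$se_y^2
  b <- .wmedian(r, w)
  se <- .boot_se(dat, function(bx, by) .wmedian(by / bx, bx^2 / dat$se_y^2),
                 n_boot, seed)
  new_mr_estimate("weighted_median", b, se, nrow(dat))
}

#' Weighted-mode estimate
#'
#' Mode of the weighted kernel density of the Wald ratios (bandwidth
#' `phi * 0.9 * min(sd, mad) * n^(-1/5)`); consistent when the largest group
#' of instruments sharing a causal estimate is valid. Standard error by
#' seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier, default 1.
#' @return One-row estimate tibble.
#' @export
mr_weighted_mode <- function(dat, phi = 1, n_boot = 1000, seed = 20230328) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 3, "weighted mode")
  r <- dat$beta_y / dat$beta_x
  w <- dat$beta_x^2 / dat$se_y^2
  b <- .wmode(r, w, phi)
  se <- .boot_se(dat, function(bx, by) .wmode(by / bx, bx^2 / dat$se_y^2, phi),
                 n_boot, seed)
  new_mr_estimate("weighted_mode", b, se, nrow(dat))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW (multiplicative-random-effects) estimate omitting each
#' SNP in turn, plus the all-SNP row. A SNP is flagged influential when its
#' omission flips the sign of the estimate or moves the p-value across 0.05.
#'
#' @param dat Harmonized panel (>= 3 SNPs).
#' @return Tibble with `n_snp + 1` rows: `snp` (omitted SNP or `"All"`),
#'   estimate columns, `influential`.
#' @export
mr_leave_one_out <- function(dat) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 3, "leave-one-out")
  full <- mr_ivw(dat, "mre")
  rows <- purrr::map_dfr(seq_len(nrow(dat)), function(j) {
    est <- mr_ivw(dat[-j, , drop = FALSE], "mre")
    dplyr::mutate(est, snp = dat$snp[j], .before = 1)
  })
  rows$influential <- sign(rows$b) != sign(full$b) |
    (rows$pval < 0.05) != (full$pval < 0.05)
  all_row <- dplyr::mutate(full, snp = "All", .before = 1)
  all_row$influential <- FALSE
  dplyr::bind_rows(rows, all_row)
}

#' Heterogeneity and pleiotropy diagnostics
#'
#' One-row summary in the layout of a per-analysis diagnostics table:
#' number of SNPs, summed variance explained, I2-GX, Cochran's Q with its
#' p-value and the p < 0.1 heterogeneity flag, and the MR-Egger intercept
#' with its p-value (horizontal-pleiotropy flag at p < 0.05).
#'
#' @param dat Harmonized panel (>= 3 SNPs for the Egger columns; with 2 SNPs
#'   those columns are `NA`).
#' @return One-row tibble.
#' @export
mr_heterogeneity <- function(dat) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 2, "heterogeneity diagnostics")
  cq <- mr_cochran_q(dat)
  r2 <- if ("eaf_x" %in% names(dat) && all(is.finite(dat$eaf_x))) {
    sum(2 * dat$beta_x^2 * dat$eaf_x * (1 - dat$eaf_x))
  } else NA_real_
  if (nrow(dat) >= 3) {
    eg <- mr_egger(dat)
    intercept <- eg$b[eg$method == "egger_intercept"]
    p_int <- eg$pval[eg$method == "egger_intercept"]
    i2 <- attr(eg, "i2_gx")
  } else {
    intercept <- NA_real_; p_int <- NA_real_; i2 <- NA_real_
  }
  tibble::tibble(
    n_snp = nrow(dat), r2_explained = r2, i2_gx = i2,
    q = cq$q, df = cq$df, p_q = cq$p_q, heterogeneity = cq$heterogeneity,
    egger_intercept = intercept, p_intercept = p_int,
    pleiotropy = !is.na(p_int) & p_int < 0.05
  )
}

#' Run the full univariable estimator suite on one harmonized panel
#'
#' Computes every estimator the panel size supports: Wald ratio (1 SNP), IVW
#' fixed and multiplicative-random effects (>= 2), MR-Egger slope and
#' intercept, weighted median and weighted mode (>= 3), plus heterogeneity
#' diagnostics, leave-one-out (>= 3) and MR-PRESSO (>= 4, optional).
#'
#' @param dat Harmonized panel.
#' @param n_boot,seed,phi Passed to the bootstrap estimators.
#' @param run_presso Run [mr_presso()] when the panel allows (default TRUE).
#' @param n_sim MR-PRESSO simulation count.
#' @param outlier_alpha MR-PRESSO outlier significance level.
#' @return An object of class `mr_analysis` with components `estimates`,
#'   `heterogeneity`, `loo`, `presso`, `n_snp`. [tidy()] returns the
#'   estimates, [glance()] the diagnostics row, [autoplot()] a forest plot.
#' @export
mr_analyse <- function(dat, n_boot = 1000, seed = 20230328, phi = 1,
                       run_presso = TRUE, n_sim = 1000, outlier_alpha = 0.05) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 1, "mr_analyse")
  n <- nrow(dat)
  if (n == 1L) {
    est <- mr_wald_ratio(dat)
    het <- NULL; loo <- NULL; presso <- NULL
  } else {
    est <- dplyr::bind_rows(mr_ivw(dat, "fe"), mr_ivw(dat, "mre"))
    het <- mr_heterogeneity(dat)
    loo <- NULL; presso <- NULL
    if (n >= 3) {
      est <- dplyr::bind_rows(est, mr_egger(dat),
                              mr_weighted_median(dat, n_boot, seed),
                              mr_weighted_mode(dat, phi, n_boot, seed))
      loo <- mr_leave_one_out(dat)
    }
    if (n >= 4 && isTRUE(run_presso)) {
      presso <- mr_presso(dat, n_sim = n_sim, seed = seed,
                          outlier_alpha = outlier_alpha)
    }
  }
  structure(list(estimates = est, heterogeneity = het, loo = loo,
                 presso = presso, n_snp = n),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("<mr_analysis> %d instrument(s)\n", x$n_snp))
  print(x$estimates)
  if (!is.null(x$heterogeneity)) {
    cat("\nDiagnostics:\n")
    print(x$heterogeneity)
  }
  if (!is.null(x$presso)) {
    cat(sprintf("\nMR-PRESSO global p = %.4g; %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outlier_snp_ids)))
  }
  invisible(x)
}

#' @export
tidy.mr_analysis <- function(x, ...) x$estimates

#' @export
glance.mr_analysis <- function(x, ...) {
  if (is.null(x$heterogeneity)) return(tibble::tibble(n_snp = x$n_snp))
  x$heterogeneity
}
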