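# MR-PRESSO: pleiotropy residual sum and outlier test. Detects instruments
# whose residual about the leave-one-out IVW fit is larger than expected
# under the no-pleiotropy model, via seeded parametric simulation of the
# global residual sum of squares and of per-SNP residuals.

#' MR-PRESSO global test and outlier detection
#'
#' The observed statistic is the weighted residual sum of squares
#' `sum_j (beta_y_j - b_(-j) * beta_x_j)^2 / se_y_j^2`, where `b_(-j)` is the
#' IVW slope with SNP j left out. Its null distribution comes from `n_sim`
#' parametric simulations in which each SNP's `beta_x` and `beta_y` are
#' redrawn around the observed `beta_x` and the leave-one-out fitted value
#' with the observed standard errors. The global p-value is
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`; per-SNP outlier p-values come
#' from each SNP's simulated residual distribution, Bonferroni-adjusted by
#' the number of SNPs. Detected outliers are removed and the IVW estimate is
#' recomputed (`corrected_estimate`). The distortion test is not
#' implemented.
#'
#' @param dat Harmonized panel (>= 4 SNPs with `se_x`).
#' @param n_sim Number of simulations, default 1000.
#' @param seed Simulation seed.
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier test, default 0.05.
#' @return An object of class `mr_presso`: list with `global_rss`,
#'   `global_p`, `outlier_table`, `outlier_snp_ids`, `corrected_estimate`
#'   (present iff outliers were removed), `n_sim`, `n_snp`.
#' @export
mr_presso <- function(dat, n_sim = 1000, seed = 20230328, outlier_alpha = 0.05) {
  dat <- tibble::as_tibble(dat)
  .check_panel(dat, 4, "mr_presso")
  n <- nrow(dat)
  bx <- dat$beta_x; by <- dat$beta_y
  w <- 1 / dat$se_y^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  b_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
  fitted <- b_loo * bx
  r_obs <- w * (by - fitted)^2
  rss_obs <- sum(r_obs)

  withr::with_seed(seed, {
    xs <- matrix(stats::rnorm(n * n_sim, mean = bx, sd = dat$se_x), nrow = n)
    ys <- matrix(stats::rnorm(n * n_sim, mean = fitted, sd = dat$se_y), nrow = n)
  })
  sxy_s <- colSums(w * xs * ys)
  sxx_s <- colSums(w * xs^2)
  sxy_m <- matrix(sxy_s, n, n_sim, byrow = TRUE)
  sxx_m <- matrix(sxx_s, n, n_sim, byrow = TRUE)
  bl <- (sxy_m - w * xs * ys) / (sxx_m - w * xs^2)
  rs <- w * (ys - bl * xs)^2
  rss_sim <- colSums(rs)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_out <- (1 + rowSums(rs >= r_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_out * n)
  is_out <- p_adj < outlier_alpha
  outlier_table <- tibble::tibble(snp = dat$snp, residual = r_obs,
                                  p = p_out, p_adj = p_adj, outlier = is_out)
  corrected <- NULL
  if (any(is_out) && sum(!is_out) >= 2) {
    corrected <- mr_ivw(dat[!is_out, , drop = FALSE], "mre")
    corrected$method <- "ivw_mre_outlier_corrected"
  }
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_table = outlier_table,
                 outlier_snp_ids = dat$snp[is_out],
                 corrected_estimate = corrected,
                 n_sim = n_sim, n_snp = n, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS = %.4g, p = %.4g (%d sims, %d SNPs)\n",
              x$global_rss, x$global_p, x$n_sim, x$n_snp))
  if (length(x$outlier_snp_ids)) {
    cat("outliers:", paste(x$outlier_snp_ids, collapse = ", "), "\n")
  } else {
    cat("no outliers detected\n")
  }
  invisible(x)
}

#' @export
tidy.mr_presso <- function(x, ...) x$outlier_table

#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(global_rss = x$global_rss, global_p = x$global_p,
                 n_outliers = length(x$outlier_snp_ids),
                 n_snp = x$n_snp, n_sim = x$n_sim)
}
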