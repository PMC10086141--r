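# Seeded generator of two-sample GWAS summary statistics with known causal,
# pleiotropic, and mediation structure. Summary statistics are simulated
# directly (no individual-level genotypes): closed-form standard-error
# approximations for standardized continuous traits and for binary outcomes
# on the log-odds scale suffice for calibration.

.gws_z <- function(threshold = 5e-8) stats::qnorm(1 - threshold / 2)

# per-block sub-streams derived from the master seed so the exposure,
# mediator and outcome samples are drawn independently (two-sample design)
.substream <- function(seed, k) as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)

#' Simulation configuration
#'
#' Defaults emulate a consortium-scale two-sample design with a binary
#' outcome: an exposure GWAS of 300,000, an outcome GWAS of 260,000 with a
#' 4.2% case fraction, a mediator GWAS of 50,000, 30 instruments with
#' effect-allele frequencies uniform on (0.05, 0.5), and a fifth of SNPs
#' palindromic to exercise harmonization.
#'
#' @param n_snp Number of exposure instruments.
#' @param eaf_range Effect-allele frequency range (uniform draw).
#' @param beta_x_sd Spread of true SNP-exposure effects (standardized trait
#'   units per allele); draws are truncated so every instrument passes
#'   genome-wide significance in expectation.
#' @param beta_m_sd Spread of true mediator-specific SNP effects.
#' @param n_exposure,n_outcome,n_mediator Sample sizes (>= 100).
#' @param theta True exposure-to-outcome effect (log odds per unit).
#' @param beta1,beta2,beta3 True mediation coefficients (set all three for
#'   [simulate_mediation_triplet()]).
#' @param pleiotropy_mean,pleiotropy_sd Direct SNP-to-outcome (horizontal
#'   pleiotropy) effect distribution; a non-zero mean is directional
#'   pleiotropy with InSIDE satisfied.
#' @param n_outliers Number of SNPs whose outcome effect is displaced.
#' @param outlier_shift_sds Displacement in units of the SNP's `se_y`.
#' @param case_fraction Outcome case fraction in (0, 1).
#' @param palindromic_fraction Fraction of SNPs assigned A/T or G/C alleles.
#' @param n_snp_mediator Mediator-specific instruments (triplet mode).
#' @param seed Master seed; output is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snp = 30, eaf_range = c(0.05, 0.5), beta_x_sd = 0.03,
                       beta_m_sd = 0.08, n_exposure = 3e5, n_outcome = 2.6e5,
                       n_mediator = 5e4, theta = 0.4,
                       beta1 = NULL, beta2 = NULL, beta3 = NULL,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       n_outliers = 0, outlier_shift_sds = 10,
                       case_fraction = 0.042, palindromic_fraction = 0.2,
                       n_snp_mediator = 20, seed = 1) {
  cfg <- list(n_snp = n_snp, eaf_range = eaf_range, beta_x_sd = beta_x_sd,
              beta_m_sd = beta_m_sd, n_exposure = n_exposure,
              n_outcome = n_outcome, n_mediator = n_mediator, theta = theta,
              beta1 = beta1, beta2 = beta2, beta3 = beta3,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              n_outliers = n_outliers, outlier_shift_sds = outlier_shift_sds,
              case_fraction = case_fraction,
              palindromic_fraction = palindromic_fraction,
              n_snp_mediator = n_snp_mediator, seed = seed)
  if (!(is.numeric(eaf_range) && length(eaf_range) == 2 &&
        eaf_range[1] > 0 && eaf_range[2] < 1 && eaf_range[1] < eaf_range[2])) {
    mrm_abort("eaf_range must be a non-degenerate interval within (0,1)",
              "mrm_config_error")
  }
  if (any(c(n_exposure, n_outcome, n_mediator) < 100)) {
    mrm_abort("sample sizes must be at least 100", "mrm_config_error")
  }
  if (n_outliers >= n_snp) {
    mrm_abort("n_outliers must be smaller than n_snp", "mrm_config_error")
  }
  if (case_fraction <= 0 || case_fraction >= 1) {
    mrm_abort("case_fraction must lie in (0,1)", "mrm_config_error")
  }
  structure(cfg, class = "sim_config")
}

# draw true per-allele effects from Normal(0, sd) truncated so that
# |beta| / se exceeds the genome-wide significance z in expectation
.draw_truncated <- function(n, sd, se, z = .gws_z()) {
  thr <- z * se
  b <- stats::rnorm(n, 0, sd)
  for (iter in 1:1000) {
    bad <- abs(b) < thr
    if (!any(bad)) return(b)
    b[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  mrm_abort("cannot draw genome-wide-significant effects: beta_x_sd too small for this sample size",
            "mrm_config_error")
}

# allele assignment: palindromic_fraction of SNPs get A/T or G/C pairs
.draw_alleles <- function(n, pal_fraction) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal_pairs <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pal <- stats::runif(n) < pal_fraction
  pick <- function(pairs, k) pairs[sample.int(length(pairs), k, replace = TRUE)]
  out <- vector("list", n)
  out[pal] <- pick(pal_pairs, sum(pal))
  out[!pal] <- pick(nonpal_pairs, sum(!pal))
  tibble::tibble(ea = vapply(out, `[`, character(1), 1),
                 oa = vapply(out, `[`, character(1), 2),
                 palindromic = pal)
}

# SNP positions spaced 6 Mb apart on cycling chromosomes, beyond the default
# clumping window, so independent simulated SNPs clump to themselves
.snp_map <- function(n) {
  tibble::tibble(
    snp = sprintf("rs%06d", seq_len(n)),
    chr = as.character(rep_len(1:22, n)),
    pos = (ceiling(seq_len(n) / 22)) * 6e6 + (seq_len(n) %% 22) * 1e5
  )
}

.se_continuous <- function(n_sample, eaf) 1 / sqrt(2 * n_sample * eaf * (1 - eaf))
.se_binary <- function(n_sample, cf, eaf) {
  1 / sqrt(2 * n_sample * cf * (1 - cf) * 2 * eaf * (1 - eaf))
}

.sumstat_table <- function(map, alleles, eaf, beta, se, n_sample,
                           n_cases = NA_real_) {
  tibble::tibble(
    snp = map$snp, chr = map$chr, pos = map$pos,
    ea = alleles$ea, oa = alleles$oa, eaf = eaf,
    beta = beta, se = se, pval = p_normal(beta, se),
    n = n_sample, n_cases = n_cases
  )
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates per-SNP exposure effects with sampling error and a binary
#' outcome on the log-odds scale: `beta_y = theta * beta_x_true + alpha_j`
#' with `alpha_j ~ Normal(pleiotropy_mean, pleiotropy_sd)` expressed on the
#' exposure-increasing allele orientation (horizontal pleiotropy; a non-zero
#' mean is directional and InSIDE is satisfied by construction). Exposure
#' and outcome
#' draws use independent random sub-streams (two-sample, non-overlapping
#' design). `n_outliers` SNPs get their outcome effect displaced by
#' `outlier_shift_sds * se_y`.
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure` and `outcome` summary-statistics tibbles and
#'   a `truth` tibble storing every latent value.
#' @export
simulate_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_snp
  map <- .snp_map(n)
  withr::with_seed(.substream(cfg$seed, 1), {
    alleles <- .draw_alleles(n, cfg$palindromic_fraction)
    eaf <- stats::runif(n, cfg$eaf_range[1], cfg$eaf_range[2])
    se_x <- .se_continuous(cfg$n_exposure, eaf)
    bx_true <- .draw_truncated(n, cfg$beta_x_sd, se_x)
    alpha <- stats::rnorm(n, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    outlier <- rep(FALSE, n)
    if (cfg$n_outliers > 0) outlier[sample.int(n, cfg$n_outliers)] <- TRUE
  })
  # pleiotropy acts on the exposure-increasing allele orientation, so a
  # non-zero mean is directional in the MR-Egger sense (InSIDE holds)
  by_true <- cfg$theta * bx_true + sign(bx_true) * alpha
  se_y <- .se_binary(cfg$n_outcome, cfg$case_fraction, eaf)
  withr::with_seed(.substream(cfg$seed, 2),
                   bx_obs <- stats::rnorm(n, bx_true, se_x))
  withr::with_seed(.substream(cfg$seed, 3),
                   by_obs <- stats::rnorm(n, by_true, se_y))
  by_obs <- by_obs + ifelse(outlier, cfg$outlier_shift_sds * se_y, 0)

  list(
    exposure = .sumstat_table(map, alleles, eaf, bx_obs, se_x, cfg$n_exposure),
    outcome = .sumstat_table(map, alleles, eaf, by_obs, se_y, cfg$n_outcome,
                             n_cases = round(cfg$case_fraction * cfg$n_outcome)),
    truth = tibble::tibble(
      snp = map$snp, eaf = eaf, true_beta_x = bx_true, alpha = alpha,
      true_beta_y = by_true, outlier = outlier, theta = cfg$theta
    )
  )
}

#' Simulate an exposure / mediator / outcome summary-statistics triplet
#'
#' Mediation structure with known coefficients: exposure instruments carry
#' `beta_m_true = beta1 * beta_x_true` and
#' `beta_y_true = beta3 * beta_x_true + beta2 * beta_m_true (+ pleiotropy)`;
#' mediator-specific instruments draw their own mediator effects
#' (`beta_x_true = 0`) and act on the outcome only through the mediator
#' (`beta_y_true = beta2 * beta_m_true`). All three summary sets contain
#' every SNP so cross-trait lookups always resolve. The truth record
#' includes the implied total effect `beta3 + beta1 * beta2` and the true
#' proportion mediated.
#'
#' @param cfg A [sim_config()] with `beta1`, `beta2`, `beta3` set.
#' @return List with `exposure`, `mediator`, `outcome` tibbles, a per-SNP
#'   `truth` tibble, and `params` (true coefficients, total, proportion).
#' @export
simulate_mediation_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$beta1) || is.null(cfg$beta2) || is.null(cfg$beta3)) {
    mrm_abort("mediation simulation requires beta1, beta2 and beta3",
              "mrm_config_error")
  }
  n_x <- cfg$n_snp
  n_m <- cfg$n_snp_mediator
  n <- n_x + n_m
  map <- .snp_map(n)
  is_x_iv <- seq_len(n) <= n_x

  withr::with_seed(.substream(cfg$seed, 1), {
    alleles <- .draw_alleles(n, cfg$palindromic_fraction)
    eaf <- stats::runif(n, cfg$eaf_range[1], cfg$eaf_range[2])
    se_x <- .se_continuous(cfg$n_exposure, eaf)
    se_m <- .se_continuous(cfg$n_mediator, eaf)
    bx_true <- numeric(n)
    bx_true[is_x_iv] <- .draw_truncated(n_x, cfg$beta_x_sd, se_x[is_x_iv])
    bm_own <- numeric(n)
    bm_own[!is_x_iv] <- .draw_truncated(n_m, cfg$beta_m_sd, se_m[!is_x_iv])
    alpha <- stats::rnorm(n, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
  })
  bm_true <- cfg$beta1 * bx_true + bm_own
  orient <- ifelse(is_x_iv, sign(bx_true), sign(bm_own))
  by_true <- cfg$beta3 * bx_true + cfg$beta2 * bm_true + orient * alpha
  se_y <- .se_binary(cfg$n_outcome, cfg$case_fraction, eaf)

  withr::with_seed(.substream(cfg$seed, 2),
                   bx_obs <- stats::rnorm(n, bx_true, se_x))
  withr::with_seed(.substream(cfg$seed, 4),
                   bm_obs <- stats::rnorm(n, bm_true, se_m))
  withr::with_seed(.substream(cfg$seed, 3),
                   by_obs <- stats::rnorm(n, by_true, se_y))

  indirect <- cfg$beta1 * cfg$beta2
  total <- cfg$beta3 + indirect
  list(
    exposure = .sumstat_table(map, alleles, eaf, bx_obs, se_x, cfg$n_exposure),
    mediator = .sumstat_table(map, alleles, eaf, bm_obs, se_m, cfg$n_mediator),
    outcome = .sumstat_table(map, alleles, eaf, by_obs, se_y, cfg$n_outcome,
                             n_cases = round(cfg$case_fraction * cfg$n_outcome)),
    truth = tibble::tibble(
      snp = map$snp, eaf = eaf, exposure_instrument = is_x_iv,
      true_beta_x = bx_true, true_beta_m = bm_true, true_beta_y = by_true,
      alpha = alpha
    ),
    params = list(beta1 = cfg$beta1, beta2 = cfg$beta2, beta3 = cfg$beta3,
                  indirect = indirect, total = total,
                  proportion_mediated = indirect / total)
  )
}
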