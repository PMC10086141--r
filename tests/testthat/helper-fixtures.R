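# Fixtures built in code: random summary-statistics tables and harmonized
# panels with known generating parameters.

# random valid summary-statistics records (non-palindromic alleles so that
# harmonization is unambiguous unless a test wants otherwise)
random_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    alle <- pairs[sample.int(4, n, replace = TRUE)]
    beta <- rnorm(n, 0, 0.05)
    se <- runif(n, 0.005, 0.03)
    tibble::tibble(
      snp = sprintf("rs%06d", sample.int(1e6, n)),
      chr = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(1e8, n),
      ea = vapply(alle, `[`, character(1), 1),
      oa = vapply(alle, `[`, character(1), 2),
      eaf = runif(n, 0.05, 0.95),
      beta = beta,
      se = se,
      pval = 2 * pnorm(-abs(beta / se)),
      n = 1e5,
      n_cases = NA_real_
    )
  })
}

# harmonized panel straight from generating parameters: by = a + theta*bx + e
random_panel <- function(n, theta = 0.5, seed = 1, intercept = 0,
                         pleio_sd = 0, se_x_range = c(0.002, 0.01),
                         se_y_range = c(0.01, 0.05)) {
  withr::with_seed(seed, {
    bx <- rnorm(n, 0.08, 0.03)
    bx[abs(bx) < 0.02] <- 0.02
    se_x <- runif(n, se_x_range[1], se_x_range[2])
    se_y <- runif(n, se_y_range[1], se_y_range[2])
    by <- intercept + theta * bx + rnorm(n, 0, pleio_sd) + rnorm(n, 0, se_y)
    tibble::tibble(snp = sprintf("s%03d", seq_len(n)),
                   beta_x = bx, se_x = se_x, beta_y = by, se_y = se_y)
  })
}

# turn simulated exposure/outcome tables (identical allele frames by
# construction) into a harmonized panel without the alignment machinery
panel_from_sim <- function(sim) {
  tibble::tibble(
    snp = sim$exposure$snp,
    beta_x = sim$exposure$beta, se_x = sim$exposure$se,
    eaf_x = sim$exposure$eaf,
    beta_y = sim$outcome$beta, se_y = sim$outcome$se
  )
}

# independent weighted-median oracle: explicit interpolation of the weighted
# empirical CDF, coded without approx()
wmedian_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  k <- length(r)
  if (0.5 >= s[k]) return(r[k])
  i <- max(which(s < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}
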