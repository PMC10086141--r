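test_that("wald ratio arithmetic and degenerate instrument", {
  dat <- tibble::tibble(snp = "s1", beta_x = 0.1, se_x = 0.01,
                        beta_y = 0.2, se_y = 0.05)
  est <- mr_wald_ratio(dat)
  expect_equal(est$b, 2)
  expect_equal(est$se, 0.5)
  est0 <- mr_wald_ratio(dplyr::mutate(dat, beta_y = 0))
  expect_equal(est0$b, 0)
  expect_error(mr_wald_ratio(dplyr::mutate(dat, beta_x = 0)),
               class = "mrm_input_error")
  # joint sign flip leaves the ratio unchanged
  estf <- mr_wald_ratio(dplyr::mutate(dat, beta_x = -beta_x,
                                      beta_y = -beta_y))
  expect_equal(estf$b, est$b)
})

test_that("a perfect-fit panel gives the exact slope, Q = 0 and fe = mre", {
  dat <- tibble::tibble(snp = paste0("s", 1:4), beta_x = c(0.1, 0.2, 0.3, 0.4),
                        se_x = 0.01, beta_y = 0.5 * c(0.1, 0.2, 0.3, 0.4),
                        se_y = 0.02)
  fe <- mr_ivw(dat, "fe"); mre <- mr_ivw(dat, "mre")
  expect_equal(fe$b, 0.5)
  expect_equal(attr(fe, "q"), 0, tolerance = 1e-24)
  expect_equal(mre$se, fe$se)
  cq <- mr_cochran_q(dat)
  expect_equal(cq$q, 0, tolerance = 1e-20)
  expect_equal(cq$p_q, 1)
  expect_false(cq$heterogeneity)
})

test_that("IVW matches a weighted-least-squares oracle on random panels", {
  for (seed in 1:20) {
    dat <- random_panel(sample(3:15, 1), theta = 0.4, seed = seed,
                        pleio_sd = 0.01)
    w <- 1 / dat$se_y^2
    fit <- lm(beta_y ~ 0 + beta_x, data = dat, weights = w)
    est <- mr_ivw(dat, "fe")
    expect_equal(est$b, unname(coef(fit)), tolerance = 1e-10)
    # oracle SEs via the regression machinery: strip lm's dispersion and
    # re-apply the fixed/multiplicative conventions
    sig <- summary(fit)$sigma
    se_fe_oracle <- unname(summary(fit)$coefficients[, 2]) / sig
    q_oracle <- sum(w * resid(fit)^2)
    expect_equal(est$se, se_fe_oracle, tolerance = 1e-10)
    mre <- mr_ivw(dat, "mre")
    expect_equal(mre$b, est$b)
    expect_equal(mre$se,
                 se_fe_oracle * max(1, sqrt(q_oracle / (nrow(dat) - 1))),
                 tolerance = 1e-10)
    # se(mre) exceeds se(fe) exactly when Q > df
    expect_equal(mre$se > est$se, q_oracle > nrow(dat) - 1)
  }
})

test_that("Cochran's Q matches a term-by-term brute-force sum", {
  dat <- random_panel(8, seed = 31, pleio_sd = 0.05)
  b_ref <- mr_ivw(dat, "fe")$b
  q_brute <- 0
  for (j in seq_len(nrow(dat))) {
    q_brute <- q_brute + (dat$beta_x[j]^2 / dat$se_y[j]^2) *
      (dat$beta_y[j] / dat$beta_x[j] - b_ref)^2
  }
  cq <- mr_cochran_q(dat)
  expect_equal(cq$q, q_brute, tolerance = 1e-10)
  expect_equal(cq$df, 7)
})

test_that("MR-Egger recovers an exact line and matches the WLS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  dat <- tibble::tibble(snp = paste0("s", 1:4), beta_x = bx, se_x = 0.01,
                        beta_y = 0.03 + 0.6 * bx, se_y = 0.02)
  eg <- mr_egger(dat)
  expect_equal(eg$b[eg$method == "egger_slope"], 0.6, tolerance = 1e-12)
  expect_equal(eg$b[eg$method == "egger_intercept"], 0.03, tolerance = 1e-12)

  for (seed in 1:20) {
    dat <- random_panel(sample(4:15, 1), theta = 0.3, seed = 200 + seed,
                        intercept = 0.02, pleio_sd = 0.02)
    s <- ifelse(dat$beta_x < 0, -1, 1)
    w <- 1 / dat$se_y^2
    fit <- lm(I(s * beta_y) ~ I(s * beta_x), data = dat, weights = w)
    sig <- summary(fit)$sigma
    se_oracle <- unname(summary(fit)$coefficients[, 2]) / sig * max(1, sig)
    eg <- mr_egger(dat)
    expect_equal(eg$b[eg$method == "egger_intercept"],
                 unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(eg$b[eg$method == "egger_slope"],
                 unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$se, se_oracle[c(2, 1)], tolerance = 1e-10)
  }
})

test_that("I2-GX approaches 100% when exposure effects are measured exactly", {
  dat <- random_panel(10, seed = 40)
  dat$se_x <- 1e-6
  expect_gt(i2_gx(dat), 99.9)
})

test_that("weighted median reduces to the plain median under equal weights", {
  dat <- tibble::tibble(snp = paste0("s", 1:3),
                        beta_x = 1, se_x = 0.01,
                        beta_y = c(1, 2, 9), se_y = 1)
  est <- mr_weighted_median(dat, n_boot = 50, seed = 1)
  expect_equal(est$b, 2)
  # odd-n equal weights generally
  dat5 <- tibble::tibble(snp = paste0("s", 1:5), beta_x = 1, se_x = 0.01,
                         beta_y = c(3, 1, 4, 1.5, 9), se_y = 1)
  expect_equal(mr_weighted_median(dat5, n_boot = 50, seed = 1)$b,
               median(dat5$beta_y))
})

test_that("a dominant-weight SNP pins the weighted median near its ratio", {
  dat <- tibble::tibble(snp = paste0("s", 1:5),
                        beta_x = c(1, 1, 1, 1, 1),
                        se_x = 0.01,
                        beta_y = c(0.9, 2, 3, 4, 5),
                        se_y = c(0.05, 1, 1, 1, 1))  # SNP 1 carries ~99% weight
  est <- mr_weighted_median(dat, n_boot = 50, seed = 1)
  expect_equal(est$b, 0.9, tolerance = 0.05)
})

test_that("weighted median matches the brute-force CDF-interpolation oracle", {
  for (seed in 1:25) {
    dat <- random_panel(sample(3:20, 1), seed = 300 + seed, pleio_sd = 0.05)
    r <- dat$beta_y / dat$beta_x
    w <- dat$beta_x^2 / dat$se_y^2
    est <- mr_weighted_median(dat, n_boot = 2, seed = 1)
    expect_lt(abs(est$b - wmedian_oracle(r, w)),
              1e-12 * max(1, abs(est$b)))
  }
})

test_that("weighted mode: degenerate cluster, planted mode, weight scaling", {
  dat <- tibble::tibble(snp = paste0("s", 1:4), beta_x = c(0.1, 0.2, 0.4, 0.8),
                        se_x = 0.01, beta_y = 0.7 * c(0.1, 0.2, 0.4, 0.8),
                        se_y = 0.05)
  est <- mr_weighted_mode(dat, n_boot = 20, seed = 1)
  expect_equal(est$b, 0.7, tolerance = 1e-9)  # all ratios identical

  withr::with_seed(50, {
    bx <- runif(9, 0.1, 0.3)
    ratios <- c(rnorm(7, 0.5, 0.03), rnorm(2, 3, 0.03))
  })
  dat2 <- tibble::tibble(snp = paste0("s", 1:9), beta_x = bx, se_x = 0.01,
                         beta_y = ratios * bx, se_y = 0.05)
  est2 <- mr_weighted_mode(dat2, n_boot = 20, seed = 1)
  expect_equal(est2$b, 0.5, tolerance = 0.2)

  # halving all outcome SEs rescales every weight by 4: same estimate
  dat3 <- dplyr::mutate(dat2, se_y = se_y / 2)
  est3 <- mr_weighted_mode(dat3, n_boot = 20, seed = 1)
  expect_equal(est3$b, est2$b)
})

test_that("estimators are equivariant to joint sign flips and reordering", {
  dat <- random_panel(10, seed = 60, pleio_sd = 0.02)
  flip <- rep(c(1, -1), 5)
  dat_f <- dplyr::mutate(dat, beta_x = flip * beta_x, beta_y = flip * beta_y)
  dat_r <- dat[c(7, 3, 1, 10, 2, 9, 4, 8, 5, 6), ]
  for (variant in list(dat_f, dat_r)) {
    expect_equal(mr_ivw(variant, "fe")$b, mr_ivw(dat, "fe")$b,
                 tolerance = 1e-12)
    expect_equal(mr_ivw(variant, "mre")$se, mr_ivw(dat, "mre")$se,
                 tolerance = 1e-12)
    expect_equal(mr_egger(variant)$b, mr_egger(dat)$b, tolerance = 1e-12)
    expect_equal(mr_weighted_median(variant, n_boot = 2, seed = 1)$b,
                 mr_weighted_median(dat, n_boot = 2, seed = 1)$b,
                 tolerance = 1e-12)
    expect_equal(mr_weighted_mode(variant, n_boot = 2, seed = 1)$b,
                 mr_weighted_mode(dat, n_boot = 2, seed = 1)$b,
                 tolerance = 1e-12)
  }
})

test_that("leave-one-out has n+1 rows, flags nothing on homogeneous panels", {
  dat <- random_panel(8, seed = 70)
  loo <- mr_leave_one_out(dat)
  expect_equal(nrow(loo), 9)
  expect_equal(loo$snp[9], "All")
  expect_false(any(loo$influential))
})

test_that("omitting a dominant-weight SNP moves the estimate the most", {
  dat <- random_panel(6, seed = 71)
  dat$se_y[1] <- dat$se_y[1] / 50       # SNP 1 dominates the weights
  dat$beta_y[1] <- dat$beta_x[1] * 2    # and disagrees with the rest
  loo <- mr_leave_one_out(dat)
  full_b <- loo$b[loo$snp == "All"]
  deltas <- abs(loo$b[loo$snp != "All"] - full_b)
  expect_equal(which.max(deltas), 1L)
})

test_that("insufficient panels raise directed errors", {
  one <- random_panel(1, seed = 80)
  expect_error(mr_ivw(one), "wald", class = "mrm_insufficient_instruments")
  two <- random_panel(2, seed = 81)
  expect_error(mr_egger(two), class = "mrm_insufficient_instruments")
  expect_error(mr_weighted_median(two), class = "mrm_insufficient_instruments")
  expect_error(mr_presso(random_panel(3, seed = 82)),
               class = "mrm_insufficient_instruments")
})

test_that("mr_analyse bundles the suite and its tidiers work", {
  dat <- random_panel(8, seed = 90)
  ana <- mr_analyse(dat, n_boot = 30, n_sim = 100)
  expect_s3_class(ana, "mr_analysis")
  expect_setequal(ana$estimates$method,
                  c("ivw_fe", "ivw_mre", "egger_slope", "egger_intercept",
                    "weighted_median", "weighted_mode"))
  expect_identical(tidy(ana), ana$estimates)
  expect_equal(glance(ana)$n_snp, 8)
  expect_s3_class(autoplot(ana), "ggplot")
  expect_s3_class(plot_mr_scatter(dat), "ggplot")
  expect_s3_class(plot_leave_one_out(ana$loo), "ggplot")
})
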