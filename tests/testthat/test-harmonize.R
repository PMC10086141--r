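mk_rec <- function(snp = "rs1", ea, oa, beta, se = 0.05, eaf = NA_real_) {
  tibble::tibble(snp = snp, chr = "1", pos = 1e6, ea = ea, oa = oa,
                 eaf = eaf, beta = beta, se = se,
                 pval = 2 * pnorm(-abs(beta / se)), n = 1e5,
                 n_cases = NA_real_)
}

test_that("swapped alleles flip the outcome effect sign", {
  h <- align_pair(mk_rec(ea = "A", oa = "G", beta = 0.1, eaf = 0.3),
                  mk_rec(ea = "G", oa = "A", beta = 0.2, eaf = 0.68))
  expect_equal(h$beta_y, -0.2)
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$eaf_y, 1 - 0.68)
})

test_that("strand complements align without a sign change", {
  h <- align_pair(mk_rec(ea = "A", oa = "G", beta = 0.1, eaf = 0.3),
                  mk_rec(ea = "T", oa = "C", beta = 0.2, eaf = 0.31))
  expect_equal(h$beta_y, 0.2)
  expect_equal(h$action, "strand_flipped")
})

test_that("complemented-and-swapped alleles flip the sign", {
  h <- align_pair(mk_rec(ea = "A", oa = "G", beta = 0.1, eaf = 0.3),
                  mk_rec(ea = "C", oa = "T", beta = 0.2, eaf = 0.7))
  expect_equal(h$beta_y, -0.2)
  expect_equal(h$eaf_y, 0.3)
})

test_that("irreconcilable alleles are excluded", {
  h <- align_pair(mk_rec(ea = "A", oa = "G", beta = 0.1),
                  mk_rec(ea = "A", oa = "C", beta = 0.2))
  expect_equal(h$action, "excluded")
  expect_equal(h$reason, "allele mismatch")
})

test_that("palindromes with discordant frequencies are strand-flipped", {
  # enumeration oracle: of the four orientations of an A/T pair with
  # eaf_x = 0.30, only the strand-flipped one makes frequencies concord
  h <- align_pair(mk_rec(ea = "A", oa = "T", beta = 0.1, eaf = 0.30),
                  mk_rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.70))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$beta_y, -0.2)
  expect_equal(h$eaf_y, 0.30)
})

test_that("palindromes with concordant frequencies are kept as-is", {
  h <- align_pair(mk_rec(ea = "A", oa = "T", beta = 0.1, eaf = 0.30),
                  mk_rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.28))
  expect_equal(h$action, "kept")
  expect_equal(h$beta_y, 0.2)
})

test_that("ambiguous palindromes (MAF above the 45% band) are excluded", {
  h <- align_pair(mk_rec(ea = "A", oa = "T", beta = 0.1, eaf = 0.47),
                  mk_rec(ea = "T", oa = "A", beta = 0.2, eaf = 0.30))
  expect_equal(h$action, "excluded")
  expect_equal(h$reason, "ambiguous palindrome")
})

test_that("palindromes without frequency are conservatively excluded", {
  h <- align_pair(mk_rec(ea = "C", oa = "G", beta = 0.1),
                  mk_rec(ea = "C", oa = "G", beta = 0.2, eaf = 0.3))
  expect_equal(h$reason, "palindrome without frequency")
})

test_that("the drop policy excludes every palindrome regardless of frequency", {
  h <- align_pair(mk_rec(ea = "A", oa = "T", beta = 0.1, eaf = 0.2),
                  mk_rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.2),
                  resolve_palindromes = FALSE)
  expect_equal(h$action, "excluded")
  expect_match(h$reason, "drop policy")
})

test_that("dataset harmonization intersects, audits and preserves order", {
  ex <- validate_sumstats(random_records(5, seed = 20))
  out <- ex
  out$beta <- rnorm(5)
  h <- harmonise(ex, out)
  expect_equal(nrow(h), 5)
  expect_equal(h$snp, ex$snp)
  expect_true(all(harmonization_audit(h)$action == "kept"))

  h2 <- harmonise(ex, out[-2, ])
  audit <- harmonization_audit(h2)
  expect_equal(audit$reason[audit$snp == ex$snp[2]], "missing in outcome")
  expect_equal(nrow(h2), 4)
})

test_that("empty intersection is an analysis error", {
  ex <- validate_sumstats(random_records(3, seed = 21))
  out <- validate_sumstats(random_records(3, seed = 22))
  expect_error(harmonise(ex, out), "no overlapping",
               class = "mrm_analysis_error")
})

test_that("harmonization is involution-safe", {
  ex <- validate_sumstats(random_records(8, seed = 23))
  out <- ex
  out$beta <- rnorm(8, 0, 0.1)
  h1 <- harmonise(ex, out)
  # feed the harmonized frame back in as exposure/outcome tables
  ex2 <- ex
  out2 <- dplyr::mutate(ex, beta = h1$beta_y, se = h1$se_y, eaf = h1$eaf_y)
  h2 <- harmonise(ex2, out2)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_true(all(harmonization_audit(h2)$action == "kept"))
})

test_that("estimates are invariant under random allele relabeling of the outcome", {
  # the key correctness property: flipping (ea, oa, beta sign, eaf) of the
  # outcome must not change the causal estimate
  for (seed in 1:5) {
    ex <- validate_sumstats(random_records(12, seed = 100 + seed))
    out <- ex
    withr::with_seed(seed, {
      out$beta <- 0.5 * ex$beta + rnorm(12, 0, 0.02)
      flip <- runif(12) < 0.5
      comp <- c(A = "T", T = "A", C = "G", G = "C")
      strand <- runif(12) < 0.5
    })
    scrambled <- out
    scrambled$ea[flip] <- out$oa[flip]
    scrambled$oa[flip] <- out$ea[flip]
    scrambled$beta[flip] <- -out$beta[flip]
    scrambled$eaf[flip] <- 1 - out$eaf[flip]
    scrambled$ea[strand] <- comp[scrambled$ea[strand]]
    scrambled$oa[strand] <- comp[scrambled$oa[strand]]

    est_ref <- mr_ivw(harmonise(ex, out), "fe")
    est_scr <- mr_ivw(harmonise(ex, scrambled), "fe")
    expect_equal(est_scr$b, est_ref$b, tolerance = 1e-12)
    expect_equal(est_scr$se, est_ref$se, tolerance = 1e-12)
  }
})

test_that("align_pair refuses mismatched snp ids", {
  expect_error(align_pair(mk_rec(snp = "rs1", ea = "A", oa = "G", beta = 1),
                          mk_rec(snp = "rs2", ea = "A", oa = "G", beta = 1)),
               class = "mrm_usage_error")
})
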