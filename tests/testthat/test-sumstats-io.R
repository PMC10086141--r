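test_that("well-formed tables validate with no rejects and row order kept", {
  x <- random_records(3, seed = 42)
  out <- validate_sumstats(x)
  expect_equal(nrow(out), 3)
  expect_equal(nrow(sumstat_rejects(out)), 0)
  expect_equal(out$snp, x$snp)
})

test_that("invalid rows are routed to the reject report with reasons", {
  x <- random_records(5, seed = 1)
  x$se[2] <- 0
  x$ea[3] <- "AT"           # indel-like allele
  x$oa[4] <- x$ea[4]        # identical alleles
  x$eaf[5] <- 1.2
  out <- validate_sumstats(x)
  rej <- sumstat_rejects(out)
  expect_equal(nrow(out), 1)
  expect_equal(nrow(rej), 4)
  expect_match(rej$reason[rej$snp == x$snp[2]], "nonpositive SE")
  expect_match(rej$reason[rej$snp == x$snp[3]], "invalid effect allele")
  expect_match(rej$reason[rej$snp == x$snp[4]], "identical alleles")
  expect_match(rej$reason[rej$snp == x$snp[5]], "EAF outside")
})

test_that("missing p-values are recomputed as two-sided normal p", {
  x <- random_records(4, seed = 2)
  x$pval[2] <- NA
  out <- validate_sumstats(x)
  expect_equal(out$pval[2], 2 * pnorm(-abs(x$beta[2] / x$se[2])))
})

test_that("p-values inconsistent with beta/se warn but are kept", {
  x <- random_records(3, seed = 3)
  x$pval[1] <- min(1, x$pval[1] * 10)
  expect_warning(out <- validate_sumstats(x), "inconsistent")
  expect_equal(nrow(out), 3)
})

test_that("write-read round-trip reproduces records field by field", {
  for (seed in 1:5) {
    x <- random_records(20, seed = seed)
    x$eaf[1] <- NA  # optional fields survive the trip
    x <- validate_sumstats(x)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_sumstats(x, path)
    y <- read_sumstats(path)
    expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 0)
  }
})

test_that("write-read-write is byte-identical and empty input writes header only", {
  x <- validate_sumstats(random_records(10, seed = 9))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, p1)
  write_sumstats(read_sumstats(p1), p2)
  expect_identical(readLines(p1), readLines(p2))

  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x[0, ], p3)
  expect_length(readLines(p3), 1L)
  expect_equal(strsplit(readLines(p3), "\t")[[1]], sumstat_columns())
})

test_that("column mapping resolves arbitrary source headers", {
  x <- random_records(3, seed = 4)
  names(x) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE", "P",
                "N", "NCASE")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(x, path)
  y <- read_sumstats(path, column_map = c(snp = "SNP", chr = "CHR",
                                          pos = "BP", ea = "A1", oa = "A2",
                                          eaf = "FRQ", beta = "BETA",
                                          se = "SE", pval = "P"))
  expect_equal(nrow(y), 3)
  expect_equal(y$beta, x$BETA)
})

test_that("a missing required column is a configuration error naming it", {
  x <- random_records(3, seed = 5)
  x$se <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(x, path)
  expect_error(read_sumstats(path), "se", class = "mrm_config_error")
})

test_that("LD lookup is symmetric, reflexive, and defaults configurable", {
  ld <- ld_table(tibble::tibble(snp_a = "s1", snp_b = "s2", r2 = 0.5))
  expect_equal(ld_r2(ld, "s2", "s1"), 0.5)
  expect_equal(ld_r2(ld, "s1", "s2"), 0.5)
  expect_equal(ld_r2(ld, "s1", "s1"), 1)
  expect_equal(ld_r2(ld, "s1", "s9"), 0)
  ld2 <- ld_table(default_r2 = 0.3)
  expect_equal(ld_r2(ld2, "a", "b"), 0.3)
  expect_equal(ld_r2(NULL, "a", "b"), 0)
})

test_that("LD r2 outside [0,1] is an input error", {
  expect_error(ld_table(tibble::tibble(snp_a = "a", snp_b = "b", r2 = 1.4)),
               class = "mrm_input_error")
})
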