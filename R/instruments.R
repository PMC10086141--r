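# Instrument selection: genome-wide significance filter, greedy LD clumping,
# and instrument-strength statistics (F, R-squared explained).

#' Filter to genome-wide-significant SNPs
#'
#' Retains rows with `pval` strictly below the threshold (a SNP at exactly
#' the threshold is excluded), preserving input order.
#'
#' @param x Summary-statistics tibble.
#' @param threshold Significance threshold, default `5e-8`.
#' @return Filtered tibble in input order.
#' @export
filter_genomewide <- function(x, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  dplyr::filter(tibble::as_tibble(x), .data$pval < threshold)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the lowest-p unclaimed SNP as an index and removes every
#' unclaimed SNP on the same chromosome within `window_kb` kilobases whose
#' r-squared with the index exceeds `r2_max` (both conditions must hold to
#' exclude). Ties on p are broken by (chr, pos, snp) so the result does not
#' depend on input order. Indices are returned sorted by p ascending.
#'
#' With no LD table, absent pairs take the table default (0), so clumping
#' degrades to keeping everything; supply an `ld_table` built with a positive
#' `default_r2` for distance-only clumping.
#'
#' @param x Summary-statistics tibble with `chr`, `pos`, `pval`.
#' @param ld An [ld_table()] or `NULL`.
#' @param r2_max Exclusion threshold on r-squared (exclusive), default 0.01.
#' @param window_kb Window in kilobases (inclusive bound), default 5000.
#' @return Tibble of retained index SNPs, sorted by p.
#' @export
clump_instruments <- function(x, ld = NULL, r2_max = 0.01, window_kb = 5000) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0L) return(x)
  if (any(!is.finite(x$pos)) || any(is.na(x$chr))) {
    mrm_abort("clumping requires chr and pos on every record", "mrm_input_error")
  }
  window_bp <- window_kb * 1000
  remaining <- x[order(x$pval, x$chr, x$pos, x$snp), , drop = FALSE]
  kept <- remaining[0, , drop = FALSE]
  while (nrow(remaining) > 0L) {
    idx <- remaining[1L, , drop = FALSE]
    kept <- dplyr::bind_rows(kept, idx)
    near <- remaining$chr == idx$chr &
      abs(remaining$pos - idx$pos) <= window_bp
    r2 <- ld_r2(ld, idx$snp, remaining$snp)
    remaining <- remaining[!(near & r2 > r2_max), , drop = FALSE]
  }
  kept
}

#' Instrument-strength statistics
#'
#' Per-SNP F-statistic `(beta/se)^2` and variance explained
#' `2 * beta^2 * eaf * (1 - eaf)` (absent when `eaf` is missing), with the
#' conventional weak-instrument flag at F < 10. Panel-level totals (minimum
#' and mean F, summed R-squared) are attached as the `totals` attribute and
#' retrievable with [instrument_strength_totals()].
#'
#' @param x Summary-statistics tibble.
#' @return Tibble with columns `snp`, `f_stat`, `r2_explained`, `weak`.
#' @export
instrument_strength <- function(x) {
  x <- tibble::as_tibble(x)
  out <- tibble::tibble(
    snp = x$snp,
    f_stat = (x$beta / x$se)^2,
    r2_explained = ifelse(is.finite(x$eaf),
                          2 * x$beta^2 * x$eaf * (1 - x$eaf), NA_real_),
    weak = (x$beta / x$se)^2 < 10
  )
  attr(out, "totals") <- tibble::tibble(
    n_snp = nrow(out),
    f_min = suppressWarnings(min(out$f_stat)),
    f_mean = mean(out$f_stat),
    r2_total = if (all(is.finite(out$r2_explained))) sum(out$r2_explained) else NA_real_,
    n_weak = sum(out$weak)
  )
  out
}

#' @rdname instrument_strength
#' @param strength A tibble returned by [instrument_strength()].
#' @export
instrument_strength_totals <- function(strength) {
  attr(strength, "totals")
}
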