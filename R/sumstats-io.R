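# GWAS summary-statistics I/O and validation.
#
# A summary-statistics table carries one row per SNP with the canonical
# columns below. Only biallelic single-nucleotide variants are accepted:
# palindrome logic and strand flipping are undefined for indels.

#' Canonical summary-statistics columns
#'
#' Column order and names used by [read_sumstats()] and [write_sumstats()]:
#' `snp`, `chr`, `pos`, `ea` (effect allele), `oa` (other allele), `eaf`
#' (effect-allele frequency), `beta`, `se`, `pval`, `n`, `n_cases`.
#' Required: `snp`, `ea`, `oa`, `beta`, `se`; the rest are optional.
#'
#' @return Character vector of canonical column names.
#' @export
sumstat_columns <- function() {
  c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n", "n_cases")
}

.required_cols <- c("snp", "ea", "oa", "beta", "se")
.bases <- c("A", "C", "G", "T")

#' Validate a summary-statistics table
#'
#' Every input row ends up in exactly one of two places: the returned
#' (accepted) tibble or the reject report attached as `attr(x, "rejects")`,
#' which names the reason for each rejection. Missing p-values are recomputed
#' from `beta`/`se` as two-sided normal p-values (they are needed downstream
#' to order clumping). A p-value that disagrees with the normal p of
#' `beta/se` by more than a factor of two raises a warning but is kept.
#'
#' @param x A data frame with (a subset of) the canonical columns.
#' @param recompute_pval Recompute absent p-values from `beta`/`se`?
#' @return A tibble of accepted rows (canonical columns, original order)
#'   with a `rejects` attribute holding the rejected rows and their reasons.
#' @export
validate_sumstats <- function(x, recompute_pval = TRUE) {
  x <- tibble::as_tibble(x)
  for (col in setdiff(sumstat_columns(), names(x))) x[[col]] <- NA
  x <- x[sumstat_columns()]

  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  x$ea <- toupper(as.character(x$ea))
  x$oa <- toupper(as.character(x$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_cases")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }

  reasons <- vector("list", nrow(x))
  add_reason <- function(bad, why) {
    for (i in which(bad)) reasons[[i]] <<- c(reasons[[i]], why)
  }

  add_reason(is.na(x$snp) | x$snp == "", "missing snp id")
  add_reason(is.na(x$ea) | !(x$ea %in% .bases), "invalid effect allele")
  add_reason(is.na(x$oa) | !(x$oa %in% .bases), "invalid other allele")
  add_reason(!is.na(x$ea) & !is.na(x$oa) & x$ea == x$oa, "identical alleles")
  add_reason(!is.finite(x$beta), "missing beta")
  add_reason(!is.finite(x$se) | x$se <= 0, "nonpositive SE")
  add_reason(is.finite(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "EAF outside (0,1)")
  add_reason(is.finite(x$pval) & (x$pval <= 0 | x$pval > 1), "p-value outside (0,1]")

  bad <- !vapply(reasons, is.null, logical(1))
  rejects <- x[bad, , drop = FALSE]
  rejects$reason <- vapply(reasons[bad], paste, character(1), collapse = "; ")
  accepted <- x[!bad, , drop = FALSE]

  # consistency check: printed p vs normal p of beta/se (warning only)
  have_p <- is.finite(accepted$pval)
  if (any(have_p)) {
    pn <- p_normal(accepted$beta[have_p], accepted$se[have_p])
    ratio <- accepted$pval[have_p] / pmax(pn, .Machine$double.xmin)
    off <- is.finite(ratio) & (ratio > 2 | ratio < 0.5) & pn > 1e-300
    if (any(off)) {
      rlang::warn(sprintf(
        "%d row(s) have p-values inconsistent with beta/se beyond a factor of 2",
        sum(off)
      ))
    }
  }
  if (recompute_pval) {
    miss <- !is.finite(accepted$pval)
    accepted$pval[miss] <- p_normal(accepted$beta[miss], accepted$se[miss])
  }

  attr(accepted, "rejects") <- tibble::as_tibble(rejects)
  accepted
}

#' Reject report of a validated summary-statistics table
#'
#' @param x A tibble returned by [validate_sumstats()] or [read_sumstats()].
#' @return Tibble of rejected rows with a `reason` column.
#' @export
sumstat_rejects <- function(x) {
  rej <- attr(x, "rejects")
  if (is.null(rej)) rej <- tibble::tibble()
  rej
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table with a header row, renames source
#' columns to the canonical names via `column_map`, validates every row
#' ([validate_sumstats()]) and returns the accepted rows in file order.
#'
#' @param path File path.
#' @param column_map Named character vector mapping canonical names to source
#'   headers, e.g. `c(snp = "SNP", beta = "b", se = "SE")`. Canonical headers
#'   need no mapping.
#' @param delim Field delimiter; autodetected (tab vs comma) when `NULL`.
#' @inheritParams validate_sumstats
#' @return Tibble of accepted records with a `rejects` attribute.
#' @export
read_sumstats <- function(path, column_map = NULL, delim = NULL,
                          recompute_pval = TRUE) {
  if (!file.exists(path)) mrm_abort(paste0("file not found: ", path), "mrm_io_error")
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      mrm_abort(paste0("column_map refers to absent column(s): ",
                       paste(missing_src, collapse = ", ")), "mrm_config_error")
    }
    raw <- dplyr::rename(raw, !!!setNames(unname(column_map), names(column_map)))
  }
  absent <- setdiff(.required_cols, names(raw))
  if (length(absent)) {
    mrm_abort(paste0("required column(s) missing: ",
                     paste(absent, collapse = ", ")), "mrm_config_error")
  }
  out <- validate_sumstats(raw[intersect(sumstat_columns(), names(raw))],
                           recompute_pval = recompute_pval)
  if (nrow(out) == 0L) mrm_abort("no valid summary-statistics rows", "mrm_input_error")
  out
}

#' Write GWAS summary statistics to a canonical TSV
#'
#' Writes the canonical columns tab-delimited with full double precision
#' (shortest round-trip representation), so `read_sumstats(write_sumstats(x))`
#' reproduces `x` exactly and a write-read-write cycle is byte-identical.
#'
#' @param x Summary-statistics tibble (validated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  x <- tibble::as_tibble(x)
  for (col in setdiff(sumstat_columns(), names(x))) x[[col]] <- NA
  readr::write_tsv(x[sumstat_columns()], path, progress = FALSE)
  invisible(path)
}

# ---- pairwise LD lookup -----------------------------------------------------

#' Pairwise LD lookup table
#'
#' Builds a symmetric r-squared lookup from a table of SNP pairs. Queries of a
#' SNP with itself return 1; absent pairs return `default_r2` (0 by default:
#' treat unknown pairs as independent, which degrades clumping to the
#' distance-only rule when no LD panel is available).
#'
#' @param pairs Data frame with columns `snp_a`, `snp_b`, `r2`, or `NULL`.
#' @param default_r2 r-squared returned for pairs absent from the table.
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(pairs = NULL, default_r2 = 0) {
  stopifnot(is.numeric(default_r2), default_r2 >= 0, default_r2 <= 1)
  r2 <- numeric(0)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pairs <- tibble::as_tibble(pairs)
    need <- c("snp_a", "snp_b", "r2")
    if (!all(need %in% names(pairs))) {
      mrm_abort("LD table needs columns snp_a, snp_b, r2", "mrm_config_error")
    }
    pairs$r2 <- as.numeric(pairs$r2)
    if (any(!is.finite(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)) {
      mrm_abort("LD r2 values must lie in [0, 1]", "mrm_input_error")
    }
    key <- .ld_key(pairs$snp_a, pairs$snp_b)
    r2 <- pairs$r2[!duplicated(key)]
    names(r2) <- key[!duplicated(key)]
  }
  structure(list(r2 = r2, default_r2 = default_r2), class = "ld_table")
}

.ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read a pairwise LD table
#'
#' @param path Path to a 3-column delimited table (`snp_a`, `snp_b`, `r2`).
#' @inheritParams ld_table
#' @return An `ld_table`.
#' @export
read_ld <- function(path, default_r2 = 0) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  pairs <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  ld_table(pairs, default_r2 = default_r2)
}

#' Query pairwise LD
#'
#' Symmetric lookup: `ld_r2(ld, a, b)` equals `ld_r2(ld, b, a)`; the r2 of a
#' SNP with itself is 1; absent pairs return the table's configured default.
#' Vectorised over `a`/`b`. A `NULL` lookup behaves as an empty table with
#' default 0.
#'
#' @param ld An `ld_table` or `NULL`.
#' @param a,b SNP identifiers (recycled to common length).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) ld <- ld_table()
  stopifnot(inherits(ld, "ld_table"))
  k <- max(length(a), length(b))
  a <- rep_len(as.character(a), k)
  b <- rep_len(as.character(b), k)
  out <- rep_len(ld$default_r2, k)
  hit <- match(.ld_key(a, b), names(ld$r2))
  out[!is.na(hit)] <- ld$r2[hit[!is.na(hit)]]
  out[a == b] <- 1
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("<ld_table> %d pair(s), default r2 = %g\n",
              length(x$r2), x$default_r2))
  invisible(x)
}
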