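# Effect-allele harmonization: place exposure (and mediator) and outcome
# effects on a common effect-allele frame; resolve or exclude palindromic
# SNPs using allele frequencies.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) .complement[ea] == oa

# Align one outcome-side record (beta/se/eaf + alleles) to the exposure's
# effect-allele frame. Returns list(beta, se, eaf, action, reason, note,
# palindromic). `action` is one of kept / sign_flipped / strand_flipped /
# excluded.
.align_one <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, beta_y, se_y, eaf_y,
                       freq_band = 0.45, resolve_palindromes = TRUE) {
  res <- list(beta = NA_real_, se = NA_real_, eaf = NA_real_,
              action = "excluded", reason = NA_character_, note = NA_character_,
              palindromic = isTRUE(unname(is_palindromic(ea_x, oa_x))))
  fail <- function(reason) { res$reason <- reason; res }

  if (is.na(ea_y) || is.na(oa_y)) return(fail("missing alleles"))

  if (res$palindromic) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) return(fail("allele mismatch"))
    if (!resolve_palindromes) return(fail("palindromic SNP (drop policy)"))
    if (!is.finite(eaf_x) || !is.finite(eaf_y)) {
      return(fail("palindrome without frequency"))
    }
    if (min(eaf_x, 1 - eaf_x) > freq_band || min(eaf_y, 1 - eaf_y) > freq_band) {
      return(fail("ambiguous palindrome"))
    }
    swapped <- ea_y != ea_x
    if (swapped) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
    if ((eaf_x < 0.5) == (eaf_y < 0.5)) {
      res$action <- if (swapped) "sign_flipped" else "kept"
    } else {
      # frequencies discordant on this labelling: the reported strand is the
      # other one; flip the outcome to make frequencies concord
      beta_y <- -beta_y; eaf_y <- 1 - eaf_y
      res$action <- "strand_flipped"
    }
    res$beta <- beta_y; res$se <- se_y; res$eaf <- eaf_y
    return(res)
  }

  if (ea_y == ea_x && oa_y == oa_x) {
    res$action <- "kept"
  } else if (ea_y == oa_x && oa_y == ea_x) {
    beta_y <- -beta_y
    if (is.finite(eaf_y)) eaf_y <- 1 - eaf_y
    res$action <- "sign_flipped"
  } else if (unname(.complement[ea_y]) == ea_x && unname(.complement[oa_y]) == oa_x) {
    res$action <- "strand_flipped"
  } else if (unname(.complement[ea_y]) == oa_x && unname(.complement[oa_y]) == ea_x) {
    beta_y <- -beta_y
    if (is.finite(eaf_y)) eaf_y <- 1 - eaf_y
    res$action <- "sign_flipped"
    res$note <- "strand complemented and swapped"
  } else {
    return(fail("allele mismatch"))
  }
  if (is.finite(eaf_x) && is.finite(eaf_y) && abs(eaf_x - eaf_y) > 0.2) {
    res$note <- paste(stats::na.omit(c(res$note, "EAF discrepancy > 0.2")),
                      collapse = "; ")
  }
  res$beta <- beta_y; res$se <- se_y; res$eaf <- eaf_y
  res
}

#' Align one exposure/outcome SNP pair to a common effect allele
#'
#' Handles matching alleles, swapped alleles (effect sign flipped, frequency
#' complemented), strand complements, and palindromic A/T–G/C pairs, which
#' are oriented by frequency concordance or excluded when either frequency
#' lies within the ambiguity band (minor-allele frequency above `freq_band`,
#' i.e. EAF in (0.45, 0.55) at the default) or is missing.
#'
#' @param exposure,outcome Single-row summary-statistics tibbles for the same
#'   SNP.
#' @param freq_band Palindrome ambiguity band on the minor-allele frequency,
#'   default 0.45.
#' @param resolve_palindromes Resolve unambiguous palindromes by frequency
#'   (`TRUE`, default) or drop all palindromic SNPs (`FALSE`).
#' @return One-row tibble with the outcome effect on the exposure's frame:
#'   columns `snp`, `ea`, `oa`, `beta_x`, `se_x`, `eaf_x`, `beta_y`, `se_y`,
#'   `eaf_y`, `palindromic`, `action`, `reason`, `note`.
#' @export
align_pair <- function(exposure, outcome, freq_band = 0.45,
                       resolve_palindromes = TRUE) {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  stopifnot(nrow(exposure) == 1L, nrow(outcome) == 1L)
  if (!identical(exposure$snp, outcome$snp)) {
    mrm_abort("align_pair requires records for the same snp id", "mrm_usage_error")
  }
  a <- .align_one(exposure$ea, exposure$oa, exposure$eaf,
                  outcome$ea, outcome$oa, outcome$beta, outcome$se, outcome$eaf,
                  freq_band = freq_band,
                  resolve_palindromes = resolve_palindromes)
  tibble::tibble(
    snp = exposure$snp, chr = exposure$chr, pos = exposure$pos,
    ea = exposure$ea, oa = exposure$oa,
    beta_x = exposure$beta, se_x = exposure$se, eaf_x = exposure$eaf,
    pval_x = exposure$pval,
    beta_y = a$beta, se_y = a$se, eaf_y = a$eaf,
    palindromic = a$palindromic, action = a$action, reason = a$reason,
    note = a$note
  )
}

#' Harmonize exposure, outcome (and optionally mediator) summary statistics
#'
#' Intersects the exposure instrument list with the outcome (and mediator)
#' tables on `snp`, aligns every association to the exposure's effect-allele
#' frame via [align_pair()] and returns the kept instruments in exposure
#' order. Every exposure SNP appears in the audit table (attribute `audit`,
#' accessor [harmonization_audit()]) with the action taken; excluded SNPs
#' never reach the estimators.
#'
#' @param exposure Exposure instrument tibble (post-clumping).
#' @param outcome Outcome summary-statistics tibble.
#' @param mediator Optional mediator summary-statistics tibble; its effects
#'   are aligned to the same frame (columns `beta_m`, `se_m`, `eaf_m`).
#' @inheritParams align_pair
#' @return Tibble of harmonized instruments with an `audit` attribute.
#' @export
harmonise <- function(exposure, outcome, mediator = NULL, freq_band = 0.45,
                      resolve_palindromes = TRUE) {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  with_m <- !is.null(mediator)
  if (with_m) mediator <- tibble::as_tibble(mediator)

  rows <- vector("list", nrow(exposure))
  audit <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, , drop = FALSE]
    audit_row <- tibble::tibble(snp = ex$snp, action = "excluded",
                                reason = NA_character_, eaf_x = ex$eaf,
                                eaf_y = NA_real_, note = NA_character_)
    oy <- outcome[match(ex$snp, outcome$snp), , drop = FALSE]
    if (is.na(oy$snp[1])) {
      audit_row$reason <- "missing in outcome"
      audit[[i]] <- audit_row
      next
    }
    h <- align_pair(ex, oy, freq_band = freq_band,
                    resolve_palindromes = resolve_palindromes)
    audit_row$action <- h$action
    audit_row$reason <- h$reason
    audit_row$eaf_y <- h$eaf_y
    audit_row$note <- h$note
    if (h$action == "excluded") {
      audit[[i]] <- audit_row
      next
    }
    if (with_m) {
      om <- mediator[match(ex$snp, mediator$snp), , drop = FALSE]
      if (is.na(om$snp[1])) {
        audit_row$action <- "excluded"
        audit_row$reason <- "missing in mediator"
        audit[[i]] <- audit_row
        next
      }
      m <- .align_one(ex$ea, ex$oa, ex$eaf, om$ea, om$oa, om$beta, om$se,
                      om$eaf, freq_band = freq_band,
                      resolve_palindromes = resolve_palindromes)
      if (m$action == "excluded") {
        audit_row$action <- "excluded"
        audit_row$reason <- paste0("mediator: ", m$reason)
        audit[[i]] <- audit_row
        next
      }
      h$beta_m <- m$beta; h$se_m <- m$se; h$eaf_m <- m$eaf
      h$pval_m <- om$pval
    }
    audit[[i]] <- audit_row
    rows[[i]] <- h
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    mrm_abort("no overlapping instruments after harmonization",
              "mrm_analysis_error")
  }
  attr(out, "audit") <- dplyr::bind_rows(audit)
  out
}

#' Harmonization audit table
#'
#' @param x A tibble returned by [harmonise()].
#' @return Tibble with one row per exposure SNP: `snp`, `action`, `reason`,
#'   `eaf_x`, `eaf_y`, `note`.
#' @export
harmonization_audit <- function(x) attr(x, "audit")
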