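# Orchestration: run the exposure-by-outcome analysis grid, collect the
# IVW p-value family, apply Benjamini-Hochberg FDR, classify, and run the
# gated two-step mediation analysis.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()] with
#' `method = "BH"`), output aligned to input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values in input order (empty input gives an empty vector).
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    mrm_abort("p-values must lie in (0, 1]", "mrm_input_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Classify a test by p-value and q-value
#'
#' `significant` when both p and q fall below their cutoffs; `suggestive`
#' (a plausible causal relationship) when p is below its cutoff but q is
#' not; `null` otherwise.
#'
#' @param p,q Vectors of p-values and BH q-values.
#' @param p_cut,q_cut Cutoffs, both 0.05 by default.
#' @return Character vector in `{"significant", "suggestive", "null"}`.
#' @export
classify_significance <- function(p, q, p_cut = 0.05, q_cut = 0.05) {
  dplyr::case_when(
    p < p_cut & q < q_cut ~ "significant",
    p < p_cut ~ "suggestive",
    .default = "null"
  )
}

.headline_method <- function(heterogeneity_flag, headline) {
  switch(headline,
    # the published selection sentence as written: heterogeneity present ->
    # fixed effects; absent -> multiplicative random effects
    as_published = if (isTRUE(heterogeneity_flag)) "ivw_fe" else "ivw_mre",
    # the community convention is the inverse
    conventional = if (isTRUE(heterogeneity_flag)) "ivw_mre" else "ivw_fe",
    mre = "ivw_mre",
    fe = "ivw_fe"
  )
}

#' Run the exposure-by-outcome MR analysis grid
#'
#' For every exposure/outcome cell: genome-wide filter, LD clumping,
#' harmonization, the full estimator suite with diagnostics, then one
#' Benjamini-Hochberg family over the headline IVW p-values of all cells,
#' and classification. Cells with fewer than 2 surviving instruments are
#' marked `insufficient instruments` and the run continues. Deterministic
#' given its arguments (all stochastic components are seeded).
#'
#' @param exposures Named list of exposure summary-statistics tibbles.
#' @param outcomes Named list of outcome summary-statistics tibbles.
#' @param ld Optional [ld_table()] shared by all clumping steps.
#' @param p_threshold Instrument significance threshold (default 5e-8).
#' @param clump_r2,clump_window_kb Clumping parameters.
#' @param freq_band,resolve_palindromes Harmonization parameters.
#' @param headline Which IVW standard error feeds the FDR family:
#'   `"as_published"` (default) selects fixed effects when Cochran's Q has
#'   p < 0.1 and multiplicative random effects otherwise, as the source
#'   analysis states it; `"conventional"` inverts that; `"mre"`/`"fe"` force
#'   one model. The choice is recorded per cell.
#' @param n_boot,seed,phi,run_presso,n_sim Estimator-suite parameters.
#' @param p_cut,q_cut Classification cutoffs.
#' @return Object of class `mr_grid`: `estimates` (all methods, all cells),
#'   `diagnostics`, `family` (headline p, q, class per cell), `analyses`
#'   (nested `mr_analysis` objects), `thresholds`. [tidy()] returns the
#'   estimates, [glance()] the family table.
#' @export
mr_grid <- function(exposures, outcomes, ld = NULL, p_threshold = 5e-8,
                    clump_r2 = 0.01, clump_window_kb = 5000,
                    freq_band = 0.45, resolve_palindromes = TRUE,
                    headline = c("as_published", "conventional", "mre", "fe"),
                    n_boot = 1000, seed = 20230328, phi = 1,
                    run_presso = TRUE, n_sim = 1000,
                    p_cut = 0.05, q_cut = 0.05) {
  headline <- match.arg(headline)
  stopifnot(length(names(exposures)) == length(exposures),
            length(names(outcomes)) == length(outcomes))
  if (anyDuplicated(names(exposures)) || anyDuplicated(names(outcomes))) {
    mrm_abort("exposure and outcome labels must be unique", "mrm_config_error")
  }

  ivs <- purrr::map(exposures, function(ex) {
    clump_instruments(filter_genomewide(ex, p_threshold), ld = ld,
                      r2_max = clump_r2, window_kb = clump_window_kb)
  })

  analyses <- list()
  estimates <- list()
  diagnostics <- list()
  family <- list()
  for (ex_label in names(exposures)) {
    for (out_label in names(outcomes)) {
      cell <- paste(ex_label, out_label, sep = " -> ")
      iv <- ivs[[ex_label]]
      dat <- tryCatch(
        harmonise(iv, outcomes[[out_label]], freq_band = freq_band,
                  resolve_palindromes = resolve_palindromes),
        mrm_analysis_error = function(e) NULL
      )
      if (is.null(dat) || nrow(dat) < 2) {
        family[[cell]] <- tibble::tibble(
          exposure = ex_label, outcome = out_label, n_snp = if (is.null(dat)) 0L else nrow(dat),
          method = NA_character_, b = NA_real_, p = NA_real_,
          status = "insufficient instruments"
        )
        next
      }
      ana <- mr_analyse(dat, n_boot = n_boot, seed = seed, phi = phi,
                        run_presso = run_presso, n_sim = n_sim)
      analyses[[cell]] <- ana
      estimates[[cell]] <- dplyr::mutate(ana$estimates, exposure = ex_label,
                                         outcome = out_label, .before = 1)
      diagnostics[[cell]] <- dplyr::mutate(ana$heterogeneity,
                                           exposure = ex_label,
                                           outcome = out_label, .before = 1)
      hm <- .headline_method(ana$heterogeneity$heterogeneity, headline)
      head_row <- ana$estimates[ana$estimates$method == hm, ]
      family[[cell]] <- tibble::tibble(
        exposure = ex_label, outcome = out_label, n_snp = ana$n_snp,
        method = hm, b = head_row$b, p = head_row$pval, status = "ok"
      )
    }
  }
  family <- dplyr::bind_rows(family)
  ok <- family$status == "ok"
  family$q <- NA_real_
  family$q[ok] <- bh_adjust(family$p[ok])
  family$class <- NA_character_
  family$class[ok] <- classify_significance(family$p[ok], family$q[ok],
                                            p_cut, q_cut)
  structure(list(
    estimates = dplyr::bind_rows(estimates),
    diagnostics = dplyr::bind_rows(diagnostics),
    family = family,
    analyses = analyses,
    instruments = ivs,
    thresholds = list(p_threshold = p_threshold, clump_r2 = clump_r2,
                      clump_window_kb = clump_window_kb,
                      freq_band = freq_band, headline = headline,
                      het_p = 0.1, egger_intercept_p = 0.05,
                      p_cut = p_cut, q_cut = q_cut,
                      n_boot = n_boot, seed = seed, n_sim = n_sim)
  ), class = "mr_grid")
}

#' @export
print.mr_grid <- function(x, ...) {
  cat(sprintf("<mr_grid> %d cell(s); headline = %s\n",
              nrow(x$family), x$thresholds$headline))
  print(x$family)
  invisible(x)
}

#' @export
tidy.mr_grid <- function(x, ...) x$estimates

#' @export
glance.mr_grid <- function(x, ...) x$family

#' Write grid outputs as TSV tables
#'
#' Emits `results_main.tsv` (per-method odds ratios rounded to two decimals
#' with CI strings), `estimates_full.tsv` (full precision),
#' `diagnostics.tsv`, `family.tsv` and `thresholds.tsv` under `out_dir`.
#' Identical grids produce byte-identical files.
#'
#' @param grid An `mr_grid` object.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_grid <- function(grid, out_dir) {
  stopifnot(inherits(grid, "mr_grid"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  main <- dplyr::mutate(
    grid$estimates,
    OR = sprintf("%.2f", .data$or),
    CI95 = sprintf("%.2f-%.2f", .data$or_low, .data$or_high),
    p = signif(.data$pval, 3)
  )
  readr::write_tsv(main[c("exposure", "outcome", "method", "n_snp",
                          "OR", "CI95", "p")],
                   file.path(out_dir, "results_main.tsv"), progress = FALSE)
  readr::write_tsv(grid$estimates, file.path(out_dir, "estimates_full.tsv"),
                   progress = FALSE)
  readr::write_tsv(grid$diagnostics, file.path(out_dir, "diagnostics.tsv"),
                   progress = FALSE)
  readr::write_tsv(grid$family, file.path(out_dir, "family.tsv"),
                   progress = FALSE)
  thresholds <- tibble::tibble(parameter = names(grid$thresholds),
                               value = vapply(grid$thresholds, format,
                                              character(1)))
  readr::write_tsv(thresholds, file.path(out_dir, "thresholds.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}

#' Two-step mediation analysis for one exposure / mediator / outcome trio
#'
#' Step one of the surrounding workflow establishes which mediators are
#' causally related to the outcome; this function applies the q < 0.05
#' eligibility gate (when a step-one `mr_grid` is supplied), then estimates
#' `beta1` (univariable IVW of the exposure instruments on the mediator),
#' `beta2`/`beta3` (multivariable IVW on the outcome via
#' [assemble_mvmr_panel()]), and the mediation decomposition with Sobel's
#' test. A gated-out mediator returns an explicit non-eligible result, not
#' silence.
#'
#' @param exposure,mediator,outcome Full summary-statistics tibbles.
#' @param grid Optional step-one `mr_grid`; when given,
#'   `mediator_label`/`outcome_label` must name a cell and its q-value must
#'   be below `q_gate` for the analysis to proceed.
#' @param mediator_label,outcome_label Labels identifying the step-one cell.
#' @param q_gate Eligibility threshold on the step-one q-value.
#' @param se1_method IVW standard-error model for `beta1`
#'   (`"mre"` default, or `"fe"`).
#' @param ld,p_threshold,clump_r2,clump_window_kb,freq_band Selection and
#'   harmonization parameters.
#' @return Object of class `mr_mediation`: `eligible`, `reason`,
#'   `beta1_fit`, `mvmr_fit`, `decomposition` (a
#'   `mediation_decomposition`), `panel`. [tidy()] gives the one-row
#'   decomposition table.
#' @export
mr_mediation <- function(exposure, mediator, outcome, grid = NULL,
                         mediator_label = NULL, outcome_label = NULL,
                         q_gate = 0.05, se1_method = c("mre", "fe"),
                         ld = NULL, p_threshold = 5e-8, clump_r2 = 0.01,
                         clump_window_kb = 5000, freq_band = 0.45) {
  se1_method <- match.arg(se1_method)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "mr_grid"),
              !is.null(mediator_label), !is.null(outcome_label))
    row <- grid$family[grid$family$exposure == mediator_label &
                         grid$family$outcome == outcome_label, ]
    if (nrow(row) != 1L) {
      mrm_abort("mediator/outcome cell not found in the step-one grid",
                "mrm_usage_error")
    }
    if (!is.finite(row$q) || row$q >= q_gate) {
      return(structure(list(
        eligible = FALSE,
        reason = sprintf("not eligible (q >= %.2g)", q_gate),
        beta1_fit = NULL, mvmr_fit = NULL, decomposition = NULL, panel = NULL
      ), class = "mr_mediation"))
    }
  }
  ex_iv <- clump_instruments(filter_genomewide(exposure, p_threshold),
                             ld = ld, r2_max = clump_r2,
                             window_kb = clump_window_kb)
  med_iv <- clump_instruments(filter_genomewide(mediator, p_threshold),
                              ld = ld, r2_max = clump_r2,
                              window_kb = clump_window_kb)
  # beta1: exposure -> mediator, univariable IVW on the exposure instruments
  dat1 <- harmonise(ex_iv, mediator, freq_band = freq_band)
  fit1 <- mr_ivw(dat1, mode = se1_method)
  # beta2, beta3: conditional effects from multivariable IVW on the outcome
  panel <- assemble_mvmr_panel(ex_iv, med_iv, exposure, mediator, outcome,
                               ld = ld, r2_max = clump_r2,
                               window_kb = clump_window_kb,
                               freq_band = freq_band)
  fitm <- mvmr_ivw(panel, exposures = c("x", "m"),
                   labels = c("exposure", "mediator"))
  est <- fitm$estimates
  dec <- two_step_mediation(
    beta1 = fit1$b, se1 = fit1$se,
    beta2 = est$b[est$exposure == "mediator"],
    se2 = est$se[est$exposure == "mediator"],
    beta3 = est$b[est$exposure == "exposure"],
    se3 = est$se[est$exposure == "exposure"]
  )
  structure(list(eligible = TRUE, reason = NA_character_, beta1_fit = fit1,
                 mvmr_fit = fitm, decomposition = dec, panel = panel),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  if (!x$eligible) {
    cat("<mr_mediation>", x$reason, "\n")
    return(invisible(x))
  }
  cat("<mr_mediation>\n")
  print(x$decomposition)
  invisible(x)
}

#' @export
tidy.mr_mediation <- function(x, ...) {
  if (!x$eligible) {
    return(tibble::tibble(eligible = FALSE, reason = x$reason))
  }
  dplyr::mutate(tidy(x$decomposition), eligible = TRUE, .before = 1)
}
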