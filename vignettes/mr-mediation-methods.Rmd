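---
title: "Methods: two-sample MR and MVMR-based mediation in mrmediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and MVMR-based mediation in mrmediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediation)
```

## The estimation problem

Two-sample Mendelian randomization treats genetic variants as instruments:
each SNP contributes an exposure association and an outcome association
measured in non-overlapping samples, and under the three instrumental
assumptions (relevance, no confounding of instrument and outcome,
exclusion restriction) the ratio of outcome to exposure effects estimates
the causal effect. The package works entirely on the summary scale — a
tibble of per-SNP records is the universal currency — and implements the
full workflow: selection, harmonization, estimation, diagnostics, FDR over
an analysis grid, and a two-step mediation decomposition.

## Instrument selection

* **Significance filter.** `filter_genomewide()` keeps SNPs with
  p strictly below 5e-8. The boundary is exclusive; a SNP at exactly the
  threshold is dropped.
* **Clumping.** `clump_instruments()` is greedy: the lowest-p unclaimed
  SNP becomes an index and removes unclaimed SNPs that are *both* within
  5,000 kb (inclusive) on the same chromosome *and* have r² > 0.01 with
  the index. Both conditions must hold — distance alone never excludes.
  The index-selection order is the community convention (lowest p first);
  ties on p are broken by (chr, pos, snp) so results are independent of
  input order and platform. LD arrives as a precomputed pairwise table
  (`ld_table()`); absent pairs default to r² = 0 (treat as independent),
  which intentionally degrades to keeping everything when no panel is
  supplied — supply `default_r2 = 1` to force distance-only clumping.
* **Strength.** Per-SNP F = β²/se² and R² = 2β²·EAF·(1−EAF); F < 10 flags
  a weak instrument. These are descriptive; nothing is auto-dropped.

## Harmonization

`harmonise()` places outcome (and mediator) effects on the exposure's
effect-allele frame. Matching alleles are kept; swapped alleles flip the
effect sign and complement the frequency; strand complements are
re-labelled; anything irreconcilable is excluded. Palindromic (A/T, G/C)
pairs cannot be resolved from allele labels: they are oriented by
frequency concordance (both sides' EAF on the same side of 0.5) and
*excluded* when either side's minor-allele frequency exceeds 0.45 — i.e.
EAF within (0.45, 0.55) — because strand orientation cannot then be
inferred with useful accuracy. Palindromes lacking a frequency on either
side are excluded conservatively. A flag (`resolve_palindromes = FALSE`)
switches to dropping all palindromes; the audit table records which rule
fired for every SNP. Non-palindromic alignment never consults EAF except
to warn when frequencies disagree by more than 0.2 after alignment.

The load-bearing correctness property, enforced by a randomized test, is
that downstream estimates are invariant under arbitrary relabeling of
(effect allele, other allele, effect sign, EAF ↔ 1−EAF) of either input,
and that harmonization is involution-safe.

## Estimators and diagnostics

All weighted regressions are authored from explicit normal equations (they
are the package's core); `lm()` appears only as an independent oracle in
the tests, with agreement required to 1e-10 relative error.

* **IVW.** Origin-constrained weighted regression, weights 1/se_y². FE and
  MRE share the point estimate; the MRE standard error multiplies by
  max(1, √(Q/(n−1))), flooring dispersion at 1 so underdispersion never
  shrinks the interval. The published analysis this design follows states
  an FE/MRE *selection* rule that inverts the usual convention
  (fixed effects when heterogeneity is present); rather than guessing
  intent, both models are always computed and the headline choice is an
  explicit switch (`headline` in `mr_grid()`, default `"as_published"`,
  recorded per cell in the output).
* **Cochran's Q / I²GX.** Q uses the ratio form with weights β_x²/se_y²;
  heterogeneity flags at p < 0.1. I²GX is the I² of the |β_x| estimates
  weighted 1/se_x², flooring at 0; values near 100% mean regression
  dilution does not materially affect MR-Egger.
* **MR-Egger.** Instruments are oriented to β_x ≥ 0, then a two-parameter
  weighted regression. SEs carry the same max(1, residual sd) factor;
  p-values use the t distribution with n−2 df (regression convention),
  while confidence intervals remain ±1.96·se like every other method, to
  match the symmetric intervals conventionally reported.
* **Weighted median.** Linear interpolation of the weighted empirical CDF
  at 0.5 with standardised cumulative weights (cum − w/2)/Σw; under equal
  weights and odd n this is exactly the plain median.
* **Weighted mode.** Gaussian kernel density of the ratios with bandwidth
  φ·0.9·min(sd, mad)·n^(−1/5), evaluated on a fixed 512-point grid
  spanning the ratio range ± 3 bandwidths; the argmax breaks ties toward
  the smallest value. A zero bandwidth (identical ratios) returns the
  common ratio; a zero *mad* with non-identical ratios falls back to the
  sd-based bandwidth.
* **Bootstrap SEs.** Weighted median and mode use a seeded parametric
  bootstrap (each β_x, β_y redrawn from Normal(observed, se)); defaults
  n_boot = 1000, seed = 20230328. Point estimates are exactly equivariant
  under joint per-SNP sign flips and SNP reordering; bootstrap SEs are
  seed-stream dependent and only statistically so.
* **MR-PRESSO.** Observed statistic: weighted residual sum of squares
  about leave-one-out IVW fits. Null distribution: parametric simulation
  around the leave-one-out fitted values (vectorised across simulations);
  global p = (1 + #{RSS* ≥ RSS})/(n_sim + 1); per-SNP outlier p-values
  from each SNP's simulated residual distribution, Bonferroni-adjusted by
  n. Detected outliers are removed and IVW recomputed. Note the Bonferroni
  floor: with n SNPs, outlier detection requires n_sim + 1 > n/α
  (n_sim = 1000 suffices for 30 SNPs at α = 0.05). The distortion test is
  deliberately not implemented.
* **Leave-one-out.** IVW-MRE omitting each SNP; influential = sign flip of
  the estimate or p crossing 0.05.

## Multivariable MR and mediation

`assemble_mvmr_panel()` unions the exposure and mediator instrument sets,
looks up all three associations per SNP, harmonizes to the exposure frame,
and re-clumps the union so the retained SNPs are mutually independent (an
assumption of the normal equations); the union is ordered by the smaller
of the exposure and mediator p-values, each SNP's own source significance.
`mvmr_ivw()` regresses β_y on (β_x, β_m) with weights 1/se_y², no
intercept, dispersion floored at 1. A column that is identically zero is
dropped (coefficient NA) so the reduction to univariable IVW is exact;
genuinely collinear designs raise an error carrying the condition number
(threshold 1e8 on the weighted design).

`two_step_mediation()` combines β₁ (univariable IVW of exposure on
mediator), β₂ and β₃ (MVMR conditional effects): indirect = β₁β₂,
total = β₃ + β₁β₂ (an identity holding to machine precision), proportion
mediated = indirect/total on the log-odds scale, Sobel
z = β₁β₂/√(β₂²se₁² + β₁²se₂²). Two deliberate choices:

* The Sobel SE uses the first-order delta form without the se₁²se₂² term,
  and β₁'s standard error defaults to the MRE model (`se1_method = "mre"`),
  because that combination reproduces the published worked example's z
  statistic from its printed coefficients; both are configurable.
* The proportion-mediated formula, evaluated as written on the published
  worked-example coefficients (β₁ = 0.61, β₂ = ln 1.49, β₃ = ln 1.25),
  gives ≈ 0.52 — not the 39.14% printed alongside them. The package
  evaluates the formula and documents the divergence; it does not tune
  toward the printed percentage, whose derivation is not reconstructible
  from the printed coefficients.

In `mr_grid()`, the BH-FDR family is exactly the exposure×outcome headline
IVW tests of one run (cells without sufficient instruments are marked and
excluded from the family); the step-two exposure→mediator test is not a
family member. `mr_mediation()` applies the step-one eligibility gate as
specified — a mediator proceeds only with q < 0.05 — and a gated-out
mediator returns an explicit non-eligible record.

## The synthetic-data generator

`simulate_sumstats()` draws, per SNP: EAF ~ U(0.05, 0.5); a true exposure
effect from Normal(0, beta_x_sd) truncated so the instrument passes
genome-wide significance in expectation; se_x = 1/√(2·n_exposure·p(1−p));
a pleiotropy term α_j ~ Normal(mean, sd) expressed on the
exposure-increasing allele orientation (so a non-zero mean is directional
in the Egger sense while InSIDE holds); a binary-outcome standard error
1/√(2·n_outcome·cf(1−cf)·2p(1−p)); and independent observation noise for
the exposure and outcome samples (separate random sub-streams per trait,
emulating the two-sample design). Optional outliers displace β_y by a
stated number of outcome SEs. `simulate_mediation_triplet()` adds a
mediator GWAS: exposure instruments transmit β₁·β_x to the mediator and
β₃·β_x + β₂·β_m to the outcome; mediator-specific instruments have zero
exposure effect. All tables pass `validate_sumstats()` with zero rejects,
and the generator is a pure function of its config.

Defaults are fixed once at study-realistic values: n_exposure = 300,000
(an anthropometric-consortium scale), n_outcome = 260,000 with case
fraction 0.042 (a biobank venous-thromboembolism scale), n_mediator =
50,000 (a biomarker GWAS scale), 30 exposure instruments and 20
mediator-specific instruments, beta_x_sd = 0.03 (instrument F statistics
around 100), beta_m_sd = 0.08, and a 20% palindromic fraction to exercise
harmonization. SNPs are placed 6 Mb apart on cycling chromosomes so truly
independent instruments survive clumping unchanged.

What the generator does *not* emulate: LD between instruments (SNPs are
independent; only an explicit pairwise table exercises clumping), sample
overlap, winner's-curse selection on the *observed* estimate (truncation
is on the true effect), allele-frequency differences between samples,
population stratification, and non-linear or interaction effects.
Passing calibration tests therefore demonstrate correctness of the
estimators under the stated sampling model, not robustness to those
real-data pathologies.

## Test problem sizes

The simulation-based checks run at sizes chosen to balance Monte-Carlo
error against a fast default test run: type-I calibration uses 1,000
replicates of 30-SNP panels (rejection rate required within [0.03, 0.07]);
effect recovery 500 replicates (mean within 0.02 of θ = 0.4, coverage
within [0.92, 0.97]); Egger-intercept centering 200 replicates with
directional pleiotropy mean 0.05; MR-PRESSO detection 100 runs with one
SNP displaced by 10 SEs (≥ 90% detection); mediation recovery 200
replicates of (β₁, β₂, β₃) = (0.6, 0.4, 0.24) (median estimated proportion
within ±0.10 of 0.50). Oracle-equivalence checks compare against
`lm()`-based weighted-least-squares fits on 100 random panels at 1e-10
relative tolerance, and the weighted median against a brute-force CDF
interpolation at 1e-12.

## Degenerate inputs and numerical conventions

Single-instrument analyses route to the Wald ratio; β_x = 0 is a
degenerate-instrument error. IVW requires 2 SNPs, Egger/median/mode 3,
MR-PRESSO 4, MVMR one more than the number of exposures — each violation
raises a typed, directed error. A zero total effect makes the proportion
mediated undefined (NA with a warning), not an exception. Confidence
intervals use the literal 1.96 multiplier throughout, matching
conventionally printed symmetric intervals. Text output rounds odds
ratios to two decimals (`write_grid()`'s main table) while full-precision
companions preserve testability.

## Limitations

The package consumes precomputed pairwise LD only; it performs no
reference-panel processing, no proxy-SNP substitution for instruments
missing in the outcome, no Steiger filtering, and none of the newer
estimators (MR-RAPS, contamination mixture, cML). Real consortium GWAS
inputs are read with `read_sumstats()` but are never fetched by the
package, and headline published odds ratios can only be reproduced when
the user supplies those data.
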