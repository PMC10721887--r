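---
title: "Methods: polygenic modification of monogenic kidney disease penetrance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic modification of monogenic kidney disease penetrance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Pathogenic variants in *PKD1*/*PKD2* (autosomal dominant polycystic kidney
disease) and *COL4A3*/*COL4A4*/*COL4A5* (collagen-IV nephropathies) are the
two most common monogenic causes of chronic kidney disease (CKD), yet both
show incomplete penetrance and highly variable expressivity, even within
pedigrees. One candidate explanation is polygenic background: thousands of
common variants each nudging renal function, summarized by a genome-wide
polygenic score (GPS). `penetrax` implements the full analytic chain needed
to test that hypothesis in biobank-style data — qualifying-variant
classification, electronic CKD phenotyping, ancestry-calibrated scoring,
carrier-stratified association models with cross-cohort meta-analysis, and a
phenome-wide scan — together with a synthetic data generator that makes the
whole chain falsifiable.

## The disease model and its assumptions

Everything downstream estimates coefficients of one generative model.
Writing $c$ for carrier status, $g$ for the standardized GPS, and $a$ for
the APOL1 recessive risk genotype:

$$\operatorname{logit} P(\text{CKD}) = \beta_0 + \beta_c c + \beta_g g +
\beta_i c\,g + \beta_a a + \beta_{\text{age}}\frac{\text{age}-55}{10} +
\beta_{\text{male}} + \beta_{\text{dm}}$$

Key assumptions, each of which is also a design decision of the simulator:

- **Logistic, not probit, liability.** Planted log-odds-ratios are then
  exactly the estimands of the logistic fits, giving an exact oracle for
  parameter-recovery tests. A probit simulator would make every recovered
  coefficient attenuation-biased by design.
- **Intercept calibration.** $\beta_0$ is solved numerically (per cohort,
  by `uniroot` on the mean case probability) so the marginal case rate
  equals the configured `baseline_case_rate` despite the nonlinearity of
  the logistic mean — a closed-form intercept would miss by Jensen's
  inequality.
- **Carrier status in the liability is the strict (M1) dominant carrier
  flag** for each gene set. Looser tiers (M2, M3) therefore recover
  attenuated effects, which is the scientifically expected behavior of
  diluted carrier definitions, not a bug.

## Qualifying variants

Three evidence tiers classify rare variants after QC:

| Tier | Rule |
|------|------|
| M1 | pLOF ∪ {ClinVar "P", ≥ 2 submitters, no conflict} |
| M2 | pLOF ∪ {ClinVar "P" or "LP", ≥ 2 submitters, no conflict} |
| M3 | pLOF ∪ {missense, REVEL > 0.70, 5/5 predictors damaging} |

pLOF means stop-gain, frameshift, stop-lost, start-lost, or essential
splice (acceptor/donor); `splice_region_variant` does not qualify. A B/LB
assertion from ClinVar *or* Varsome vetoes a variant from every tier, and
this veto is the only way Varsome enters — its P/LP assertions never
qualify a variant. M1 ⊆ M2 always; M3 need not contain M1 (a "P" missense
with low REVEL is in M1 but not M3).

Decisions where the design was genuinely open:

- **Missing predictor data fail the missense test.** Conservative: M1/M2
  are unaffected and M3 stays specific.
- **A Varsome VUS does not block a ClinVar-P variant.** Only B/LB excludes.
- **Compound heterozygotes are called from unphased genotypes** as ≥ 2
  distinct heterozygous QVs in one autosomal gene. In-cis pairs are
  therefore possible false positives; the simulator plants exactly such a
  pair so tests document (rather than hide) this behavior.
- **The ClinVar conflict flag is an input bit**, not recomputed from
  submitter records: assertion aggregation semantics are upstream content.
- **Boundary semantics.** GQ/DP use strict "greater than" (a call at
  GQ = 90 is masked); the frequency filter removes on "greater than", so a
  variant exactly at its ceiling survives. Cohort-internal allele
  frequency is recomputed *after* genotype masking and participates in the
  filter as one more source; whether the original analyses computed it
  before or after masking is not documented, and the post-masking choice is
  the conservative one (masked calls cannot rescue a variant).

## CKD e-phenotype

eGFR comes from the 2009 CKD-EPI creatinine equation (primary; the race
coefficient is driven by an explicit indicator column and never inferred)
or the 2021 race-free refit. Cases: eGFR < 60 ml/min/1.73 m² or a renal
replacement record. Controls: eGFR > 90 and no CKD billing codes.
eGFR 60–90 is excluded to limit misclassification from age-related decline.
With several creatinine values per participant the median is used
(deterministic, robust; the source analyses do not state their choice).
The simulator *inverts* the 2009 equation from a sampled target eGFR, so
phenotype labels are a deterministic function of the truth record — the
phenotyping module can be tested for exact agreement.

## Ancestry, kinship, and the score

- **LD pruning** follows the 500-variant window / 50-variant step / r² 0.05
  convention (variant-count interpretation), removing the later variant of
  an offending pair — deterministic given input order, and audited in tests
  by brute-force all-pairs checks.
- **PCA is fit on the labeled reference panel only**; cohort samples are
  projected through fixed loadings. Ancestry is assigned by a 500-tree
  random forest on 10 PCs with an internal stratified holdout reporting
  accuracy.
- **Kinship** uses the KING-robust between-family estimator
  $(N_{Aa,Aa} - 2N_{AA,aa})/(N^{(i)}_{Aa} + N^{(j)}_{Aa})$ with greedy
  exclusion above 0.0442 (most-connected sample first, lexicographic
  ties). All-pairs estimation is quadratic in n, so `run_pipeline`
  auto-skips the stage above a configurable ceiling (default 5,000) while
  the estimator itself is tested at realistic pair counts.
- **Score calibration** proceeds raw score → reference-fit mean adjustment
  (linear model on PCs) → reference-fit variance adjustment (log squared
  residual on PCs, with a smearing correction so the reference variance is
  unbiased) → APOL1 residualization → standardization → cohort-wide
  tertiles. Mean-only adjustment is available as a switch. APOL1
  adjustment removes the association by residualizing the recessive
  risk-genotype indicator rather than adding a weighted term; both
  readings of "adjusted for" are defensible, and residualization is the
  one that guarantees score ⊥ APOL1 downstream (verified to |r| < 0.01 in
  tests).
- **Tertiles are cut on the cohort-wide standardized distribution** and
  applied to carriers and noncarriers alike: the stratified figures
  compare carrier tertiles against the noncarrier middle tertile on a
  single scale, which carrier-only tertiles would break.

One simulator-specific choice deserves emphasis: the generator reserves a
dedicated set of common markers for PCA/kinship (`n_pca_variants`),
disjoint from the score weights. With desk-scale marker counts, letting the
score's own variants drive the principal components makes the mean
adjustment regress out genuine within-ancestry score variation (a leakage
artifact of small m, negligible at biobank marker counts but a ~3%
attenuation here). Real pipelines approximate this separation through
sheer marker abundance; the simulator makes it explicit.

## Association statistics

Wald inference throughout, matching the OR ± CI reporting style. Per-SD
GPS effects scale the score by the control-group standard deviation.
Sparse strata (any carrier × case cell < 5, or detected separation) fall
back to hand-implemented Firth penalized logistic regression — biobank
carrier strata can be as small as single digits, where plain ML is
unstable. Covariates follow each analysis's own convention: age, sex,
diabetes, batch and 4 ancestry PCs for the carrier and per-SD models;
diabetes is omitted from the tertile models; the PheWAS uses 5 PCs. All
are configurable. Fixed-effects pooling is the one-line inverse-variance
formula, cross-checked in tests against an independent meta-analysis
package at 1e-10 tolerance. Discrimination is AUROC (full model via fitted
probabilities, crude via the score alone, DeLong CIs) and incremental
Nagelkerke pseudo-R² (full minus covariates-only).

## What the generator emulates — and what it does not

Emulated: two cohorts with different ancestry mixes (≈94% vs ≈43%
European) and age ranges (40–69 vs 18–89); Balding–Nichols allele-frequency
differentiation (Fst 0.10) driving PC separation; AR(1) LD blocks
(ρ = 0.35, block size 25) making pruning and clumping non-trivial; APOL1
risk-allele frequencies concentrated in African-ancestry groups, with the
raw score deliberately contaminated through two APOL1 tag markers so the
adjustment has real work to do; annotation edge cases populating every
classification branch (single-submitter, conflict, benign veto, REVEL
boundary, essential vs non-essential splice); planted compound
heterozygote, in-cis pair, homozygote, hemizygous male, and a heterozygous
X call in a male; GQ/DP failures; missing creatinine; an eGFR 60–90
exclusion tranche; ICD code multisets with carrier-enriched phecodes.

Not emulated: read-level sequencing error, imputation uncertainty,
realistic haplotype phasing, EHR temporal structure and informative
missingness, survey data, and realistic per-stratum covariate
distributions (covariate effects are chosen for testability, not
epidemiological realism). A green suite therefore certifies the
*computational* chain, not robustness to real-data artifacts upstream of
it.

Default study conditions: n = 200,000 (165,000 + 35,000), ADPKD carrier
frequency 6e-4 (~120 strict-tier carriers), COL4A 3e-3, planted carrier
ORs 17 (ADPKD) and 1.37 (COL4A), GPS OR 1.7 per SD, null interaction,
APOL1 OR 2, baseline case rate 3%. Marker counts (500 score + 800 PCA) are
the package's design size for desk-scale runs; the per-variant carrier cap
keeps every surviving-class variant at or below its frequency ceiling in
the cohort-recomputed source, so the frequency filter never removes a
variant the truth record counts on. Calibration replication (interaction
type-I error) uses 200 draws of the generative outcome model at n = 20,000.

## Numerical choices and degenerate inputs

- Tertile ties go to the lower stratum; degenerate (constant) score
  distributions are an error, not a silent 1-tertile cohort.
- Empty carrier tertiles are reported as NA rows, never dropped.
- Firth IRLS uses step-halving for stability and the penalized Fisher
  information for standard errors.
- Missing dosages contribute 0 to the score under sum semantics
  (mean-imputation mode available); missing APOL1 genotypes count as
  non-risk with a logged count; estimates with non-finite SE are dropped
  from pooling with a warning.
- Monomorphic variants are removed before pruning with a warning; variants
  losing every alternate call to masking are dropped with their count
  reported; the filter report is an exact partition of its input.
- Every stage derives its own RNG stream from the master seed, so stages
  are individually re-runnable and whole runs are byte-identical.

## Known limitations

- Recessive analyses under the strict tiers are intrinsically underpowered
  at any realistic carrier frequency; the recessive machinery is exercised
  under the loosest tier, mirroring how such analyses are actually run.
- The Firth fallback handles separation but very small strata still carry
  wide intervals; the per-stratum case counts are always reported so users
  can see when an interval is vacuous.
- The phecode map shipped is synthetic (16 phecodes) and structurally,
  not nosologically, faithful; users with the standard map can supply it
  in the same long format.
- Unphased compound-heterozygote calls overcount by in-cis pairs, as
  documented above.
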