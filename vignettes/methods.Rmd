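---
title: "Methods: phenotyping CD4 recovery and gene-burden association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping CD4 recovery and gene-burden association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd4recover)
```

This vignette documents the models, parameter choices and numerical
conventions behind `cd4recover`, and what its synthetic-data experiments do
and do not demonstrate about real cohort data.

## The scientific setting

After starting suppressive combination antiretroviral therapy (cART), most
people with HIV regain circulating CD4 T cells at roughly 50–150
cells/mm³ in the first year; a substantial minority (immunologic
non-responders) gain very little despite an undetectable viral load. The
package implements a case-control design around that contrast: classify
longitudinal cohort visits into response phenotypes, select good and poor
responders, screen clinical covariates, and test genes for rare/common
variant burden differences between the groups.

## Visit phenotyping

Visits are semiannual, so the visit index is the clock: one year is two
inter-visit intervals, and all "rolling year" quantities compare a visit with
the one two positions away.

**Imputation** (`impute_gaps()`). A run of at most `max_imputed_run = 2`
consecutive missing CD4 (or viral-load-status) values is filled only when
measured visits flank the gap on both sides and cART status is constant over
the flank-to-flank span. CD4 is filled by linear interpolation on visit
index; suppression status by the flanking consensus (both flanks must
agree). The source description states *when* imputation applies but not how
values are computed; linear interpolation and flank consensus are the
minimal-assumption choices, and measured values are never altered.

**Smoothing** (`smooth_cd4()`). Each non-missing CD4 becomes the unweighted
mean over a centered window of `smooth_window = 3` visits, shrinking to two
values at series endpoints or next to a missing neighbor. Unweighted means
match the stated "two or three nearby visits" without inventing weights.

**Classification** (`classify_visits()`). The code taxonomy distinguishes the
first-ever cART visit, reinitiation after a gap, suppressed vs viremic
on-therapy visits (suppression judged by the per-visit below-detection flag
by default, because assay limits differ across calendar eras; the
`vl_lt_limit` rule compares measured copies/mL with the per-visit limit),
minimal-gain suppressed visits (trailing-year smoothed gain below the poor
threshold), and short vs long-term off-therapy spells. Visits whose inputs
are missing, or whose history is too short for the rule, are
`NOT_DETERMINED`. A suppressed visit too early in follow-up to evaluate the
trailing-year gain is coded plain `CART_SUPPRESSED`: suppression is decidable
from that visit alone, and only the minimal-gain refinement needs history.

**Responder calls** (`call_responders()`). Within each maximal run of
suppressed on-therapy visits, every rolling-year gain must be
≥ `good_gain_per_year = 100` cells/mm³/yr (plus positive gain above nadir,
run ≥ 2 years) for GOOD, or < `poor_gain_per_year = 50` in every rolling year
(run ≥ 1 year) for POOR. The thresholds are config defaults anchored to the
50–150 cells/mm³ first-year standard for an adequate response; the binding
operational definition in the original study lives in its supplementary SAS
algorithm, so the config is the single place to re-point them. A participant
whose runs qualify for both groups, or for neither, is INDETERMINATE — we
deliberately do not invent a precedence rule. Ties among qualifying runs go
to the earliest.

**Matching** (`match_groups()`). Frequency matching within race/ethnicity
strata: good responders are sampled without replacement (seeded) to the
poor-responder stratum counts; strata with no good responders are dropped
with a warning, shortfalls keep all available good responders.

## Clinical covariate association

Binary predictors use the cross-product odds ratio with Wald 95% intervals
and p-values — back-computing the published cohort table from its printed
counts reproduces the printed ORs, bounds and p-values exactly, which is the
evidence that Wald (not profile or exact) statistics were the method in use.
Adherence is dichotomized >95% vs ≤95% with unknowns excluded; analyses are
complete-case. Forward stepwise selection enters the candidate with the
smallest multivariate Wald p below 0.05, with name-order tie-breaks; nadir
CD4 is never a candidate because it is part of the outcome definition.

## Genotype QC, annotation and ancestry

VCF genotypes with read depth below 8 or genotype quality below 20 are set
to missing (non-strict: DP = 8 and GQ = 20 survive); multi-allelic and
non-SNP records are skipped with counts. Dosages are oriented to the cohort
minor allele. Per-SNP statistics are the call rate, cohort MAF, the
conditional exact Hardy-Weinberg test (full enumeration of heterozygote
counts given allele counts, two-sided by probability ordering), the
excess-heterozygosity ratio R — defined here as observed over expected
heterozygote count under HWE, since the source's legend names but never
defines R; the choice affects only reporting, not inference — and the
allelic Fisher exact test of association (the genotypic table is an equally
defensible reading; allelic is the convention we fixed).

CMC bins come from the *reference* MAF lookup (emulating a population
reference database), with absent variants assigned to the rarest (<1%) bin;
KBAC's rare/common cut uses the *cohort* MAF strictly below 5%. The two
frequencies deliberately play different roles, mirroring their separate
descriptions in the source. Coordinates are 1-based inclusive throughout,
matching VCF.

Ancestry PCA standardizes each variant by `sqrt(2p(1-p))`, mean-imputes
missing dosages, drops monomorphic variants, and fixes component signs by
making the largest-magnitude loading positive, so results are reproducible
and invariant to sample order. No LD pruning is applied (none was
described). The first two components are the stratification covariates.

## Burden tests

**CMC.** All five bins — including the common ones — collapse to carrier
indicators, because the source reports one beta per bin; degenerate
(variant-free or constant) bins carry no degree of freedom. The omnibus
statistic is the likelihood-ratio chi-square of the logistic model with the
indicators against the covariates-only null, with `df` = number of
non-degenerate bins. Missing dosage within a region counts as non-carrier,
with a logged count.

**KBAC.** Samples are grouped by identical rare-variant dosage vectors; each
non-null multi-marker genotype is weighted by the hypergeometric CDF of its
case-carrier count; the score is the weighted sum of case-control genotype
frequency differences, one-sided for risk, with weights recomputed in every
resample.

**Permutation p-values** use the `(exceedances + 1)/(n + 1)` estimator
(no gene reports p = 0). When `choose(n, n_cases)` does not exceed
`max_perm` under label permutation, all case assignments are enumerated and
the p-value is exact. Adaptive early stopping ends resampling once the
one-sided 99% Clopper-Pearson lower bound on p exceeds ten times the
reporting threshold, so candidate hits always receive full resolution while
clearly null genes stop after a few hundred resamples. Published exome scans
of this design use 10⁶ permutations with p ≤ 0.001; the desk default is 10⁴
(`permutation_plan(max_perm = 1e4)`), which resolves p-values to 10⁻⁴ —
sufficient for the 0.001 threshold — in minutes rather than days.

**Covariate adjustment under permutation.** The proprietary software used in
the original analysis does not document its scheme. Our default for adjusted
tests is a parametric bootstrap: phenotypes are redrawn from the
covariates-only null logistic fit, preserving the covariate-phenotype
structure; plain label permutation (which breaks it) remains available via
the plan's `scheme`. Only the statistical contract — calibration and
one-sidedness — is reproducible against the original, not its internals.

**Transcript rerun.** Both tests are repeated per transcript interval, but
only for genes that met the a-priori threshold, to keep the added
multiple-testing burden minimal.

## The synthetic generator: what it emulates and what it does not

`sim_scenario()` defaults encode the study conditions: 90 participants
(targeting roughly 48 good / 42 poor), ages N(42, 8²) with a per-year
good-response odds ratio of 0.894, semiannual visits with a 2-visit pre-cART
phase, an 80 copies/mL detection limit, 5% per-visit blip and missingness
rates, nadir CD4 ~ N(180, 100²) truncated at 10, and CD4 slopes of
150 ± 30 (good) vs 20 ± 15 (poor) cells/mm³/yr with 25 cells/mm³ visit
noise. CD4 trajectories are piecewise linear in time plus Gaussian noise —
the minimal structure the phenotyper consumes; no published distributional
description of the real trajectories exists, so these are calibration
choices, not estimates. The genome is 200 genes × 25 SNPs with ancestral
frequencies from a Beta(0.4, 4) spectrum, two subpopulations at Fst 0.1
(Balding-Nichols draws, Hardy-Weinberg within subpopulation), per-genotype
DP/GQ values with a 2% sub-threshold fraction, and a 10% hole in the
reference-MAF lookup to exercise the absent→rarest-bin rule.

Planted effects are retrospective, matching the case-control design: carrier
status at ten designated rare sites per causal gene is re-sampled conditional
on the true response group, carriers spread round-robin so every planted
allele stays well below the 5% rare cutoff. The default carrier log-odds of
4.5 (carrier OR ≈ 90 over a 5% poor-group rate) was set by power simulation
of the implemented tests so the planted genes function as positive controls —
detected at the exome-wide permutation threshold with near certainty at
n = 90. They demonstrate that the machinery finds strong localized signal;
they say nothing about power for realistic effect sizes, which at n = 90 is
modest for any rare-variant test.

The generator does **not** simulate linkage disequilibrium beyond
subpopulation frequency divergence, read-level data, genotyping error beyond
the DP/GQ masking, or time-varying treatment regimens. Passing tests
therefore validate the analysis logic and its calibration under the stated
model, not robustness to those real-data features.

The stepwise demonstration uses a separate fixture
(`simulate_age_signal_cohort()`): an outcome driven only by age plus five
null covariates that are correlated with age *and with one another* through
a shared latent era/cohort factor — as age-linked exposures (smoking years,
ovarian reserve, early-era nucleoside use) are in real cohorts. With
mutually independent null covariates the probability that none of five
false-enters at p < 0.05 is only ~0.77, so the clustered structure is what
makes "age first and alone" the overwhelmingly likely outcome; the fixture
uses n = 400 so the age effect itself is detected with probability ~1 and
the check isolates false-entry behavior.

## Numerical choices and degenerate inputs

- Logistic fits inside the permutation loop use a compiled IRLS kernel whose
  deviance matches `glm.fit` to numerical precision (verified in the tests);
  separation or non-convergence flags the result rather than silently
  reporting it.
- Permutation exceedance comparisons use `stat ≥ observed − 10⁻¹²` so that
  floating-point ties count as exceedances (conservative).
- Zero cells in a 2×2 are an error, never silently continuity-corrected.
- Monomorphic variants: HWE p = 1, heterozygosity ratio undefined,
  association skipped. All-missing variants are dropped from PCA with a log
  entry. Genes whose rare sites have no carriers get a KBAC score of 0 and
  p = 1. Regions with zero variants are skipped and logged.
- Burden tests canonicalize sample order internally, so permutation p-values
  are identical across input orderings at a fixed seed.

## Problem sizes used by the checks

The packaged experiments run at the study's scale on one CPU: the type-I
calibration pools five independent 90-woman cohorts of 100 null genes (2,000
permutations per gene, adaptive); the recovery experiment scans ten 200-gene
exomes at 4,000 permutations; the PCA check uses 90 samples × 5,000 variants;
the stepwise check runs 100 replicates. These sizes were chosen so the whole
suite completes in a few minutes while keeping every check at the cohort size
the design targets.

## Known limitations

- The phenotyping thresholds are anchored to the public first-year-gain
  standard, not to the study's unpublished operational algorithm; analyses
  of real exports should revisit `phenotype_config()` against their
  protocol.
- The adjusted permutation scheme is a principled reconstruction, not a
  re-implementation of the original proprietary software.
- Reproducing the original study's specific gene hits requires its
  restricted genotypes and is out of scope by design; the package reproduces
  the method, its calibration, and the printed clinical statistics.
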