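# cd4recover

Tools for studying why some people on suppressive combination antiretroviral
therapy (cART) rebuild their CD4 T-cell counts quickly while others — the
immunologic non-responders — barely gain cells despite an undetectable viral
load. The package implements the full analysis chain of a case-control exome
study of CD4 recovery in women with HIV: longitudinal phenotyping of
semiannual cohort visits into good/poor responder groups, univariate and
forward-stepwise logistic analysis of clinical covariates, VCF genotype QC
with ancestry principal components, and gene-level variant-burden association
with permutation p-values. A synthetic cohort-and-genome generator with
planted effects stands in for the restricted study data, so every stage is
testable end to end.

## The statistics at the core

**Phenotyping.** CD4 counts are imputed over short gaps (runs of at most two
missing visits with measured, cART-stable flanks), smoothed over a centered
window of up to three visits, and each visit is classified (on/off therapy,
suppressed/viremic, minimal-gain). A participant is a **good responder** when
a suppressed run spans ≥ 2 years with every rolling-year smoothed gain
≥ 100 cells/mm³/yr and positive gain above nadir, and a **poor responder**
when a run spans ≥ 1 year with every rolling-year gain < 50 cells/mm³/yr.

**Clinical association.** For a 2×2 exposure table the odds ratio is the
cross-product `OR = ad/bc` with Wald interval
`exp(ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`; continuous predictors get the
logistic-MLE OR per stated unit. Forward stepwise selection adds the
candidate with the smallest multivariate Wald p while it is below 0.05.

**Burden tests.** For a gene region with variants grouped into five
reference-frequency bins (<1%, 1–2.5%, 2.5–5%, 5–10%, ≥10%; variants absent
from the reference lookup go to the rarest bin), the **CMC** test enters one
carrier indicator per non-degenerate bin into a logistic model and compares
it with the covariates-only null by likelihood ratio. The **KBAC** test
groups samples by their multi-marker genotype over the rare (<5% MAF)
variants, weights each genotype by the hypergeometric CDF of its observed
case enrichment,

&nbsp;&nbsp;&nbsp;&nbsp;`K = Σ_j  w_j (n_jA/n_A − n_jU/n_U)`, &nbsp; `w_j = P(X ≤ n_jA)`, `X ~ Hypergeom(n_A, n_U, n_j)`,

and is one-sided for risk. Both tests get gene-wise permutation p-values
(`(exceedances + 1)/(n + 1)`, adaptive early stopping, exact enumeration when
the number of case assignments is small), unadjusted and adjusted for age and
the first two genotype principal components.

## A worked example

```r
library(cd4recover)
library(dplyr)

# the published 2x2 for >95% cART adherence (good 33|10, poor 20|20)
or_from_2x2(33, 10, 20, 20)
#> # A tibble: 1 x 6
#>      or ci_low ci_high p_wald log_or se_log_or
#>   <dbl>  <dbl>   <dbl>  <dbl>  <dbl>     <dbl>
#> 1   3.3   1.29    8.45 0.0129   1.19     0.480

# a full synthetic replicate: 90 women, 200 genes, 3 planted risk genes
sc <- sim_scenario(seed = 101)
fx <- simulate_cohort(sc)
g  <- simulate_genotypes(sc, fx)

gm <- g$genotypes |>
  assign_gene_regions(g$gene_map) |>
  annotate_ref_maf(g$ref_maf)
pcs <- genotype_pca(gm)
covars <- tibble(participant_id = fx$truth$participants$participant_id,
                 age = fx$participants$age) |>
  left_join(pcs$scores, by = c(participant_id = "sample"))

scan <- run_burden_scan(gm, fx$truth$participants, covariates = covars,
                        plan = permutation_plan(seed = 7, max_perm = 4000,
                                                stop_threshold = 0.001))
scan$hits
#> # A tibble: 3 x 6
#>   gene     cmc_p   kbac_p cmc_hit kbac_hit classification
#>   <chr>    <dbl>    <dbl> <lgl>   <lgl>    <chr>
#> 1 G0003 0.0448   0.000250 FALSE   TRUE     KBAC-only
#> 2 G0011 0.000250 0.000250 TRUE    TRUE     both
#> 3 G0042 0.000250 0.000250 TRUE    TRUE     both
```

The hit list contains exactly the three genes carrying planted rare-variant
effects. `classification` reads off the mechanism: KBAC-only hits are driven
by rare variants, CMC-only hits by common ones, and `both` means the signal
is visible to both tests (here the planted rare burden is strong enough for
CMC's rare bins too). Exact p-values vary with the permutation seed and the
planted-effect draw.

The whole chain — simulate → phenotype → clinical association → QC/PCA →
burden scan with transcript rerun — also runs as one reproducible unit:

```r
run_pipeline(run_config(out_dir = "my_run", seed = 1))
```

which writes per-stage tab-delimited outputs and a JSON manifest.

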