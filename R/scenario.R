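#' Define a synthetic cohort + genome scenario
#'
#' A `sim_scenario` fully parameterizes one synthetic replicate of the study
#' design: a two-group cohort of women on suppressive cART whose probability of
#' a good CD4 response declines with age, semiannual CD4/viral-load
#' trajectories with missing visits, two-subpopulation genotype substructure
#' (Balding-Nichols model), and genes carrying planted rare- or common-variant
#' burden effects. The same scenario (including `seed`) always regenerates
#' bit-identical fixtures.
#'
#' Defaults emulate the study conditions: 90 participants targeted at roughly
#' 48 good / 42 poor responders, ages ~ N(42, 8) with a per-year odds ratio of
#' a good response of about 0.89, CD4 gains of ~150 cells/mm3/yr (good) vs
#' ~20 (poor) above a nadir near 180 cells/mm3, an 80 copies/mL assay
#' detection limit, and 200 genes x 25 SNPs split across two subpopulations at
#' Fst 0.1.
#'
#' @param seed Integer master seed; fixes all randomness in the replicate.
#' @param n_participants Number of participants (>= 2).
#' @param n_visits Semiannual visits per participant (>= 6: a pre-cART phase
#'   plus at least a one-year response window).
#' @param pre_cart_visits Leading off-therapy visits before cART initiation.
#' @param age_mean,age_sd Age distribution at the start of follow-up (years).
#' @param log_or_age Per-year log-odds of a good response.
#' @param p_good_base Probability of a good response at the mean age.
#' @param gain_good_mean,gain_good_sd Good-group CD4 slope on suppressive cART
#'   (cells/mm3 per year; between-participant sd).
#' @param gain_poor_mean,gain_poor_sd Poor-group CD4 slope.
#' @param cd4_noise_sd Within-participant visit-level CD4 noise (cells/mm3).
#' @param nadir_mean,nadir_sd Nadir CD4 distribution (cells/mm3, truncated
#'   below at 10).
#' @param detection_limit Viral-load assay detection limit (copies/mL).
#' @param blip_prob Per-visit probability of a transient viremic blip on cART.
#' @param missing_rate Per-visit probability that a CD4 or VL value is missing.
#' @param n_genes,variants_per_gene Synthetic exome dimensions.
#' @param fst Fixation index between the two subpopulations, in [0, 0.5].
#' @param pop2_fraction Proportion of samples drawn from subpopulation 2.
#' @param maf_spectrum Length-2 numeric: Beta shape parameters for ancestral
#'   minor-allele frequencies (truncated to [0.001, 0.5]).
#' @param causal_genes Tibble with columns `gene` (id such as `"G0001"`),
#'   `carrier_log_or` (log-odds of carrier status in good vs poor responders)
#'   and `maf_band` (`"rare"` or `"common"`); `NULL` for a fully null genome.
#' @param base_carrier_rate Poor-group carrier probability at planted rare
#'   genes.
#' @param qc_fail_rate Fraction of emitted genotypes given DP or GQ below the
#'   QC thresholds (DP < 8, GQ < 20), to exercise filtering.
#' @param ref_maf_missing_rate Fraction of variants absent from the
#'   reference-MAF lookup (they must fall in the < 1% bin downstream).
#'
#' @return An object of class `sim_scenario` (a named list).
#' @export
#' @examples
#' sc <- sim_scenario(seed = 1, n_participants = 20, n_genes = 5)
#' sc$n_participants
sim_scenario <- function(seed = 1L,
                         n_participants = 90L,
                         n_visits = 16L,
                         pre_cart_visits = 2L,
                         age_mean = 42, age_sd = 8,
                         log_or_age = log(0.894),
                         p_good_base = 48 / 90,
                         gain_good_mean = 150, gain_good_sd = 30,
                         gain_poor_mean = 20, gain_poor_sd = 15,
                         cd4_noise_sd = 25,
                         nadir_mean = 180, nadir_sd = 100,
                         detection_limit = 80,
                         blip_prob = 0.05,
                         missing_rate = 0.05,
                         n_genes = 200L,
                         variants_per_gene = 25L,
                         fst = 0.1,
                         pop2_fraction = 0.5,
                         maf_spectrum = c(0.4, 4),
                         causal_genes = default_causal_genes(),
                         base_carrier_rate = 0.05,
                         qc_fail_rate = 0.02,
                         ref_maf_missing_rate = 0.1) {
  sc <- list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    n_visits = as.integer(n_visits),
    pre_cart_visits = as.integer(pre_cart_visits),
    age_mean = age_mean, age_sd = age_sd,
    log_or_age = log_or_age, p_good_base = p_good_base,
    gain_good_mean = gain_good_mean, gain_good_sd = gain_good_sd,
    gain_poor_mean = gain_poor_mean, gain_poor_sd = gain_poor_sd,
    cd4_noise_sd = cd4_noise_sd,
    nadir_mean = nadir_mean, nadir_sd = nadir_sd,
    detection_limit = detection_limit,
    blip_prob = blip_prob,
    missing_rate = missing_rate,
    n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    fst = fst, pop2_fraction = pop2_fraction,
    maf_spectrum = maf_spectrum,
    causal_genes = causal_genes,
    base_carrier_rate = base_carrier_rate,
    qc_fail_rate = qc_fail_rate,
    ref_maf_missing_rate = ref_maf_missing_rate
  )
  class(sc) <- "sim_scenario"
  validate_scenario(sc)
  sc
}

#' Default planted-effect table: three rare-burden genes
#'
#' Planted genes act as positive controls: effects are sized by power
#' simulation so that detection at the exome-wide permutation threshold
#' (p <= 0.001) is essentially certain at n = 90 (carrier odds ratio
#' exp(4.5) ~ 90 over a 5% poor-group carrier rate).
#'
#' @return Tibble with columns `gene`, `carrier_log_or`, `maf_band`.
#' @export
default_causal_genes <- function() {
  tibble::tibble(
    gene = c("G0003", "G0011", "G0042"),
    carrier_log_or = c(4.5, 4.5, 4.5),
    maf_band = c("rare", "rare", "rare")
  )
}

validate_scenario <- function(sc) {
  probs <- c(sc$p_good_base, sc$blip_prob, sc$missing_rate, sc$pop2_fraction,
             sc$base_carrier_rate, sc$qc_fail_rate, sc$ref_maf_missing_rate)
  assert_that(all(probs >= 0 & probs <= 1), "all probabilities must lie in [0, 1]")
  assert_that(sc$fst >= 0 && sc$fst <= 0.5, "fst must lie in [0, 0.5]")
  assert_that(sc$n_participants >= 2, "n_participants must be >= 2")
  assert_that(sc$n_visits >= 6,
              "n_visits must be >= 6 (pre-cART phase plus a >= 1-year response window)")
  assert_that(sc$pre_cart_visits >= 1 && sc$pre_cart_visits <= sc$n_visits - 4,
              "pre_cart_visits must leave at least 4 on-cART visits")
  assert_that(length(sc$maf_spectrum) == 2 && all(sc$maf_spectrum > 0),
              "maf_spectrum must be two positive Beta shape parameters")
  if (!is.null(sc$causal_genes)) {
    assert_that(all(c("gene", "carrier_log_or", "maf_band") %in% names(sc$causal_genes)),
                "causal_genes needs columns gene, carrier_log_or, maf_band")
    assert_that(all(sc$causal_genes$maf_band %in% c("rare", "common")),
                "maf_band must be 'rare' or 'common'")
  }
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> seed", x$seed, "|", x$n_participants, "participants x",
      x$n_visits, "visits |", x$n_genes, "genes x", x$variants_per_gene,
      "SNPs | fst", x$fst, "\n")
  if (!is.null(x$causal_genes) && nrow(x$causal_genes) > 0) {
    cat("  planted genes:", paste(x$causal_genes$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))
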