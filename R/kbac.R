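#' Hypergeometric kernel weights for multi-marker genotypes
#'
#' Each non-null multi-marker genotype (a distinct rare-variant dosage
#' pattern) gets the weight `P(X <= n_j_cases)` where X counts cases among
#' `n_j` draws without replacement from the pooled sample of `n_cases` cases
#' and `n_controls` controls. Genotypes whose carriers are mostly cases get
#' weights near 1; case-depleted genotypes get small weights.
#'
#' @param case_counts Cases carrying each genotype.
#' @param total_counts Total carriers of each genotype (must be > 0).
#' @param n_cases,n_controls Cohort composition.
#' @return Numeric weights in (0, 1].
#' @export
kbac_weights <- function(case_counts, total_counts, n_cases, n_controls) {
  assert_that(all(total_counts > 0), "genotypes with zero carriers are excluded")
  assert_that(all(case_counts <= total_counts), "case carriers exceed carriers")
  phyper(case_counts, m = n_cases, n = n_controls, k = total_counts)
}

# Group samples by identical rare-variant dosage vectors. Missing dosages are
# treated as non-carrier (0) and counted.
kbac_grouping <- function(gm, variant_idx, rare_maf = 0.05) {
  assert_that("cohort_maf" %in% names(gm$variants),
              "variants carry no cohort_maf")
  maf <- gm$variants$cohort_maf[variant_idx]
  rare_idx <- variant_idx[!is.na(maf) & maf < rare_maf]
  if (length(rare_idx) == 0) {
    return(list(n_rare_markers = 0L))
  }
  sub <- gm$dosage[, rare_idx, drop = FALSE]
  n_missing <- sum(is.na(sub))
  sub[is.na(sub)] <- 0L
  key <- apply(sub, 1, paste, collapse = ",")
  null_key <- paste(rep("0", length(rare_idx)), collapse = ",")
  groups <- match(key, sort(unique(key)))
  group_keys <- sort(unique(key))
  non_null <- which(group_keys != null_key)
  # indicator matrix: non-null genotype groups x samples
  G <- matrix(0L, nrow = length(non_null), ncol = nrow(sub))
  for (r in seq_along(non_null)) G[r, groups == non_null[r]] <- 1L
  list(n_rare_markers = length(rare_idx), rare_idx = rare_idx,
       G = G, group_size = rowSums(G), n_groups = length(non_null),
       n_missing_as_ref = n_missing)
}

# Vectorized KBAC scores for an n x B matrix of phenotypes.
kbac_score_batch <- function(G, group_size, ymat) {
  if (nrow(G) == 0) return(rep(0, ncol(ymat)))
  n <- ncol(G)
  nA <- colSums(ymat)
  nU <- n - nA
  NJA <- G %*% ymat # groups x B: case carriers per genotype
  B <- ncol(ymat)
  k <- nrow(G)
  m_rep <- matrix(rep(nA, each = k), nrow = k)
  u_rep <- matrix(rep(nU, each = k), nrow = k)
  size_rep <- matrix(rep(group_size, times = B), nrow = k)
  W <- phyper(NJA, m = m_rep, n = u_rep, k = size_rep)
  diff <- NJA / m_rep - (size_rep - NJA) / u_rep
  colSums(W * diff)
}

#' KBAC rare-variant burden test
#'
#' Kernel-Based Adaptive Clustering: samples are grouped by their multi-marker
#' genotype over the region's rare variants (cohort MAF strictly below
#' `rare_maf`; missing dosages count as non-carrier with a logged count); each
#' non-null genotype is weighted by the hypergeometric kernel of its observed
#' case enrichment; the score sums weighted differences in genotype frequency
#' between cases and controls. The test is one-sided (risk direction):
#' the permutation p is the fraction of null statistics at least as large as
#' the observed score, with the `+1` correction, and weights are recomputed
#' in every resample. With covariates, the plan's parametric bootstrap redraws
#' phenotypes from the covariates-only null logistic fit.
#'
#' @param gm A [genotype_matrix()].
#' @param variant_idx Indices of the region's variants in `gm`.
#' @param phenotype Binary vector (1 = case/good response) or responder-call
#'   tibble aligned to `gm$samples`.
#' @param covariates Optional matrix/data frame for the adjusted test.
#' @param plan A [permutation_plan()].
#' @param rare_maf Rare cutoff on cohort MAF (default 0.05, strict).
#' @param gene Optional gene label.
#' @return Object of class `kbac_result`; see [tidy.kbac_result()].
#' @export
kbac_test <- function(gm, variant_idx, phenotype, covariates = NULL,
                      plan = permutation_plan(), rare_maf = 0.05,
                      gene = NA_character_) {
  y <- align_phenotype(phenotype, gm$samples)
  ord <- order(gm$samples)

  grp <- kbac_grouping(gm, variant_idx, rare_maf)
  if (grp$n_rare_markers == 0L) {
    abort(paste0("gene ", gene, ": no rare variants below MAF ", rare_maf,
                 "; KBAC not applicable"), class = "cd4recover_no_rare")
  }
  if (grp$n_groups == 0L) {
    # rare sites exist but nobody carries them: the score is identically 0
    return(structure(list(
      gene = gene, n_rare_markers = grp$n_rare_markers,
      n_multimarker_genotypes = 0L, n_missing_as_ref = grp$n_missing_as_ref,
      kbac_score = 0, p_perm = 1, n_perm_used = 0L, exhaustive = FALSE,
      adjusted = !is.null(covariates)
    ), class = "kbac_result"))
  }
  G <- grp$G[, ord, drop = FALSE]
  y <- y[ord]
  covariates <- if (!is.null(covariates)) as.matrix(covariates)[ord, , drop = FALSE]

  score <- kbac_score_batch(G, grp$group_size, matrix(y, ncol = 1))[1]

  null_probs <- NULL
  if (!is.null(covariates)) {
    f0 <- logistic_deviance(cbind(1, covariates), y)
    null_probs <- f0$fitted
  }
  stat_fun <- function(ymat) kbac_score_batch(G, grp$group_size, ymat)
  perm <- permute_p(score, stat_fun, y, plan, null_probs = null_probs)

  structure(list(
    gene = gene, n_rare_markers = grp$n_rare_markers,
    n_multimarker_genotypes = grp$n_groups,
    n_missing_as_ref = grp$n_missing_as_ref,
    kbac_score = score, p_perm = perm$p_perm,
    n_perm_used = perm$n_perm_used, exhaustive = perm$exhaustive,
    adjusted = !is.null(covariates)
  ), class = "kbac_result")
}

#' @export
print.kbac_result <- function(x, ...) {
  cat("<kbac_result>", x$gene, "|", x$n_rare_markers, "rare markers,",
      x$n_multimarker_genotypes, "genotypes | score",
      signif(x$kbac_score, 4), "| p_perm", signif(x$p_perm, 3),
      if (x$adjusted) "(adjusted)" else "(unadjusted)", "\n")
  invisible(x)
}

#' Tidy a KBAC result
#'
#' @param x A `kbac_result`.
#' @param ... Unused.
#' @return One-row tibble mirroring the per-gene report columns.
#' @method tidy kbac_result
#' @export
tidy.kbac_result <- function(x, ...) {
  tibble::tibble(
    gene = x$gene, test = "KBAC", adjusted = x$adjusted,
    n_rare_markers = x$n_rare_markers,
    n_multimarker_genotypes = x$n_multimarker_genotypes,
    statistic = x$kbac_score, p_perm = x$p_perm,
    n_perm_used = x$n_perm_used
  )
}

#' @rdname tidy.kbac_result
#' @method glance kbac_result
#' @export
glance.kbac_result <- function(x, ...) {
  tibble::tibble(gene = x$gene, p_perm = x$p_perm,
                 n_perm_used = x$n_perm_used)
}
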