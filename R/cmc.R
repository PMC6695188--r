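#' Collapse a gene region into per-bin carrier indicators
#'
#' The CMC (Combined Multivariate and Collapsing) design matrix: for each of
#' the five reference-frequency bins, a sample's indicator is 1 when it
#' carries the minor allele (dosage >= 1) at any non-missing variant of that
#' bin within the region. Samples missing at every variant of a bin get
#' indicator 0, with the count of such sample-bin pairs logged. Bins with no
#' variants, or whose indicator is constant across samples, are flagged
#' degenerate and carry no degree of freedom downstream.
#'
#' @param gm A [genotype_matrix()] whose `variants` carry a `bin` column
#'   (see [annotate_ref_maf()]).
#' @param variant_idx Integer indices of the region's variants.
#' @return List of class `cmc_collapse`: `indicators` (samples x 5 matrix,
#'   columns `bin0..bin4`), `bin_counts` (markers per bin), `degenerate`
#'   (logical per bin), `n_all_missing` (logged count).
#' @export
cmc_collapse <- function(gm, variant_idx) {
  assert_that(length(variant_idx) >= 1, "region has zero variants")
  assert_that("bin" %in% names(gm$variants),
              "variants carry no bin assignment; run annotate_ref_maf()")
  bins <- gm$variants$bin[variant_idx]
  n <- length(gm$samples)
  ind <- matrix(0L, nrow = n, ncol = 5,
                dimnames = list(gm$samples, paste0("bin", 0:4)))
  bin_counts <- integer(5)
  n_all_missing <- 0L
  for (b in 0:4) {
    idx <- variant_idx[bins == b]
    bin_counts[b + 1] <- length(idx)
    if (length(idx) == 0) next
    sub <- gm$dosage[, idx, drop = FALSE]
    carrier <- rowSums(sub >= 1L, na.rm = TRUE) > 0
    all_miss <- rowSums(!is.na(sub)) == 0
    n_all_missing <- n_all_missing + sum(all_miss)
    ind[, b + 1] <- as.integer(carrier & !all_miss)
  }
  degenerate <- bin_counts == 0 | apply(ind, 2, function(z) length(unique(z)) == 1)
  structure(list(indicators = ind, bin_counts = bin_counts,
                 degenerate = degenerate, n_all_missing = n_all_missing),
            class = "cmc_collapse")
}

#' CMC burden test with omnibus likelihood-ratio statistic
#'
#' Fits the logistic model `phenotype ~ covariates + non-degenerate bin
#' indicators` and compares it with the covariates-only null by likelihood
#' ratio; the omnibus chi-square has one degree of freedom per non-degenerate
#' bin. The asymptotic p comes from the chi-square distribution, and the
#' permutation p re-evaluates the same statistic under the plan's null
#' resampling scheme (phenotype label permutation when unadjusted; parametric
#' bootstrap from the covariates-only fit when adjusted, unless the plan says
#' otherwise).
#'
#' @param collapse A [cmc_collapse()] result (or indicator matrix).
#' @param phenotype Binary vector (1 = good response) aligned to samples, or
#'   a responder-call tibble.
#' @param covariates Optional numeric matrix / data frame (e.g. age, PC1,
#'   PC2) aligned to samples; `NULL` for the unadjusted test.
#' @param plan A [permutation_plan()], or `NULL` to skip the permutation p.
#' @param gene Optional gene label carried into the result.
#' @return Object of class `cmc_result`; see [tidy.cmc_result()].
#' @export
cmc_test <- function(collapse, phenotype, covariates = NULL, plan = NULL,
                     gene = NA_character_) {
  ind <- if (inherits(collapse, "cmc_collapse")) collapse$indicators else collapse
  samples <- rownames(ind)
  y <- align_phenotype(phenotype, samples %||% seq_len(nrow(ind)))

  # canonical sample order makes permutation p-values invariant to input order
  if (!is.null(samples)) {
    ord <- order(samples)
    ind <- ind[ord, , drop = FALSE]
    y <- y[ord]
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[ord, , drop = FALSE]
  } else if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
  }

  keep <- apply(ind, 2, function(z) length(unique(z)) > 1)
  B <- ind[, keep, drop = FALSE]
  df <- ncol(B)
  X0 <- cbind(`(Intercept)` = rep(1, nrow(ind)), covariates)
  X1 <- cbind(X0, B)

  if (df == 0) {
    res <- new_cmc_result(gene, collapse, df, NA_real_, NA_real_, NA_real_,
                          0L, !is.null(covariates), betas = NULL,
                          flagged = TRUE)
    return(res)
  }

  f0 <- logistic_deviance(X0, y)
  f1 <- logistic_deviance(X1, y)
  lrt <- max(0, f0$deviance - f1$deviance)
  p_asym <- pchisq(lrt, df = df, lower.tail = FALSE)
  flagged <- !f1$converged || any(abs(f1$coef) > 15, na.rm = TRUE)

  perm <- NULL
  if (!is.null(plan)) {
    if (!is.null(covariates) && plan$scheme == "label_permutation") {
      warn("label permutation with covariates does not preserve the covariate-phenotype structure")
    }
    dev0_const <- is.null(covariates) && plan$scheme == "label_permutation"
    stat_fun <- function(ymat) {
      as.vector(cmc_lrt_batch_cpp(X0, X1, ymat,
                                  if (dev0_const) f0$deviance else -1))
    }
    perm <- permute_p(lrt, stat_fun, y, plan, null_probs = f0$fitted)
  }

  betas <- cmc_betas(f1, keep)
  new_cmc_result(gene, collapse, df, lrt, p_asym,
                 perm$p_perm %||% NA_real_, perm$n_perm_used %||% 0L,
                 !is.null(covariates), betas = betas, flagged = flagged,
                 exhaustive = perm$exhaustive %||% FALSE)
}

cmc_betas <- function(fit, keep) {
  co <- fit$coef
  tibble::tibble(term = names(co), beta = unname(co))
}

new_cmc_result <- function(gene, collapse, df, lrt, p_asym, p_perm, n_perm,
                           adjusted, betas, flagged, exhaustive = FALSE) {
  cc <- if (inherits(collapse, "cmc_collapse")) collapse else NULL
  structure(list(
    gene = gene,
    n_markers = if (!is.null(cc)) sum(cc$bin_counts) else NA_integer_,
    bin_counts = if (!is.null(cc)) cc$bin_counts else rep(NA_integer_, 5),
    degenerate = if (!is.null(cc)) cc$degenerate else rep(NA, 5),
    lrt_chi2 = lrt, lrt_df = df, p_asym = p_asym,
    p_perm = p_perm, n_perm_used = n_perm,
    adjusted = adjusted, betas = betas, flagged = flagged,
    exhaustive = exhaustive
  ), class = "cmc_result")
}

#' @export
print.cmc_result <- function(x, ...) {
  cat("<cmc_result>", x$gene, "| markers", x$n_markers, "| LRT",
      signif(x$lrt_chi2, 4), "on", x$lrt_df, "df | p_asym",
      signif(x$p_asym, 3), "| p_perm", signif(x$p_perm, 3),
      if (x$adjusted) "(adjusted)" else "(unadjusted)", "\n")
  invisible(x)
}

#' Tidy a CMC result
#'
#' @param x A `cmc_result`.
#' @param ... Unused.
#' @return One-row tibble mirroring the per-gene report columns.
#' @method tidy cmc_result
#' @export
tidy.cmc_result <- function(x, ...) {
  tibble::tibble(
    gene = x$gene, test = "CMC", adjusted = x$adjusted,
    n_markers = x$n_markers,
    bin0 = x$bin_counts[1], bin1 = x$bin_counts[2], bin2 = x$bin_counts[3],
    bin3 = x$bin_counts[4], bin4 = x$bin_counts[5],
    statistic = x$lrt_chi2, df = x$lrt_df,
    p_asym = x$p_asym, p_perm = x$p_perm, n_perm_used = x$n_perm_used,
    flagged = x$flagged
  )
}

#' @rdname tidy.cmc_result
#' @method glance cmc_result
#' @export
glance.cmc_result <- function(x, ...) {
  tibble::tibble(gene = x$gene, p_perm = x$p_perm, p_asym = x$p_asym,
                 n_perm_used = x$n_perm_used)
}
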