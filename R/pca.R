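#' Ancestry principal components from genotype dosages
#'
#' Standard genotype PCA for population-substructure covariates: each variant
#' is centered by its mean dosage and scaled by `sqrt(2 p (1 - p))` (the
#' binomial standard deviation at its allele frequency), missing dosages are
#' mean-imputed, monomorphic and all-missing variants are dropped, and the
#' leading components of the sample covariance are extracted by singular
#' value decomposition. Component signs are fixed by making each component's
#' largest-magnitude variant loading positive, so results are deterministic
#' and invariant (up to that convention) under sample reordering.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of components to return (default 2; the first
#'   two are the conventional ancestry covariates).
#' @return An object of class `genotype_pca`: list with `scores` (tibble:
#'   `sample`, `PC1`, ...), `loadings` (matrix), `variance_explained`
#'   (fraction per component) and `n_variants_used`.
#' @export
genotype_pca <- function(gm, n_components = 2) {
  d <- gm$dosage
  assert_that(nrow(d) >= n_components + 1, "need at least n_components + 1 samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  n_obs <- colSums(!is.na(d))
  keep <- which(n_obs > 0 & p > 0 & p < 1)
  assert_that(length(keep) >= 1, "no polymorphic variant available")
  x <- d[, keep, drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  for (j in seq_along(keep)) {
    xj <- x[, j]
    xj[is.na(xj)] <- mu[j]
    x[, j] <- xj
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sqrt(2 * p * (1 - p)), "/")

  k <- min(n_components, nrow(z) - 1, ncol(z))
  sv <- svd(z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  for (c_ in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, c_])), c_])
    if (s < 0) {
      loadings[, c_] <- -loadings[, c_]
      scores[, c_] <- -scores[, c_]
    }
  }
  ve <- sv$d^2 / sum(sv$d^2)

  score_tb <- tibble::as_tibble(scores, .name_repair = ~ paste0("PC", seq_len(k)))
  score_tb <- dplyr::bind_cols(tibble::tibble(sample = gm$samples), score_tb)
  structure(list(scores = score_tb, loadings = loadings,
                 variance_explained = ve[seq_len(k)],
                 n_variants_used = length(keep)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("<genotype_pca>", nrow(x$scores), "samples,", x$n_variants_used,
      "variants; variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy genotype_pca
#' @export
tidy.genotype_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample", names_to = "component",
                      values_to = "score")
}

#' @method glance genotype_pca
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 n_variants_used = x$n_variants_used,
                 ve_pc1 = x$variance_explained[1])
}

#' Plot the first two ancestry components
#'
#' @param object A [genotype_pca()] result.
#' @param labels Optional vector (aligned to samples) used to color points,
#'   e.g. self-reported race/ethnicity or simulated subpopulation.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genotype_pca
#' @export
autoplot.genotype_pca <- function(object, labels = NULL, ...) {
  df <- object$scores
  if (!is.null(labels)) df$label <- as.factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(color = .data$label))
}
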