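# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# One participant's visit tibble from parallel vectors.
make_visits <- function(cd4, on_cart = rep(TRUE, length(cd4)),
                        vl_below = rep(TRUE, length(cd4)),
                        vl = rep(NA_real_, length(cd4)),
                        id = "P1", detection_limit = 80) {
  tibble::tibble(
    participant_id = id,
    visit_index = seq_along(cd4),
    cd4 = as.numeric(cd4),
    vl = as.numeric(vl),
    vl_below_detection = vl_below,
    detection_limit = detection_limit,
    on_cart = on_cart,
    adherence = NA_character_
  )
}

# A suppressed-on-cART course: pre off-cART visits, then cART with given
# CD4 gain per year starting from `nadir`.
make_course <- function(years_suppressed, gain_per_year, nadir = 100,
                        pre = 2, id = "P1") {
  n_on <- years_suppressed * 2 + 1
  cd4 <- c(rep(nadir, pre),                         # pre-cART
           nadir,                                   # first cART visit
           nadir + gain_per_year * (1:n_on) / 2)    # suppressed visits
  nv <- length(cd4)
  make_visits(
    cd4,
    on_cart = c(rep(FALSE, pre), rep(TRUE, nv - pre)),
    vl_below = c(rep(FALSE, pre + 1), rep(TRUE, nv - pre - 1)),
    vl = c(rep(50000, pre), 5000, rep(NA, nv - pre - 1)),
    id = id
  )
}

# Tiny genotype matrix from an explicit dosage matrix.
make_gm <- function(dosage, ref_maf = NULL, gene = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  v <- tibble::tibble(
    chrom = "1", pos = seq_len(m) * 1000L,
    id = paste0("v", seq_len(m)),
    ref = rep("A", m), alt = rep("G", m)
  )
  if (!is.null(gene)) v$gene <- gene
  gm <- genotype_matrix(dosage, v, sprintf("S%02d", seq_len(n)))
  if (!is.null(ref_maf)) {
    gm$variants$ref_maf <- ref_maf
    gm$variants$bin <- assign_bin(ref_maf)
  }
  gm
}

# Write a small VCF with explicit body lines (header supplied here).
write_test_vcf <- function(body_lines, samples = c("S1", "S2", "S3"),
                           format = "GT:DP:GQ") {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body_lines), path)
  path
}

# Independent brute-force HWE exact p: enumerate heterozygote counts using
# plain binomial coefficients (no shared code with the implementation).
brute_hwe_p <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  nm <- 2 * n_hom_minor + n_het
  hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  prob <- vapply(hets, function(h) {
    hm <- (nm - h) / 2
    hM <- n - h - hm
    exp(lgamma(n + 1) - lgamma(h + 1) - lgamma(hm + 1) - lgamma(hM + 1) +
          h * log(2) + lgamma(nm + 1) + lgamma(2 * n - nm + 1) -
          lgamma(2 * n + 1))
  }, numeric(1))
  obs <- prob[match(n_het, hets)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# Independent exhaustive permutation p over all case assignments at small n.
# stat_fun(y01) returns the statistic for one 0/1 phenotype vector.
exhaustive_perm_p <- function(stat_fun, y) {
  n <- length(y); k <- sum(y)
  idx <- utils::combn(n, k)
  obs <- stat_fun(y)
  stats <- apply(idx, 2, function(ii) {
    yy <- numeric(n); yy[ii] <- 1
    stat_fun(yy)
  })
  mean(stats >= obs - 1e-12)
}

# Brute-force logistic log-likelihood maximization via optim (independent of
# the package's IRLS path).
brute_logistic_deviance <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(numeric(ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  2 * fit$value
}
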