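test_that("VCF ingestion applies DP/GQ masking with non-strict survivals", {
  body <- c(
    # DP 7 masked for S1; DP 8 & GQ 20 retained for S2; GQ 19 masked for S3
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT:DP:GQ\t0/1:7:99\t1/1:8:20\t0/1:50:19",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT:DP:GQ\t0/0:50:99\t0/1:50:99\t./.:50:99"
  )
  gm <- read_vcf(write_test_vcf(body))
  alt <- gm$dosage
  alt[, gm$variants$flipped] <- 2L - alt[, gm$variants$flipped]
  expect_identical(alt[, 1], c(S1 = NA_integer_, S2 = 2L, S3 = NA_integer_))
  expect_identical(alt[, 2], c(S1 = 0L, S2 = 1L, S3 = NA_integer_))
  expect_equal(gm$log$n_masked, 2)
})

test_that("multi-allelic and non-SNP records are skipped and counted", {
  body <- c(
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT:DP:GQ\t0/1:50:99\t0/0:50:99\t0/0:50:99",
    "1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT:DP:GQ\t0/1:50:99\t0/2:50:99\t0/0:50:99",
    "1\t300\tv3\tAT\tA\t.\tPASS\t.\tGT:DP:GQ\t0/1:50:99\t0/0:50:99\t0/0:50:99"
  )
  gm <- read_vcf(write_test_vcf(body))
  expect_equal(nrow(gm$variants), 1)
  expect_equal(gm$log$n_skipped_multiallelic, 1)
  expect_equal(gm$log$n_skipped_non_snp, 1)
})

test_that("raising QC thresholds never increases call rate", {
  sc <- sim_scenario(seed = 17, n_participants = 20, n_genes = 2,
                     variants_per_gene = 10, causal_genes = NULL,
                     qc_fail_rate = 0.15)
  fx <- simulate_cohort(sc)
  g <- simulate_genotypes(sc, fx)
  d <- withr::local_tempdir()
  write_genotypes(g, d)
  loose <- read_vcf(file.path(d, "genotypes.vcf"), dp_min = 8, gq_min = 20)
  strict <- read_vcf(file.path(d, "genotypes.vcf"), dp_min = 20, gq_min = 40)
  cr <- function(gm) colMeans(!is.na(gm$dosage))
  expect_true(all(cr(strict) <= cr(loose) + 1e-12))
})

test_that("reference-frequency bins partition [0, 0.5] with absent as rarest", {
  expect_identical(assign_bin(c(0.004, 0.009999)), c(0L, 0L))
  expect_identical(assign_bin(c(0.01, 0.024)), c(1L, 1L))
  expect_identical(assign_bin(c(0.025, 0.049)), c(2L, 2L))
  expect_identical(assign_bin(c(0.05, 0.0999)), c(3L, 3L))
  expect_identical(assign_bin(c(0.10, 0.5)), c(4L, 4L))
  expect_identical(assign_bin(NA_real_), 0L)
  expect_error(assign_bin(0.6), "orientation")
  # total function on a grid of the whole domain
  grid <- seq(0, 0.5, by = 0.001)
  bins <- assign_bin(grid)
  expect_true(all(bins %in% 0:4))
  expect_true(all(diff(bins) >= 0))
})

test_that("the exact HWE test matches independent enumeration", {
  expect_equal(hwe_exact_p(49, 42, 9), brute_hwe_p(49, 42, 9), tolerance = 1e-12)
  # sweep all tables with up to 60 alleles
  for (n in c(5, 10, 17, 30)) {
    for (nm in 1:n) {
      hets <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
      for (h in hets) {
        hm <- (nm - h) / 2
        expect_equal(hwe_exact_p(n - h - hm, h, hm), brute_hwe_p(n - h - hm, h, hm),
                     tolerance = 1e-10)
      }
    }
  }
  # monomorphic sites are compatible with HWE by definition
  expect_equal(hwe_exact_p(25, 0, 0), 1)
})

test_that("per-SNP statistics match hand computations", {
  # 20 samples all heterozygous: het ratio 2, HWE p tiny
  d <- matrix(1L, nrow = 20, ncol = 1)
  gm <- make_gm(d)
  y <- rep(c(1, 0), 10)
  st <- per_snp_stats(gm, y)
  expect_equal(st$cohort_maf, 0.5)
  expect_equal(st$het_ratio, 2)
  expect_lt(st$hwe_p, 0.001)
  expect_equal(st$call_rate, 1)

  # perfect HWE at p = 0.5 (25/50/25)
  d2 <- matrix(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), ncol = 1)
  st2 <- per_snp_stats(make_gm(d2), rep(c(1, 0), 50))
  expect_equal(st2$het_ratio, 1)

  # monomorphic variant: HWE p 1, no association, undefined het ratio
  d3 <- matrix(0L, nrow = 10, ncol = 1)
  st3 <- per_snp_stats(make_gm(d3), rep(c(1, 0), 5))
  expect_equal(st3$hwe_p, 1)
  expect_true(is.na(st3$het_ratio))
  expect_true(is.na(st3$assoc_p))

  # allelic Fisher association equals a direct fisher.test
  set.seed(8)
  d4 <- matrix(rbinom(40, 2, 0.3), ncol = 2)
  y4 <- rep(c(1, 0), 10)
  st4 <- per_snp_stats(make_gm(d4), y4)
  for (j in 1:2) {
    a <- sum(d4[y4 == 1, j]); b <- 2 * 10 - a
    c_ <- sum(d4[y4 == 0, j]); d_ <- 2 * 10 - c_
    expect_equal(st4$assoc_p[j],
                 fisher.test(matrix(c(a, c_, b, d_), 2))$p.value)
    expect_equal(st4$assoc_or[j], (a * d_) / (b * c_))
  }
})

test_that("gene and reference annotations land on the right variants", {
  d <- matrix(0L, nrow = 4, ncol = 3)
  d[1, ] <- 1L
  gm <- make_gm(d) # pos 1000, 2000, 3000
  map <- tibble::tibble(gene = c("GA", "GA", "GB"),
                        transcript = c("GA.t1", "GA.t2", "GB.t1"),
                        chrom = "1",
                        start = c(500, 500, 2500), end = c(2400, 1500, 3500))
  gm <- assign_gene_regions(gm, map)
  expect_equal(gm$variants$gene, c("GA", "GA", "GB"))
  expect_equal(gm$variants$transcripts[[1]], c("GA.t1", "GA.t2"))
  expect_equal(gm$variants$transcripts[[2]], "GA.t1")

  ref <- tibble::tibble(chrom = "1", pos = c(1000L, 3000L),
                        ref = "A", alt = "G", ref_maf = c(0.2, 0.004))
  gm <- annotate_ref_maf(gm, ref)
  expect_equal(gm$variants$bin, c(4L, 0L, 0L)) # absent pos 2000 -> bin 0
})

test_that("genotype PCA is deterministic, sign-fixed and separates structure", {
  # single polymorphic variant: one component explains everything
  d <- matrix(c(0L, 1L, 2L, 1L, 0L, 0L), ncol = 2)
  d[, 2] <- 0L
  p <- genotype_pca(make_gm(d), n_components = 1)
  expect_equal(p$variance_explained[1], 1)
  expect_equal(p$n_variants_used, 1)

  # duplicated samples give duplicated score rows
  set.seed(12)
  d2 <- matrix(rbinom(60, 2, 0.4), nrow = 6)
  d2 <- rbind(d2, d2[1, , drop = FALSE])
  p2 <- genotype_pca(make_gm(d2))
  expect_equal(unlist(p2$scores[7, -1]), unlist(p2$scores[1, -1]),
               tolerance = 1e-10)

  # sample reordering leaves scores invariant (up to the sign convention)
  gm3 <- make_gm(matrix(rbinom(200, 2, 0.3), nrow = 10))
  p3 <- genotype_pca(gm3)
  ord <- sample(10)
  gm4 <- subset_samples(gm3, gm3$samples[ord])
  p4 <- genotype_pca(gm4)
  expect_equal(abs(p4$scores$PC1), abs(p3$scores$PC1[ord]), tolerance = 1e-9)

  # variance fractions are non-increasing
  expect_true(all(diff(p3$variance_explained) <= 1e-12))
})
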