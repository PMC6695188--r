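# Shared toy fixture: 8 samples, 1 rare variant pattern that can be enumerated
# exhaustively (choose(8, 4) = 70 case assignments).
toy_gm <- function() {
  d <- matrix(0L, nrow = 8, ncol = 3)
  d[c(1, 2, 5), 1] <- 1L   # rare carriers
  d[3, 2] <- 1L            # second rare variant
  d[, 3] <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L) # common variant
  make_gm(d, ref_maf = c(0.004, 0.004, 0.3))
}

test_that("CMC collapsing matches hand enumeration and flags degeneracy", {
  d <- matrix(0L, nrow = 6, ncol = 4)
  d[1, 1] <- 1L            # bin-0 carrier
  d[2, 2] <- 2L            # bin-0 homozygote
  d[c(3, 4), 3] <- 1L      # bin-4 carriers
  d[5, 4] <- NA            # missing at a bin-4 variant counts as non-carrier
  gm <- make_gm(d, ref_maf = c(0.002, 0.004, 0.2, 0.3))
  cc <- cmc_collapse(gm, 1:4)
  expect_equal(cc$bin_counts, c(2L, 0L, 0L, 0L, 2L))
  expect_equal(unname(cc$indicators[, "bin0"]), c(1, 1, 0, 0, 0, 0))
  expect_equal(unname(cc$indicators[, "bin4"]), c(0, 0, 1, 1, 0, 0))
  expect_equal(unname(cc$degenerate), c(FALSE, TRUE, TRUE, TRUE, FALSE))

  # all wild-type region: everything degenerate, test has no degrees of freedom
  gm0 <- make_gm(matrix(0L, 5, 2), ref_maf = c(0.004, 0.004))
  cc0 <- cmc_collapse(gm0, 1:2)
  expect_true(all(cc0$degenerate))
  r0 <- cmc_test(cc0, rep(c(1, 0), c(2, 3)))
  expect_true(r0$flagged)
  expect_true(is.na(r0$lrt_chi2))
  expect_error(cmc_collapse(gm0, integer(0)), "zero variants")
})

test_that("CMC omnibus LRT equals brute-force nested likelihood maximization", {
  set.seed(31)
  for (i in 1:10) {
    n <- 40
    ind <- cbind(bin0 = rbinom(n, 1, 0.3), bin4 = rbinom(n, 1, 0.5))
    rownames(ind) <- sprintf("S%02d", 1:n)
    y <- rbinom(n, 1, plogis(0.8 * ind[, 1]))
    covar <- cbind(age = rnorm(n))
    r <- cmc_test(ind, y, covariates = covar)
    X0 <- cbind(1, covar)
    X1 <- cbind(X0, ind)
    brute <- brute_logistic_deviance(X0, y) - brute_logistic_deviance(X1, y)
    expect_equal(r$lrt_chi2, brute, tolerance = 1e-6)
    expect_equal(r$p_asym, pchisq(r$lrt_chi2, r$lrt_df, lower.tail = FALSE))
  }
})

test_that("KBAC weights equal closed-form hypergeometric probabilities", {
  # all three carriers are cases in a 50/50 cohort of 100
  expect_equal(kbac_weights(3, 3, 50, 50), 1)
  # a single carrier who is a control
  expect_equal(kbac_weights(0, 1, 50, 50), 0.5)
  # two carriers split 1/1: P(X <= 1) = 1 - P(X = 2)
  expect_equal(kbac_weights(1, 2, 50, 50), 1 - (50 * 49) / (100 * 99))
  # vectorized, and bounded in (0, 1]
  w <- kbac_weights(0:3, rep(3, 4), 50, 50)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w) > 0))
  expect_error(kbac_weights(1, 0, 50, 50), "zero carriers")
})

test_that("toy permutation p-values equal exhaustive enumeration", {
  gm <- toy_gm()
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  plan <- permutation_plan(seed = 3, max_perm = 1000)

  kb <- kbac_test(gm, 1:3, y, plan = plan, rare_maf = 0.3, gene = "toy")
  expect_true(kb$exhaustive)
  expect_equal(kb$n_perm_used, choose(8, 4))
  # independent oracle: direct KBAC score over every case assignment
  kb_stat <- function(yy) {
    nA <- sum(yy); nU <- length(yy) - nA
    d <- gm$dosage[, gm$variants$cohort_maf < 0.3, drop = FALSE]
    key <- apply(d, 1, paste, collapse = "")
    out <- 0
    for (k in setdiff(unique(key), paste(rep("0", ncol(d)), collapse = ""))) {
      sel <- key == k
      njA <- sum(yy[sel])
      w <- phyper(njA, nA, nU, sum(sel))
      out <- out + w * (njA / nA - (sum(sel) - njA) / nU)
    }
    out
  }
  expect_equal(kb$p_perm, exhaustive_perm_p(kb_stat, y), tolerance = 1e-12)

  cc <- cmc_collapse(gm, 1:3)
  cm <- cmc_test(cc, y, plan = plan, gene = "toy")
  expect_true(cm$exhaustive)
  cm_stat <- function(yy) {
    ind <- cc$indicators[, !cc$degenerate, drop = FALSE]
    suppressWarnings(
      glm(yy ~ 1, family = binomial())$deviance -
        glm(yy ~ ind, family = binomial())$deviance
    )
  }
  expect_equal(cm$p_perm, exhaustive_perm_p(cm_stat, y), tolerance = 1e-9)
})

test_that("KBAC is one-sided: label swap deflates a risk signal", {
  set.seed(22)
  d <- matrix(0L, nrow = 60, ncol = 4)
  carriers <- c(1:12, 31:32) # cases 1:30 strongly enriched
  d[cbind(carriers, sample(1:4, length(carriers), TRUE))] <- 1L
  gm <- make_gm(d, ref_maf = rep(0.004, 4))
  y <- rep(c(1, 0), each = 30)
  plan <- permutation_plan(seed = 9, max_perm = 2000, adaptive = FALSE)
  risk <- kbac_test(gm, 1:4, y, plan = plan)
  swap <- kbac_test(gm, 1:4, 1 - y, plan = plan)
  expect_gt(risk$kbac_score, 0)
  expect_lt(risk$p_perm, 0.01)
  expect_gt(swap$p_perm, 0.5)
})

test_that("permutation p-values are reproducible and order-invariant", {
  sc <- sim_scenario(seed = 51, n_participants = 30, n_genes = 4,
                     variants_per_gene = 8, causal_genes = NULL)
  fx <- simulate_cohort(sc)
  g <- simulate_genotypes(sc, fx)
  gm <- annotate_ref_maf(g$genotypes, g$ref_maf)
  y <- fx$truth$participants
  idx <- which(gm$variants$gene == "G0002")
  plan <- permutation_plan(seed = 77, max_perm = 300)

  k1 <- kbac_test(gm, idx, y, plan = plan)
  k2 <- kbac_test(gm, idx, y, plan = plan)
  expect_identical(k1$p_perm, k2$p_perm)

  ord <- rev(seq_along(gm$samples))
  gm_r <- subset_samples(gm, gm$samples[ord])
  gm_r$variants <- gm$variants # keep cohort_maf/bins identical
  k3 <- kbac_test(gm_r, idx, y[ord, ], plan = plan)
  expect_identical(k1$p_perm, k3$p_perm)

  c1 <- cmc_test(cmc_collapse(gm, idx), y, plan = plan)
  c3 <- cmc_test(cmc_collapse(gm_r, idx), y[ord, ], plan = plan)
  expect_identical(c1$p_perm, c3$p_perm)
})

test_that("burden scan gates hits, attributes mechanism, and respects thresholds", {
  sc <- sim_scenario(
    seed = 1, n_participants = 90, n_genes = 12, variants_per_gene = 8,
    causal_genes = tibble::tibble(
      gene = c("G0002", "G0007"),
      carrier_log_or = c(4.5, 3.0),
      maf_band = c("rare", "common")
    )
  )
  fx <- simulate_cohort(sc)
  g <- simulate_genotypes(sc, fx)
  gm <- assign_gene_regions(g$genotypes, g$gene_map)
  gm <- annotate_ref_maf(gm, g$ref_maf)
  y <- fx$truth$participants
  plan <- permutation_plan(seed = 4, max_perm = 2000, stop_threshold = 0.005)

  scan <- run_burden_scan(gm, y, plan = plan, mode = "candidate",
                          candidate_genes = c("G0002", "G0007", "G0010"),
                          permute_unadjusted = TRUE)
  expect_equal(scan$threshold, 0.05)
  expect_true("G0002" %in% scan$hits$gene)
  h7 <- scan$hits[scan$hits$gene == "G0007", ]
  expect_equal(h7$classification, "CMC-only") # common-variant mechanism
  expect_false("G0010" %in% scan$hits$gene)

  # a zero threshold empties the hit list
  scan0 <- run_burden_scan(gm, y, plan = plan, mode = "exome", threshold = 0)
  expect_equal(nrow(scan0$hits), 0)

  # sample mismatch is a hard error
  bad <- y[1:10, ]
  expect_error(run_burden_scan(gm, bad, plan = plan), "phenotype|samples")
})

test_that("transcript rerun restricts hits to transcript intervals", {
  sc <- sim_scenario(
    seed = 6, n_participants = 90, n_genes = 6, variants_per_gene = 20,
    causal_genes = tibble::tibble(gene = "G0002", carrier_log_or = 4.5,
                                  maf_band = "rare")
  )
  fx <- simulate_cohort(sc)
  g <- simulate_genotypes(sc, fx)
  gm <- assign_gene_regions(g$genotypes, g$gene_map)
  gm <- annotate_ref_maf(gm, g$ref_maf)
  y <- fx$truth$participants
  plan <- permutation_plan(seed = 2, max_perm = 1000, stop_threshold = 0.005)

  scan <- run_burden_scan(gm, y, plan = plan, mode = "exome", threshold = 0.01)
  expect_true("G0002" %in% scan$hits$gene)
  tx <- transcript_rerun(scan, gm, g$gene_map, y, plan = plan)
  expect_true(all(tx$gene %in% scan$hits$gene))

  # the full-span transcript reproduces the gene-level statistic exactly
  full <- tx[tx$transcript == "G0002.t1" & tx$test == "KBAC", ]
  gene_row <- scan$results[scan$results$gene == "G0002" &
                             scan$results$test == "KBAC", ]
  expect_equal(full$statistic, gene_row$statistic)
  # planted signal sits in the first half: second-half transcript is null
  t2 <- tx[tx$transcript == "G0002.t2" & tx$test == "KBAC", ]
  t3 <- tx[tx$transcript == "G0002.t3" & tx$test == "KBAC", ]
  expect_lt(t2$p_perm, 0.01)
  expect_gt(t3$p_perm, 0.05)

  # a scan with no hits yields no transcript rows
  scan0 <- run_burden_scan(gm, y, plan = plan, mode = "exome", threshold = 0)
  tx0 <- transcript_rerun(scan0, gm, g$gene_map, y, plan = plan)
  expect_equal(nrow(tx0), 0)
})
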