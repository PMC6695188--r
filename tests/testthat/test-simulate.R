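test_that("scenario validation rejects impossible designs", {
  expect_error(sim_scenario(n_visits = 5), "n_visits")
  expect_error(sim_scenario(fst = 0.7), "fst")
  expect_error(sim_scenario(n_participants = 1), "n_participants")
  expect_error(
    simulate_genotypes(
      sim_scenario(seed = 1, n_participants = 10, variants_per_gene = 3,
                   n_genes = 5,
                   causal_genes = tibble::tibble(gene = "G0001",
                                                 carrier_log_or = 2,
                                                 maf_band = "rare")),
      tibble::tibble(participant_id = sprintf("P%03d", 1:10),
                     group = rep(c("GOOD", "POOR"), 5))),
    "incompatible"
  )
})

test_that("same seed gives identical fixtures; zero missing rate gives none", {
  sc <- sim_scenario(seed = 11, n_participants = 12, n_genes = 4,
                     variants_per_gene = 6, causal_genes = NULL)
  fx1 <- simulate_cohort(sc)
  fx2 <- simulate_cohort(sc)
  expect_identical(fx1$visits, fx2$visits)
  expect_identical(fx1$participants, fx2$participants)
  g1 <- simulate_genotypes(sc, fx1)
  g2 <- simulate_genotypes(sc, fx2)
  expect_identical(g1$genotypes$dosage, g2$genotypes$dosage)
  expect_identical(g1$ref_maf, g2$ref_maf)

  sc0 <- sim_scenario(seed = 11, n_participants = 12, missing_rate = 0,
                      causal_genes = NULL, n_genes = 2, variants_per_gene = 5)
  fx0 <- simulate_cohort(sc0)
  expect_false(anyNA(fx0$visits$cd4))
  expect_false(anyNA(fx0$visits$vl_below_detection))
})

test_that("cohort structure follows the design", {
  sc <- sim_scenario(seed = 5, n_participants = 30, causal_genes = NULL,
                     n_genes = 2, variants_per_gene = 5, missing_rate = 0)
  fx <- simulate_cohort(sc)
  expect_setequal(fx$visits$participant_id, fx$participants$participant_id)
  expect_true(all(fx$truth$participants$group %in% c("GOOD", "POOR")))
  # pre-cART visits are off therapy and viremic
  pre <- dplyr::filter(fx$visits, visit_index <= sc$pre_cart_visits)
  expect_true(all(!pre$on_cart))
  expect_true(all(!pre$vl_below_detection))
  expect_true(all(pre$vl > pre$detection_limit))
  # visit indices strictly increasing per participant
  ok <- fx$visits |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(mono = all(diff(visit_index) > 0))
  expect_true(all(ok$mono))
})

test_that("fst = 0 collapses the two subpopulation frequency vectors", {
  sc <- sim_scenario(seed = 8, n_participants = 10, fst = 0, n_genes = 3,
                     variants_per_gene = 8, causal_genes = NULL)
  fx <- simulate_cohort(sc)
  g <- simulate_genotypes(sc, fx)
  expect_identical(g$freqs$p1, g$freqs$p2)
  expect_identical(g$freqs$p1, g$freqs$p0)
})

test_that("marginal allele frequency converges to the subpopulation mixture", {
  sc <- sim_scenario(seed = 13, n_participants = 5000, n_visits = 6,
                     n_genes = 2, variants_per_gene = 10, causal_genes = NULL)
  truth <- tibble::tibble(participant_id = sprintf("P%04d", 1:5000),
                          group = rep(c("GOOD", "POOR"), 2500))
  g <- simulate_genotypes(sc, truth)
  w2 <- mean(g$subpop$subpop == 2)
  expected <- (1 - w2) * g$freqs$p1 + w2 * g$freqs$p2
  alt_freq <- ifelse(g$genotypes$variants$flipped,
                     1 - g$genotypes$variants$cohort_maf,
                     g$genotypes$variants$cohort_maf)
  se <- sqrt(expected * (1 - expected) / (2 * 5000))
  expect_true(all(abs(alt_freq - expected) <= 3 * se + 1e-9))
})

test_that("planted rare effects separate the response groups and stay rare", {
  sc <- sim_scenario(seed = 21)
  fx <- simulate_cohort(sc)
  g <- simulate_genotypes(sc, fx)
  gm <- g$genotypes
  good <- fx$truth$participants$group == "GOOD"
  for (cg in sc$causal_genes$gene) {
    idx <- which(gm$variants$gene == cg)[1:10]
    expect_true(all(gm$variants$cohort_maf[idx] < 0.05))
    carrier <- rowSums(gm$dosage[, idx, drop = FALSE] >= 1) > 0
    expect_gt(mean(carrier[good]), mean(carrier[!good]) + 0.3)
  }
})

test_that("written fixtures round-trip as plain text", {
  sc <- sim_scenario(seed = 3, n_participants = 8, n_genes = 2,
                     variants_per_gene = 4, causal_genes = NULL)
  fx <- simulate_cohort(sc)
  g <- simulate_genotypes(sc, fx)
  d <- withr::local_tempdir()
  write_cohort(fx, d)
  write_genotypes(g, d)
  back <- read_cohort(d)
  expect_equal(nrow(back$visits), nrow(fx$visits))
  expect_equal(back$visits$cd4, fx$visits$cd4)
  gm <- read_vcf(file.path(d, "genotypes.vcf"))
  # after masking, retained genotypes agree with the simulated dosages
  raw <- g$genotypes$dosage
  keep <- !is.na(gm$dosage)
  flip_sim <- g$genotypes$variants$flipped
  flip_read <- gm$variants$flipped
  alt_read <- gm$dosage
  alt_read[, flip_read] <- 2L - alt_read[, flip_read]
  alt_sim <- raw
  alt_sim[, flip_sim] <- 2L - alt_sim[, flip_sim]
  expect_identical(alt_read[keep], alt_sim[keep])
})
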