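test_that("short CD4 gaps are interpolated only under constant cART status", {
  cfg <- phenotype_config()
  v <- make_visits(c(300, NA, 340))
  out <- impute_gaps(v, cfg)
  expect_equal(out$cd4, c(300, 320, 340))
  expect_equal(out$imputed_cd4, c(FALSE, TRUE, FALSE))

  # run of three exceeds the two-visit limit
  v3 <- make_visits(c(300, NA, NA, NA, 400))
  expect_equal(impute_gaps(v3, cfg)$cd4, c(300, NA, NA, NA, 400))

  # cART start inside the span blocks imputation
  vc <- make_visits(c(300, NA, 340), on_cart = c(FALSE, TRUE, TRUE))
  expect_equal(impute_gaps(vc, cfg)$cd4, c(300, NA, 340))

  # leading/trailing gaps have no flank and stay missing
  ve <- make_visits(c(NA, 300, 340, NA))
  expect_equal(impute_gaps(ve, cfg)$cd4, c(NA, 300, 340, NA))
})

test_that("viral-load status imputation needs agreeing flanks", {
  cfg <- phenotype_config()
  v <- make_visits(c(300, 310, 320), vl_below = c(TRUE, NA, TRUE))
  out <- impute_gaps(v, cfg)
  expect_equal(out$vl_below_detection, c(TRUE, TRUE, TRUE))
  expect_equal(out$imputed_vl, c(FALSE, TRUE, FALSE))

  vd <- make_visits(c(300, 310, 320), vl_below = c(TRUE, NA, FALSE))
  expect_equal(impute_gaps(vd, cfg)$vl_below_detection, c(TRUE, NA, FALSE))
})

test_that("imputation never alters measured values", {
  set.seed(4)
  for (i in 1:20) {
    cd4 <- ifelse(runif(10) < 0.3, NA, round(runif(10, 100, 600)))
    v <- make_visits(cd4, vl_below = sample(c(TRUE, FALSE, NA), 10, TRUE))
    out <- impute_gaps(v, phenotype_config())
    measured <- !is.na(cd4)
    expect_identical(out$cd4[measured], cd4[measured])
  }
})

test_that("CD4 smoothing averages a shrinking centered window", {
  v <- smooth_cd4(make_visits(c(100, 200, 300)), phenotype_config())
  expect_equal(v$smoothed_cd4, c(150, 200, 250))
  # constants are a fixed point
  vc <- smooth_cd4(make_visits(rep(250, 4)), phenotype_config())
  expect_equal(vc$smoothed_cd4, rep(250, 4))
  # missing neighbors drop out of the mean; missing values stay missing
  vm <- smooth_cd4(make_visits(c(100, NA, 300, 500)), phenotype_config())
  expect_equal(vm$smoothed_cd4, c(100, NA, 400, 400))
})

test_that("visit codes follow the response taxonomy", {
  cfg <- phenotype_config()
  # never on cART, viremic, flat CD4: determinate visits are stable off-ART
  v <- make_visits(rep(400, 6), on_cart = rep(FALSE, 6),
                   vl_below = rep(FALSE, 6), vl = rep(30000, 6)) |>
    smooth_cd4(cfg) |> classify_visits(cfg)
  expect_true(all(v$code[3:6] == "OFF_ART_VIREMIC_STABLE"))
  expect_true(all(v$code[1:2] == "NOT_DETERMINED"))

  # suppressed with strong trailing gain vs minimal gain
  cd4 <- c(100, 100, 100, 175, 250, 325, 400)
  v2 <- make_visits(cd4, on_cart = c(FALSE, rep(TRUE, 6)),
                    vl_below = c(FALSE, FALSE, rep(TRUE, 5)),
                    vl = c(5e4, 5e3, rep(NA, 5))) |>
    smooth_cd4(cfg) |> classify_visits(cfg)
  expect_equal(v2$code[2], "FIRST_CART")
  expect_true(all(v2$code[5:7] == "CART_SUPPRESSED"))

  flat <- c(100, 100, 100, 105, 110, 115, 120)
  v3 <- make_visits(flat, on_cart = c(FALSE, rep(TRUE, 6)),
                    vl_below = c(FALSE, FALSE, rep(TRUE, 5)),
                    vl = c(5e4, 5e3, rep(NA, 5))) |>
    smooth_cd4(cfg) |> classify_visits(cfg)
  expect_true(all(v3$code[5:7] == "CART_SUPPRESSED_MINIMAL_GAIN"))

  # viremia on cART and reinitiation after a gap
  v4 <- make_visits(rep(300, 6),
                    on_cart = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
                    vl_below = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
                    vl = c(NA, 500, 2e4, 2e4, 900, NA)) |>
    smooth_cd4(cfg) |> classify_visits(cfg)
  expect_equal(v4$code[1], "FIRST_CART")
  expect_equal(v4$code[2], "CART_VIREMIC")
  expect_true(all(v4$code[3:4] == "SHORT_OFF_ART_VIREMIC_DECLINING"))
  expect_equal(v4$code[5], "REINITIATED_CART")

  # missing suppression status on cART cannot be classified
  v5 <- make_visits(rep(300, 4), on_cart = rep(TRUE, 4),
                    vl_below = c(TRUE, TRUE, NA, TRUE)) |>
    smooth_cd4(cfg) |> classify_visits(cfg)
  expect_equal(v5$code[3], "NOT_DETERMINED")
})

test_that("responder calls implement the rolling-year rules", {
  cfg <- phenotype_config()
  participants <- tibble::tibble(participant_id = "P1", nadir_cd4 = 100,
                                 age = 40)
  good <- phenotype_cohort(make_course(5, 150), participants, cfg)$calls
  expect_equal(good$group, "GOOD")
  expect_equal(good$suppressed_years, 5)
  expect_gt(good$gain_above_nadir, 0)

  poor <- phenotype_cohort(make_course(2, 10), participants, cfg)$calls
  expect_equal(poor$group, "POOR")

  # a single suppressed visit is insufficient observation
  one <- phenotype_cohort(make_course(0, 150), participants, cfg)$calls
  expect_equal(one$group, "INDETERMINATE")

  # intermediate gains (between the poor and good thresholds) qualify neither
  mid <- phenotype_cohort(make_course(3, 75), participants, cfg)$calls
  expect_equal(mid$group, "INDETERMINATE")
})

test_that("phenotyping chain is idempotent", {
  cfg <- phenotype_config()
  sc <- sim_scenario(seed = 31, n_participants = 10, n_genes = 2,
                     variants_per_gene = 5, causal_genes = NULL)
  v <- simulate_cohort(sc)$visits
  once <- v |> impute_gaps(cfg) |> smooth_cd4(cfg) |> classify_visits(cfg)
  twice <- once |>
    dplyr::select(-"smoothed_cd4", -"code") |>
    impute_gaps(cfg) |> smooth_cd4(cfg) |> classify_visits(cfg)
  expect_equal(twice$cd4, once$cd4)
  expect_equal(twice$smoothed_cd4, once$smoothed_cd4)
  expect_equal(twice$code, once$code)
})

test_that("raising the good-gain threshold never creates a GOOD call", {
  participants <- tibble::tibble(participant_id = "P1", nadir_cd4 = 100,
                                 age = 40)
  for (gain in c(40, 90, 110, 160)) {
    v <- make_course(3, gain)
    lo <- phenotype_cohort(v, participants,
                           phenotype_config(good_gain_per_year = 100))$calls
    hi <- phenotype_cohort(v, participants,
                           phenotype_config(good_gain_per_year = 140))$calls
    if (lo$group != "GOOD") expect_false(hi$group == "GOOD")
  }
})

test_that("frequency matching is stratified, capped and deterministic", {
  calls <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:30),
    group = c(rep("GOOD", 20), rep("POOR", 10))
  )
  participants <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:30),
    race_ethnicity = c(rep("A", 10), rep("B", 10), rep("A", 5), rep("B", 5))
  )
  m1 <- match_groups(calls, participants, ratio = 1, seed = 7)
  counts <- dplyr::count(m1, race_ethnicity, group)
  expect_true(all(counts$n == 5))
  m2 <- match_groups(calls, participants, ratio = 1, seed = 7)
  expect_identical(m1, m2)

  # shortfall: keep every available good responder
  short <- match_groups(
    calls[c(1:3, 21:25), ],
    participants[c(1:3, 21:25), ], ratio = 1, seed = 1
  )
  expect_equal(sum(short$group == "GOOD"), 3)

  # stratum with poor responders only is dropped with a warning
  expect_warning(
    m3 <- match_groups(calls[c(1:10, 26:30), ], participants[c(1:10, 26:30), ],
                       seed = 2),
    "dropped"
  )
  expect_true(all(m3$race_ethnicity == "A"))
})
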