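#' Generate a synthetic cohort of semiannual visits
#'
#' Draws a cohort under the study design the analysis assumes: each
#' participant receives an age and clinical covariates, a latent response
#' group via `logit(p_good) = logit(p_good_base) + log_or_age * (age -
#' age_mean)`, a pre-cART phase with detectable viremia and CD4 near nadir,
#' and a cART phase with viral suppression (apart from transient blips) during
#' which CD4 rises piecewise-linearly at the group-specific rate plus Gaussian
#' visit noise. Visits are semiannual (two per year). Missing CD4 and
#' viral-load values are injected independently at `missing_rate`.
#'
#' The first on-therapy visit is emitted as viremic (suppression is reached by
#' the following visit), so suppressed runs begin one visit after cART start.
#' Binary clinical covariates are drawn at group-conditional rates emulating
#' the published cohort characteristics.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `cohort_fixture`: a list with tibbles
#'   `visits` (one row per participant-visit), `participants` (one row per
#'   participant with covariates) and `truth` (list with `participants` —
#'   latent response group — and `genes` — planted-effect flags).
#' @export
#' @examples
#' fx <- simulate_cohort(sim_scenario(seed = 7, n_participants = 10))
#' dplyr::count(fx$truth$participants, group)
simulate_cohort <- function(scenario) {
  validate_scenario(scenario)
  sc <- scenario
  with_seed(child_seed(sc$seed, 1), {
    n <- sc$n_participants
    id <- sprintf("P%03d", seq_len(n))
    age <- rnorm(n, sc$age_mean, sc$age_sd)
    p_good <- inv_logit(logit(sc$p_good_base) + sc$log_or_age * (age - sc$age_mean))
    good <- rbinom(n, 1, p_good) == 1
    nadir <- pmax(10, round(rnorm(n, sc$nadir_mean, sc$nadir_sd)))
    slope <- ifelse(good,
                    rnorm(n, sc$gain_good_mean, sc$gain_good_sd),
                    rnorm(n, sc$gain_poor_mean, sc$gain_poor_sd))

    participants <- tibble::tibble(
      participant_id = id,
      age = round(age, 1),
      race_ethnicity = sample(
        c("White_nonH", "White_H", "AfAm_nonH", "Other"),
        n, replace = TRUE, prob = c(0.27, 0.13, 0.31, 0.29)
      ),
      hcv_positive = rbinom(n, 1, ifelse(good, 0.23, 0.43)) == 1,
      prior_aids = rbinom(n, 1, ifelse(good, 0.35, 0.57)) == 1,
      prior_ddi_d4t = rbinom(n, 1, ifelse(good, 0.67, 0.86)) == 1,
      smoker = rbinom(n, 1, ifelse(good, 0.31, 0.52)) == 1,
      amh_category = amh_draw(n, good),
      adherence = adherence_draw(n, good),
      nadir_cd4 = nadir,
      max_precart_log10_vl = round(rnorm(n, 4.45, 0.9), 2)
    )

    visits <- purrr::map2_dfr(seq_len(n), slope, function(i, sl) {
      participant_visits(sc, id[i], nadir[i], sl)
    })

    truth <- list(
      participants = tibble::tibble(participant_id = id,
                                    group = ifelse(good, "GOOD", "POOR")),
      genes = gene_truth_table(sc)
    )
    structure(list(visits = visits, participants = participants, truth = truth),
              class = "cohort_fixture")
  })
}

# One participant's visit rows.
participant_visits <- function(sc, id, nadir, slope) {
  nv <- sc$n_visits
  pre <- sc$pre_cart_visits
  on_cart <- seq_len(nv) > pre
  first_cart <- pre + 1L

  # Viremia: detectable pre-cART and at the first cART visit; suppressed
  # afterwards apart from blips.
  blip <- runif(nv) < sc$blip_prob
  suppressed <- on_cart & seq_len(nv) > first_cart & !blip
  viremic_vl <- round(10^rnorm(nv, 4.3, 0.5))
  viremic_vl <- pmax(viremic_vl, sc$detection_limit * 2)
  blip_vl <- round(pmax(sc$detection_limit + 1, 10^rnorm(nv, 2.5, 0.4)))

  vl <- ifelse(suppressed, NA_real_,
               ifelse(on_cart & seq_len(nv) > first_cart, blip_vl, viremic_vl))
  vl_below <- !is.na(suppressed) & suppressed

  years_on_cart <- pmax(0, (seq_len(nv) - first_cart) / 2)
  cd4 <- nadir + slope * years_on_cart + rnorm(nv, 0, sc$cd4_noise_sd)
  cd4 <- pmax(0, round(cd4))

  miss_cd4 <- runif(nv) < sc$missing_rate
  miss_vl <- runif(nv) < sc$missing_rate
  cd4[miss_cd4] <- NA_real_
  vl[miss_vl] <- NA_real_
  vl_below[miss_vl] <- NA

  tibble::tibble(
    participant_id = id,
    visit_index = seq_len(nv),
    cd4 = cd4,
    vl = vl,
    vl_below_detection = vl_below,
    detection_limit = sc$detection_limit,
    on_cart = on_cart,
    adherence = NA_character_
  )
}

amh_draw <- function(n, good) {
  out <- character(n)
  for (i in seq_len(n)) {
    p <- if (good[i]) c(0.72, 0.25, 0.03) else c(0.42, 0.55, 0.03)
    out[i] <- sample(c("detectable", "below_detection", "not_available"), 1, prob = p)
  }
  out
}

adherence_draw <- function(n, good) {
  out <- character(n)
  for (i in seq_len(n)) {
    p <- if (good[i]) c(0.69, 0.21, 0.10) else c(0.48, 0.48, 0.04)
    out[i] <- sample(c(">95%", "<=95%", "not_available"), 1, prob = p)
  }
  out
}

gene_truth_table <- function(sc) {
  genes <- gene_ids(sc$n_genes)
  truth <- tibble::tibble(gene = genes, causal = FALSE,
                          carrier_log_or = 0, maf_band = NA_character_)
  if (!is.null(sc$causal_genes) && nrow(sc$causal_genes) > 0) {
    assert_that(all(sc$causal_genes$gene %in% genes),
                "causal_genes refers to gene ids outside the simulated genome")
    idx <- match(sc$causal_genes$gene, genes)
    truth$causal[idx] <- TRUE
    truth$carrier_log_or[idx] <- sc$causal_genes$carrier_log_or
    truth$maf_band[idx] <- sc$causal_genes$maf_band
  }
  truth
}

#' @export
print.cohort_fixture <- function(x, ...) {
  cat("<cohort_fixture>", nrow(x$participants), "participants,",
      nrow(x$visits), "visits\n")
  invisible(x)
}

#' Write a cohort fixture as tab-delimited text
#'
#' Emits `visits.tsv`, `participants.tsv` and `truth_participants.tsv` /
#' `truth_genes.tsv` into `dir`.
#'
#' @param fixture A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(fixture$visits, file.path(dir, "visits.tsv"))
  readr::write_tsv(fixture$participants, file.path(dir, "participants.tsv"))
  readr::write_tsv(fixture$truth$participants, file.path(dir, "truth_participants.tsv"))
  readr::write_tsv(fixture$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory containing `visits.tsv` and `participants.tsv`.
#' @return List with tibbles `visits` and `participants`.
#' @export
read_cohort <- function(dir) {
  list(
    visits = readr::read_tsv(file.path(dir, "visits.tsv"),
                             show_col_types = FALSE),
    participants = readr::read_tsv(file.path(dir, "participants.tsv"),
                                   show_col_types = FALSE)
  )
}

#' Simulate a case-control table where only age carries signal
#'
#' Generates an outcome driven solely by age together with `n_noise` covariates
#' that are correlated with age (and, through a shared latent "era" component,
#' with one another) but carry no effect of their own. This is the fixture for
#' checking that forward stepwise selection recovers age first and alone: in
#' observational HIV cohorts, age-linked exposures (smoking years, ovarian
#' reserve, early-era nucleoside use) cluster on a common cohort/era axis
#' rather than varying independently.
#'
#' @param n Sample size.
#' @param seed Integer seed.
#' @param n_noise Number of null age-correlated covariates.
#' @param log_or_age True per-year log-odds of the outcome.
#' @param age_mean,age_sd Age distribution.
#' @param era_sd Standard deviation of the shared latent component.
#' @param noise_sd Covariate-specific residual sd.
#' @return Tibble with `y` (0/1), `age`, and `z1..z{n_noise}`.
#' @export
simulate_age_signal_cohort <- function(n = 400, seed = 1, n_noise = 5,
                                       log_or_age = log(0.85),
                                       age_mean = 42, age_sd = 8,
                                       era_sd = 6, noise_sd = 0.5) {
  with_seed(child_seed(seed, 9), {
    age <- rnorm(n, age_mean, age_sd)
    y <- rbinom(n, 1, inv_logit(log_or_age * (age - age_mean)))
    era <- rnorm(n, 0, era_sd)
    z <- vapply(seq_len(n_noise), function(j) {
      0.8 * (age - age_mean) + era + rnorm(n, 0, noise_sd)
    }, numeric(n))
    colnames(z) <- paste0("z", seq_len(n_noise))
    dplyr::bind_cols(tibble::tibble(y = y, age = age), tibble::as_tibble(z))
  })
}
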