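#' Assemble a pipeline run configuration
#'
#' One flat configuration drives the whole synthetic run: simulate ->
#' phenotype -> clinical association -> genotype QC/PCA -> burden scan. The
#' global `seed` propagates to every stochastic stage (scenario and
#' permutation plan seeds are derived from it).
#'
#' @param scenario A [sim_scenario()] (or raw list of its fields).
#' @param phenotype A [phenotype_config()] (or raw list).
#' @param plan A [permutation_plan()] (or raw list).
#' @param mode `"exome"` or `"candidate"`.
#' @param threshold Optional hit-threshold override.
#' @param candidate_genes Candidate gene ids (candidate mode).
#' @param out_dir Run directory for stage outputs and the manifest.
#' @param seed Global seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = sim_scenario(), phenotype = phenotype_config(),
                       plan = permutation_plan(), mode = "exome",
                       threshold = NULL, candidate_genes = NULL,
                       out_dir = tempfile("cd4run"), seed = 1L) {
  structure(list(scenario = scenario, phenotype = phenotype, plan = plan,
                 mode = mode, threshold = threshold,
                 candidate_genes = candidate_genes,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Collects every violation rather than stopping at the first; an empty
#' character vector means the configuration is valid.
#'
#' @param config A [run_config()] (or a bare list with the same fields).
#' @return Character vector of violations.
#' @export
validate_run_config <- function(config) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  sc <- config$scenario
  if (is.null(sc)) note("scenario is missing")
  else tryCatch(validate_scenario(sc), error = function(e) note(conditionMessage(e)))

  ph <- config$phenotype
  if (is.null(ph)) {
    note("phenotype config is missing")
  } else {
    if (!is.null(ph$good_gain_per_year) && !is.null(ph$poor_gain_per_year) &&
        ph$good_gain_per_year <= ph$poor_gain_per_year)
      note("good_gain_per_year must exceed poor_gain_per_year")
    if (!is.null(ph$min_good_years) && !is.null(ph$min_poor_years) &&
        ph$min_good_years < ph$min_poor_years)
      note("min_good_years must be >= min_poor_years")
  }

  pl <- config$plan
  if (is.null(pl)) note("permutation plan is missing")
  else if (!is.null(pl$max_perm) && pl$max_perm < 100)
    note("max_perm must be >= 100")

  if (!is.null(config$threshold) &&
      (config$threshold <= 0 || config$threshold > 1))
    note("threshold must lie in (0, 1]")
  if (!config$mode %in% c("exome", "candidate"))
    note("mode must be 'exome' or 'candidate'")
  if (identical(config$mode, "candidate") && is.null(config$candidate_genes))
    note("candidate mode needs candidate_genes")
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    note("out_dir is missing")
  bad
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order — simulate, phenotype, clinical
#' association, genotype QC + ancestry PCA, burden scan (with transcript
#' rerun for hits) — writing each stage's tab-delimited outputs under
#' `config$out_dir` together with a JSON manifest recording the configuration
#' hash, seeds, versions and per-stage row/gene counts. Re-running the same
#' configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return The manifest (invisibly), as a list.
#' @export
run_pipeline <- function(config) {
  bad <- validate_run_config(config)
  assert_that(length(bad) == 0,
              paste0("invalid configuration:\n  - ",
                     paste(bad, collapse = "\n  - ")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(stage, msg) {
    cat(sprintf("%s\t%s\t%s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf(name, paste("ERROR:", conditionMessage(e)))
      abort(paste0("stage '", name, "' failed (see ", log_path, "): ",
                   conditionMessage(e)))
    })
  }
  hashable <- unclass(config)
  hashable$out_dir <- NULL # paths are not part of the scientific configuration
  manifest <- list(config_hash = rlang::hash(hashable),
                   seed = config$seed,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("cd4recover")),
                   stages = list())

  # stage 1: simulate
  sc <- config$scenario
  sc$seed <- config$seed
  fx <- NULL; gfx <- NULL
  stage("simulate", {
    fx <- simulate_cohort(sc)
    gfx <- simulate_genotypes(sc, fx)
    write_cohort(fx, file.path(config$out_dir, "simulate"))
    write_genotypes(gfx, file.path(config$out_dir, "simulate"))
    logf("simulate", paste(nrow(fx$visits), "visits,",
                           nrow(gfx$genotypes$variants), "variants"))
  })
  manifest$stages$simulate <- list(n_visits = nrow(fx$visits),
                                   n_variants = nrow(gfx$genotypes$variants))

  # stage 2: phenotype
  ph <- NULL
  stage("phenotype", {
    ph <- phenotype_cohort(fx$visits, fx$participants, config$phenotype)
    dir.create(file.path(config$out_dir, "phenotype"), showWarnings = FALSE)
    readr::write_tsv(ph$visits, file.path(config$out_dir, "phenotype", "visit_codes.tsv"))
    readr::write_tsv(ph$calls, file.path(config$out_dir, "phenotype", "responder_calls.tsv"))
    logf("phenotype", paste(sum(ph$calls$group != "INDETERMINATE"),
                            "determinate calls"))
  })
  manifest$stages$phenotype <-
    list(n_good = sum(ph$calls$group == "GOOD"),
         n_poor = sum(ph$calls$group == "POOR"),
         n_indeterminate = sum(ph$calls$group == "INDETERMINATE"))

  det <- ph$calls[ph$calls$group %in% c("GOOD", "POOR"), ]
  cohort <- dplyr::inner_join(det, fx$participants, by = "participant_id") |>
    dplyr::mutate(good = .data$group == "GOOD")

  # stage 3: clinical association
  stw <- NULL
  stage("assoc", {
    tab <- univariate_table(
      cohort, "good",
      binary = c("prior_aids", "hcv_positive", "prior_ddi_d4t", "smoker"),
      continuous = c(age = 1)
    )
    stw <- forward_stepwise(
      cohort, "good",
      candidates = c("age", "hcv_positive", "prior_aids", "prior_ddi_d4t", "smoker")
    )
    dir.create(file.path(config$out_dir, "assoc"), showWarnings = FALSE)
    readr::write_tsv(tab, file.path(config$out_dir, "assoc", "univariate_table.tsv"))
    readr::write_tsv(tidy(stw), file.path(config$out_dir, "assoc", "stepwise_model.tsv"))
    logf("assoc", paste("stepwise selected:",
                        paste(stw$selected, collapse = ", ")))
  })
  manifest$stages$assoc <- list(selected = stw$selected)

  # stage 4: genotype QC + PCA
  gm <- NULL; pca <- NULL; snp_stats <- NULL
  stage("qc", {
    gm0 <- read_vcf(file.path(config$out_dir, "simulate", "genotypes.vcf"))
    gm0 <- subset_samples(gm0, det$participant_id)
    gm0 <- assign_gene_regions(gm0, gfx$gene_map)
    gm0 <- annotate_ref_maf(gm0, gfx$ref_maf)
    gm <- gm0
    snp_stats <- per_snp_stats(gm0, det)
    pca <- genotype_pca(gm0, n_components = 2)
    dir.create(file.path(config$out_dir, "qc"), showWarnings = FALSE)
    readr::write_tsv(dplyr::select(snp_stats, -"transcripts"),
                     file.path(config$out_dir, "qc", "snp_stats.tsv"))
    readr::write_tsv(pca$scores, file.path(config$out_dir, "qc", "pca_scores.tsv"))
    logf("qc", paste(nrow(gm0$variants), "variants after QC,",
                     pca$n_variants_used, "used for PCA"))
  })
  manifest$stages$qc <- list(n_variants = nrow(gm$variants),
                             n_pca_variants = pca$n_variants_used)

  # stage 5: burden scan
  scan <- NULL
  stage("burden", {
    covars <- dplyr::tibble(participant_id = det$participant_id,
                            age = cohort$age[match(det$participant_id,
                                                   cohort$participant_id)]) |>
      dplyr::left_join(pca$scores, by = c(participant_id = "sample"))
    plan <- config$plan
    plan$seed <- child_seed(config$seed, 5)
    scan <- run_burden_scan(gm, det, covariates = covars, plan = plan,
                             mode = config$mode,
                             candidate_genes = config$candidate_genes,
                             threshold = config$threshold)
    tx <- transcript_rerun(scan, gm, gfx$gene_map, det, covariates = covars,
                           plan = plan)
    dir.create(file.path(config$out_dir, "burden"), showWarnings = FALSE)
    readr::write_tsv(scan$results, file.path(config$out_dir, "burden", "gene_results.tsv"))
    readr::write_tsv(scan$hits, file.path(config$out_dir, "burden", "hits.tsv"))
    if (nrow(tx) > 0) {
      readr::write_tsv(tx, file.path(config$out_dir, "burden", "transcript_results.tsv"))
    }
    logf("burden", paste(nrow(scan$hits), "hits"))
  })
  manifest$stages$burden <- list(n_genes = length(unique(scan$results$gene)),
                                 n_hits = nrow(scan$hits))

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Subset a genotype matrix to selected samples
#'
#' @param gm A [genotype_matrix()].
#' @param samples Sample ids to keep (order preserved as given).
#' @return A [genotype_matrix()] restricted and re-oriented to the subset's
#'   minor alleles.
#' @export
subset_samples <- function(gm, samples) {
  m <- match(samples, gm$samples)
  assert_that(!anyNA(m), "some requested samples are absent from the matrix")
  d <- gm$dosage[m, , drop = FALSE]
  # restore ALT orientation before rebuilding so flips stay consistent
  flip <- gm$variants$flipped %||% rep(FALSE, ncol(d))
  if (any(flip)) d[, flip] <- 2L - d[, flip]
  v <- gm$variants
  v$flipped <- NULL
  v$cohort_maf <- NULL
  out <- genotype_matrix(d, v, samples)
  out$log <- gm$log
  out
}
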