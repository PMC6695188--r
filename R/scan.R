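#' Gene-wise CMC + KBAC burden scan
#'
#' Runs both burden tests for every gene region (or a candidate-gene subset),
#' unadjusted and covariate-adjusted, and collects the hit list: genes whose
#' permutation p-value falls at or below the mode's threshold by either
#' method — 0.001 for the exome-wide scan, 0.05 for a-priori candidate genes.
#' Each hit is classified `CMC-only`, `KBAC-only` or `both`, the usual
#' reading being that CMC-only hits are driven primarily by common variants,
#' KBAC-only hits by rare variants, and `both` by the two together.
#'
#' Permutation p-values are computed for the covariate-adjusted tests (the
#' values a scan reports); the unadjusted CMC result carries its asymptotic
#' LRT p, with permutation available via `permute_unadjusted`. Genes with no
#' rare variant are skipped by KBAC (and logged), so the two tests may cover
#' slightly different gene sets. Per-gene resampling seeds derive
#' deterministically from `plan$seed` and the gene name.
#'
#' @param gm A [genotype_matrix()] annotated with `gene`, `bin` and
#'   `cohort_maf` (see [assign_gene_regions()], [annotate_ref_maf()]).
#' @param phenotype Binary vector or responder-call tibble (1/GOOD = case).
#' @param covariates Optional data frame / matrix (e.g. age, PC1, PC2); a
#'   `participant_id` column, if present, is used to align rows to
#'   `gm$samples`, otherwise rows must already be aligned.
#' @param plan A [permutation_plan()].
#' @param mode `"exome"` (threshold 0.001) or `"candidate"` (0.05).
#' @param candidate_genes Gene ids for candidate mode.
#' @param threshold Override the mode's hit threshold.
#' @param adjusted_scheme Null-resampling scheme for the adjusted tests
#'   (default parametric bootstrap from the covariates-only fit).
#' @param permute_unadjusted Also compute permutation p for the unadjusted
#'   CMC test (the unadjusted KBAC p is always permutation-based).
#' @return Object of class `burden_scan`: list with `results` (long tibble:
#'   one row per gene x test x adjustment), `hits` (tibble with
#'   classification), `skipped` (KBAC-skipped genes), `mode`, `threshold`.
#' @export
run_burden_scan <- function(gm, phenotype, covariates = NULL,
                            plan = permutation_plan(),
                            mode = c("exome", "candidate"),
                            candidate_genes = NULL, threshold = NULL,
                            adjusted_scheme = "parametric_bootstrap_null",
                            permute_unadjusted = FALSE) {
  mode <- match.arg(mode)
  threshold <- threshold %||% if (mode == "exome") 0.001 else 0.05
  assert_that("gene" %in% names(gm$variants),
              "variants carry no gene assignment; run assign_gene_regions()")
  covariates <- align_covariates(covariates, gm$samples)
  y <- align_phenotype(phenotype, gm$samples)

  genes <- sort(unique(gm$variants$gene[!is.na(gm$variants$gene)]))
  if (mode == "candidate") {
    assert_that(!is.null(candidate_genes), "candidate mode needs candidate_genes")
    genes <- intersect(genes, candidate_genes)
  }

  rows <- list()
  skipped <- character(0)
  for (g in genes) {
    idx <- which(gm$variants$gene == g)
    gplan <- reseed_plan(plan, g)
    coll <- cmc_collapse(gm, idx)

    cmc_un <- cmc_test(coll, y, covariates = NULL,
                       plan = if (permute_unadjusted) gplan else NULL,
                       gene = g)
    rows[[length(rows) + 1]] <- tidy(cmc_un)

    kb_un <- tryCatch(
      kbac_test(gm, idx, y, covariates = NULL, plan = gplan, gene = g),
      cd4recover_no_rare = function(e) NULL
    )
    if (is.null(kb_un)) skipped <- c(skipped, g) else {
      rows[[length(rows) + 1]] <- tidy(kb_un)
    }

    if (!is.null(covariates)) {
      aplan <- gplan
      aplan$scheme <- adjusted_scheme
      cmc_ad <- cmc_test(coll, y, covariates = covariates, plan = aplan, gene = g)
      rows[[length(rows) + 1]] <- tidy(cmc_ad)
      if (!is.null(kb_un)) {
        kb_ad <- kbac_test(gm, idx, y, covariates = covariates, plan = aplan,
                           gene = g)
        rows[[length(rows) + 1]] <- tidy(kb_ad)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  hits <- scan_hits(results, threshold, adjusted = !is.null(covariates))
  structure(list(results = results, hits = hits, skipped = unique(skipped),
                 mode = mode, threshold = threshold,
                 adjusted = !is.null(covariates)),
            class = "burden_scan")
}

reseed_plan <- function(plan, gene) {
  h <- sum(utf8ToInt(gene) * seq_along(utf8ToInt(gene)))
  plan$seed <- as.integer((as.numeric(plan$seed) * 131 + h) %% 2147483647)
  plan
}

align_covariates <- function(covariates, samples) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates) && "participant_id" %in% names(covariates)) {
    m <- match(samples, covariates$participant_id)
    assert_that(!anyNA(m), "covariate rows missing for some samples")
    covariates <- covariates[m, setdiff(names(covariates), "participant_id"),
                             drop = FALSE]
  }
  covariates <- as.matrix(covariates)
  assert_that(nrow(covariates) == length(samples),
              "covariate rows must match samples")
  rownames(covariates) <- samples
  covariates
}

scan_hits <- function(results, threshold, adjusted) {
  use <- results[results$adjusted == adjusted, ]
  per_gene <- use |>
    dplyr::mutate(p_hit = dplyr::coalesce(.data$p_perm, .data$p_asym)) |>
    dplyr::select("gene", "test", "p_hit") |>
    tidyr::pivot_wider(names_from = "test", values_from = "p_hit")
  if (!"CMC" %in% names(per_gene)) per_gene$CMC <- NA_real_
  if (!"KBAC" %in% names(per_gene)) per_gene$KBAC <- NA_real_
  per_gene |>
    dplyr::mutate(
      cmc_hit = !is.na(.data$CMC) & .data$CMC <= threshold,
      kbac_hit = !is.na(.data$KBAC) & .data$KBAC <= threshold
    ) |>
    dplyr::filter(.data$cmc_hit | .data$kbac_hit) |>
    dplyr::mutate(classification = dplyr::case_when(
      .data$cmc_hit & .data$kbac_hit ~ "both",
      .data$cmc_hit ~ "CMC-only",
      TRUE ~ "KBAC-only"
    )) |>
    dplyr::rename(cmc_p = "CMC", kbac_p = "KBAC")
}

#' @export
print.burden_scan <- function(x, ...) {
  cat("<burden_scan>", x$mode, "mode |",
      length(unique(x$results$gene)), "genes |", nrow(x$hits),
      "hits at p <=", x$threshold,
      if (x$adjusted) "(covariate-adjusted)" else "(unadjusted)", "\n")
  invisible(x)
}

#' @method tidy burden_scan
#' @export
tidy.burden_scan <- function(x, ...) x$results

#' @method glance burden_scan
#' @export
glance.burden_scan <- function(x, ...) {
  tibble::tibble(mode = x$mode, threshold = x$threshold,
                 n_genes = length(unique(x$results$gene)),
                 n_hits = nrow(x$hits),
                 n_kbac_skipped = length(x$skipped))
}

#' Re-run burden tests per transcript for hit genes
#'
#' For each gene in the scan's hit list, restricts the region to each of its
#' transcript intervals and reruns both tests; running this only for genes
#' that met the a-priori threshold keeps the added multiple-testing burden
#' minimal. Transcripts with no variants are skipped with a log entry.
#'
#' @param scan A [run_burden_scan()] result.
#' @param gm The annotated [genotype_matrix()] used for the scan.
#' @param gene_map Transcript map (`gene`, `transcript`, `chrom`, `start`,
#'   `end`).
#' @param phenotype,covariates,plan As in [run_burden_scan()].
#' @return Tibble of per-transcript results (empty when there are no hits),
#'   plus a `skipped_transcripts` attribute.
#' @export
transcript_rerun <- function(scan, gm, gene_map, phenotype, covariates = NULL,
                             plan = permutation_plan()) {
  covariates <- align_covariates(covariates, gm$samples)
  y <- align_phenotype(phenotype, gm$samples)
  rows <- list()
  skipped <- character(0)
  for (g in scan$hits$gene) {
    tx <- gene_map[gene_map$gene == g, ]
    for (t in seq_len(nrow(tx))) {
      idx <- which(gm$variants$gene == g &
                     gm$variants$pos >= tx$start[t] &
                     gm$variants$pos <= tx$end[t])
      if (length(idx) == 0) {
        skipped <- c(skipped, tx$transcript[t])
        next
      }
      gplan <- reseed_plan(plan, tx$transcript[t])
      if (!is.null(covariates)) gplan$scheme <- "parametric_bootstrap_null"
      coll <- cmc_collapse(gm, idx)
      cm <- cmc_test(coll, y, covariates = covariates, plan = gplan, gene = g)
      rows[[length(rows) + 1]] <- dplyr::mutate(tidy(cm),
                                                transcript = tx$transcript[t])
      kb <- tryCatch(
        kbac_test(gm, idx, y, covariates = covariates, plan = gplan, gene = g),
        cd4recover_no_rare = function(e) NULL
      )
      if (!is.null(kb)) {
        rows[[length(rows) + 1]] <- dplyr::mutate(tidy(kb),
                                                  transcript = tx$transcript[t])
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  attr(out, "skipped_transcripts") <- skipped
  out
}
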