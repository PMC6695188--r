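#' Construct a genotype matrix object
#'
#' Container for a samples x SNPs dosage matrix oriented to the cohort minor
#' allele, with per-variant annotation. Dosages are counts of the minor allele
#' in \{0, 1, 2, NA\}; columns whose ALT allele frequency exceeds 0.5 are
#' flipped at construction and flagged in `variants$flipped` so file writers
#' can reconstruct ALT dosages.
#'
#' @param dosage Integer matrix (samples x variants) of ALT-allele counts.
#' @param variants Tibble with at least `chrom`, `pos`, `ref`, `alt`.
#' @param samples Sample identifiers (defaults to rownames of `dosage`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  assert_that(ncol(dosage) == nrow(variants),
              "dosage columns must match variant rows")
  assert_that(all(dosage %in% c(0L, 1L, 2L, NA)), "dosage must be 0/1/2/NA")
  storage.mode(dosage) <- "integer"
  alt_freq <- colMeans(dosage, na.rm = TRUE) / 2
  alt_freq[is.nan(alt_freq)] <- 0
  flipped <- alt_freq > 0.5
  if (any(flipped)) {
    dosage[, flipped] <- 2L - dosage[, flipped]
  }
  variants$flipped <- flipped
  variants$cohort_maf <- ifelse(flipped, 1 - alt_freq, alt_freq)
  rownames(dosage) <- samples
  structure(list(dosage = dosage, variants = variants,
                 samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", length(x$samples), "samples x",
      nrow(x$variants), "SNPs\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$variants))

#' Tidy a genotype matrix into long form
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return Tibble with one row per sample-variant pair.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample = rep(x$samples, times = nrow(x$variants)),
    chrom = rep(x$variants$chrom, each = length(x$samples)),
    pos = rep(x$variants$pos, each = length(x$samples)),
    dosage = as.vector(x$dosage)
  )
}

#' Generate synthetic genotypes with substructure and planted gene effects
#'
#' Ancestral minor-allele frequencies are drawn from the scenario's Beta
#' spectrum; the two subpopulation frequencies come from a Balding-Nichols
#' draw at the scenario `fst`; genotypes are Hardy-Weinberg within
#' subpopulation. For planted rare-effect genes, carrier status at five
#' designated rare sites is re-sampled conditional on the participant's true
#' response group (retrospective sampling) to realize the requested carrier
#' log-odds; common-effect genes get one designated common site whose allele
#' frequency is shifted by group. Per-genotype DP and GQ values are emitted
#' with a configurable fraction below the QC thresholds (DP < 8, GQ < 20), and
#' a configurable fraction of variants is omitted from the reference-MAF
#' lookup table.
#'
#' @param scenario A [sim_scenario()].
#' @param cohort A [simulate_cohort()] result (or its `truth$participants`
#'   tibble) supplying participant ids and true response groups.
#' @return An object of class `genotype_fixture`: list with `genotypes`
#'   (a [genotype_matrix()]), `dp` and `gq` (integer matrices), `ref_maf`
#'   (tibble `chrom, pos, ref, alt, ref_maf`), `gene_map` (tibble
#'   `gene, transcript, chrom, start, end`), and `subpop` (tibble).
#' @export
simulate_genotypes <- function(scenario, cohort) {
  validate_scenario(scenario)
  sc <- scenario
  truth <- if (inherits(cohort, "cohort_fixture")) cohort$truth$participants else cohort
  assert_that(all(c("participant_id", "group") %in% names(truth)),
              "cohort must provide participant_id and group")
  n <- nrow(truth)
  m <- sc$n_genes * sc$variants_per_gene
  if (!is.null(sc$causal_genes) && nrow(sc$causal_genes) > 0) {
    need <- ifelse(sc$causal_genes$maf_band == "rare", 5L, 1L)
    assert_that(all(need <= sc$variants_per_gene),
                "requested causal MAF band incompatible with variants_per_gene")
  }

  with_seed(child_seed(sc$seed, 2), {
    genes <- gene_ids(sc$n_genes)
    gene_of <- rep(genes, each = sc$variants_per_gene)
    within <- rep(seq_len(sc$variants_per_gene), times = sc$n_genes)
    gene_start <- (match(gene_of, genes) - 1L) * 100000L + 1L
    pos <- gene_start + (within - 1L) * 1000L

    # ancestral spectrum, with designated causal sites pinned
    p0 <- rbeta(m, sc$maf_spectrum[1], sc$maf_spectrum[2])
    p0 <- pmin(pmax(p0, 0.001), 0.5)
    designated <- designated_sites(sc, gene_of, within)
    p0[designated$rare_idx] <- 0.002
    p0[designated$common_idx] <- 0.3

    # Balding-Nichols subpopulation frequencies
    if (sc$fst > 0) {
      a <- p0 * (1 - sc$fst) / sc$fst
      b <- (1 - p0) * (1 - sc$fst) / sc$fst
      p1 <- rbeta(m, a, b)
      p2 <- rbeta(m, a, b)
    } else {
      p1 <- p0
      p2 <- p0
    }
    subpop <- 1L + rbinom(n, 1, sc$pop2_fraction)
    pmat <- rbind(p1, p2)[subpop, , drop = FALSE]
    dosage <- matrix(rbinom(n * m, 2, as.vector(pmat)), nrow = n)
    rownames(dosage) <- truth$participant_id

    dosage <- plant_effects(sc, dosage, designated, truth$group == "GOOD")

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

    variants <- tibble::tibble(
      chrom = "1", pos = pos, id = sprintf("rs%07d", seq_len(m)),
      ref = ref, alt = alt, gene = gene_of
    )
    gm <- genotype_matrix(dosage, variants, truth$participant_id)

    # DP / GQ with a planted sub-threshold fraction
    dp <- matrix(pmax(1L, as.integer(stats::rpois(n * m, 50))), nrow = n)
    gq <- matrix(pmin(99L, as.integer(20 + stats::rpois(n * m, 60))), nrow = n)
    fail <- matrix(runif(n * m) < sc$qc_fail_rate, nrow = n)
    fail_dp <- fail & matrix(runif(n * m) < 0.5, nrow = n)
    dp[fail_dp] <- sample(0:7, sum(fail_dp), replace = TRUE)
    gq[fail & !fail_dp] <- sample(0:19, sum(fail & !fail_dp), replace = TRUE)

    ref_maf <- tibble::tibble(
      chrom = "1", pos = pos, ref = ref, alt = alt,
      ref_maf = pmin(pmax(p0 + rnorm(m, 0, 0.005), 0), 0.5)
    )
    ref_maf <- ref_maf[runif(m) >= sc$ref_maf_missing_rate, ]

    # three transcripts per gene: full span, first half, second half
    gene_map <- purrr::map_dfr(seq_along(genes), function(g) {
      s <- (g - 1L) * 100000L + 1L
      e <- s + (sc$variants_per_gene - 1L) * 1000L
      half <- s + (ceiling(sc$variants_per_gene / 2) - 1L) * 1000L
      tibble::tibble(
        gene = genes[g],
        transcript = paste0(genes[g], c(".t1", ".t2", ".t3")),
        chrom = "1", start = c(s, s, half + 1000L), end = c(e, half, e)
      )
    })

    structure(list(genotypes = gm, dp = dp, gq = gq, ref_maf = ref_maf,
                   gene_map = gene_map,
                   subpop = tibble::tibble(participant_id = truth$participant_id,
                                           subpop = subpop),
                   freqs = tibble::tibble(p0 = p0, p1 = p1, p2 = p2)),
              class = "genotype_fixture")
  })
}

# Rare-effect genes spread carriers over up to 10 designated sites (allelic
# heterogeneity), at least 5 of which must exist.
n_designated_rare <- function(sc) min(10L, sc$variants_per_gene)

# Index designated causal sites by band.
designated_sites <- function(sc, gene_of, within) {
  rare_idx <- integer(0)
  common_idx <- integer(0)
  rare_gene <- character(0)
  common_gene <- character(0)
  cg <- sc$causal_genes
  if (!is.null(cg) && nrow(cg) > 0) {
    for (k in seq_len(nrow(cg))) {
      if (cg$maf_band[k] == "rare") {
        idx <- which(gene_of == cg$gene[k] & within <= n_designated_rare(sc))
        rare_idx <- c(rare_idx, idx)
        rare_gene <- c(rare_gene, rep(cg$gene[k], length(idx)))
      } else {
        idx <- which(gene_of == cg$gene[k] & within == 1)
        common_idx <- c(common_idx, idx)
        common_gene <- c(common_gene, cg$gene[k])
      }
    }
  }
  list(rare_idx = rare_idx, rare_gene = rare_gene,
       common_idx = common_idx, common_gene = common_gene,
       table = cg)
}

# Re-sample designated sites conditional on response group.
plant_effects <- function(sc, dosage, designated, is_good) {
  cg <- designated$table
  if (is.null(cg) || nrow(cg) == 0) return(dosage)
  n <- nrow(dosage)
  for (k in seq_len(nrow(cg))) {
    eff <- cg$carrier_log_or[k]
    if (cg$maf_band[k] == "rare") {
      idx <- designated$rare_idx[designated$rare_gene == cg$gene[k]]
      p_carry <- inv_logit(logit(sc$base_carrier_rate) + eff * is_good)
      carrier <- which(rbinom(n, 1, p_carry) == 1)
      dosage[, idx] <- 0L
      # spread carriers evenly (round-robin over shuffled carriers) so every
      # planted allele stays well below the rare-variant MAF cutoff
      carrier <- carrier[sample.int(length(carrier))]
      site <- idx[(seq_along(carrier) - 1L) %% length(idx) + 1L]
      dosage[cbind(carrier, site)] <- 1L
    } else {
      idx <- designated$common_idx[designated$common_gene == cg$gene[k]]
      p_allele <- inv_logit(logit(0.3) + (eff / 2) * is_good)
      dosage[, idx] <- rbinom(n, 2, p_allele)
    }
  }
  dosage
}

#' Write a genotype fixture to disk
#'
#' Emits `genotypes.vcf` (VCF v4.2 with GT:DP:GQ), `ref_maf.tsv`,
#' `gene_map.tsv` and `subpop.tsv`.
#'
#' @param fixture A [simulate_genotypes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genotypes <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf(fixture$genotypes, file.path(dir, "genotypes.vcf"),
            dp = fixture$dp, gq = fixture$gq)
  readr::write_tsv(fixture$ref_maf, file.path(dir, "ref_maf.tsv"))
  readr::write_tsv(fixture$gene_map, file.path(dir, "gene_map.tsv"))
  readr::write_tsv(fixture$subpop, file.path(dir, "subpop.tsv"))
  invisible(dir)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Dosages are written as unphased GT fields on the ALT allele (minor-oriented
#' columns are flipped back using `variants$flipped`), with optional DP and GQ
#' per genotype.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @param dp,gq Optional integer matrices conformable with `gm$dosage`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, dp = NULL, gq = NULL) {
  alt_dosage <- gm$dosage
  flip <- gm$variants$flipped %||% rep(FALSE, ncol(alt_dosage))
  if (any(flip)) alt_dosage[, flip] <- 2L - alt_dosage[, flip]
  gt_code <- c("0/0", "0/1", "1/1")
  has_fmt <- !is.null(dp) && !is.null(gq)
  fmt <- if (has_fmt) "GT:DP:GQ" else "GT"

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cd4recover",
    paste0("##contig=<ID=", unique(gm$variants$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_fmt) c(
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
    ),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(gm$variants)), function(j) {
    g <- gt_code[alt_dosage[, j] + 1L]
    g[is.na(g)] <- "./."
    cells <- if (has_fmt) paste(g, dp[, j], gq[, j], sep = ":") else g
    paste(c(gm$variants$chrom[j], gm$variants$pos[j], gm$variants$id[j],
            gm$variants$ref[j], gm$variants$alt[j], ".", "PASS", ".",
            fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
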