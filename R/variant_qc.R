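#' Read a VCF into a genotype matrix with quality masking
#'
#' Parses a VCF v4.x (via the vcfR parser), keeping biallelic SNP records
#' only: multi-allelic and non-SNP records are skipped and counted. Genotypes
#' with read depth below `dp_min` or genotype quality below `gq_min` are set
#' to missing (the thresholds are non-strict survivals: DP = 8, GQ = 20 are
#' retained). Dosages are then oriented to the cohort minor allele.
#'
#' @param path VCF file.
#' @param dp_min,gq_min QC thresholds; genotypes with DP < `dp_min` or
#'   GQ < `gq_min` become missing. If the file carries no DP/GQ FORMAT
#'   fields the corresponding filter is skipped with a warning.
#' @return A [genotype_matrix()]; the element `log` records
#'   `n_skipped_non_snp`, `n_skipped_multiallelic` and `n_masked` genotypes.
#' @export
read_vcf <- function(path, dp_min = 8, gq_min = 20) {
  assert_that(file.exists(path), paste("VCF not found:", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  names(fix) <- tolower(names(fix))

  multi <- grepl(",", fix$alt)
  snp <- !multi & nchar(fix$ref) == 1 & nchar(fix$alt) == 1 &
    fix$ref %in% c("A", "C", "G", "T") & fix$alt %in% c("A", "C", "G", "T")
  keep <- which(snp)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  dos <- gt_to_dosage(gt[keep, , drop = FALSE])

  fmt_fields <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  n_masked <- 0L
  for (f in c(DP = "DP", GQ = "GQ")) {
    thr <- if (f == "DP") dp_min else gq_min
    if (!f %in% fmt_fields) {
      warn(paste("VCF has no", f, "FORMAT field;", f, "filter skipped"))
      next
    }
    val <- vcfR::extract.gt(vcf, element = f, as.numeric = TRUE)[keep, , drop = FALSE]
    mask <- !is.na(val) & val < thr
    n_masked <- n_masked + sum(mask & !is.na(dos))
    dos[mask] <- NA_integer_
  }

  variants <- tibble::tibble(
    chrom = fix$chrom[keep],
    pos = as.integer(fix$pos[keep]),
    id = fix$id[keep],
    ref = fix$ref[keep],
    alt = fix$alt[keep]
  )
  gm <- genotype_matrix(t(dos), variants, samples)
  gm$log <- list(n_skipped_non_snp = sum(!snp & !multi),
                 n_skipped_multiallelic = sum(multi),
                 n_masked = n_masked)
  gm
}

# "0/0"-style GT strings -> ALT dosage (variants x samples).
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

#' Assign variants to gene regions
#'
#' Annotates each variant with the gene (and transcripts) whose interval
#' contains its position; intervals are 1-based inclusive, matching the VCF
#' coordinate convention. The gene-level interval is the union of its
#' transcript intervals.
#'
#' @param gm A [genotype_matrix()].
#' @param gene_map Tibble with `gene`, `transcript`, `chrom`, `start`, `end`
#'   (one row per transcript).
#' @return `gm` with `gene` and `transcripts` (list-column) added to
#'   `gm$variants`.
#' @export
assign_gene_regions <- function(gm, gene_map) {
  gene_iv <- gene_map |>
    dplyr::group_by(.data$gene, .data$chrom) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  v <- gm$variants
  v$gene <- NA_character_
  v$transcripts <- vector("list", nrow(v))
  for (g in seq_len(nrow(gene_iv))) {
    hit <- v$chrom == gene_iv$chrom[g] &
      v$pos >= gene_iv$start[g] & v$pos <= gene_iv$end[g]
    v$gene[hit] <- gene_iv$gene[g]
  }
  tx <- gene_map
  for (i in which(!is.na(v$gene))) {
    rows <- tx$gene == v$gene[i] & v$pos[i] >= tx$start & v$pos[i] <= tx$end
    v$transcripts[[i]] <- tx$transcript[rows]
  }
  gm$variants <- v
  gm
}

#' Attach reference minor-allele frequencies and CMC bins
#'
#' Joins a reference-frequency lookup (emulating a population reference
#' database) by chrom/pos/ref/alt and assigns the five-bin frequency class
#' used by the CMC test; variants absent from the lookup fall in the rarest
#' (< 1%) bin.
#'
#' @param gm A [genotype_matrix()].
#' @param ref_maf Tibble with `chrom`, `pos`, `ref`, `alt`, `ref_maf`.
#' @return `gm` with `ref_maf` and `bin` columns added to `gm$variants`.
#' @export
annotate_ref_maf <- function(gm, ref_maf) {
  v <- dplyr::left_join(gm$variants,
                        dplyr::select(ref_maf, "chrom", "pos", "ref", "alt",
                                      "ref_maf"),
                        by = c("chrom", "pos", "ref", "alt"))
  v$bin <- assign_bin(v$ref_maf)
  gm$variants <- v
  gm
}

#' Five-bin reference-frequency class
#'
#' Bin 0: `< 1%`; bin 1: `[1%, 2.5%)`; bin 2: `[2.5%, 5%)`; bin 3:
#' `[5%, 10%)`; bin 4: `>= 10%`. Variants absent from the reference lookup
#' (`NA`) are assumed too rare to have been catalogued and get bin 0.
#' Boundaries are left-closed: a reference MAF of exactly 5% lands in bin 3.
#'
#' @param ref_maf Numeric vector of reference minor-allele frequencies in
#'   `[0, 0.5]`, `NA` allowed.
#' @return Integer vector of bins in `0:4`.
#' @export
assign_bin <- function(ref_maf) {
  assert_that(all(is.na(ref_maf) | (ref_maf >= 0 & ref_maf <= 0.5)),
              "ref_maf above 0.5: orientation bug upstream")
  out <- rep(0L, length(ref_maf))
  ok <- !is.na(ref_maf)
  out[ok] <- findInterval(ref_maf[ok], c(0.01, 0.025, 0.05, 0.10))
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: enumerates every heterozygote count compatible
#' with the observed allele counts, computes each configuration's conditional
#' probability, and sums the probabilities no larger than the observed
#' configuration's (two-sided, by probability ordering).
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts.
#' @return The exact p-value (1 for monomorphic sites).
#' @export
hwe_exact_p <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  n_minor <- 2 * n_hom_minor + n_het
  if (n == 0 || n_minor == 0 || n_minor == 2 * n) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logw <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(h) - lfactorial(hom_min) - lfactorial(hom_maj)
  }, numeric(1))
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Per-SNP quality and association statistics
#'
#' For each variant: call rate, cohort minor-allele frequency, exact
#' Hardy-Weinberg p-value, the excess-heterozygosity ratio R (observed over
#' expected heterozygote count under HWE), and the allelic Fisher exact test
#' of association with the binary phenotype (cross-product odds ratio, Wald
#' 95% CI where all cells are positive, exact p). Monomorphic variants get
#' `hwe_p = 1`, an undefined heterozygosity ratio and no association result.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotype Logical/0-1 vector aligned to `gm$samples` (TRUE/1 = good
#'   response), or a responder-call tibble with `participant_id` and `group`.
#' @return `gm$variants` augmented with `call_rate`, `cohort_maf`, `hwe_p`,
#'   `het_ratio`, `assoc_or`, `assoc_ci_low`, `assoc_ci_high`, `assoc_p`.
#' @export
per_snp_stats <- function(gm, phenotype) {
  y <- align_phenotype(phenotype, gm$samples)
  d <- gm$dosage
  n_samp <- nrow(d)
  v <- gm$variants

  res <- purrr::map_dfr(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    obs <- !is.na(x)
    n <- sum(obs)
    call_rate <- n / n_samp
    if (n == 0) {
      return(tibble::tibble(call_rate = 0, cohort_maf = NA_real_,
                            hwe_p = NA_real_, het_ratio = NA_real_,
                            assoc_or = NA_real_, assoc_ci_low = NA_real_,
                            assoc_ci_high = NA_real_, assoc_p = NA_real_))
    }
    maf <- sum(x[obs]) / (2 * n)
    n_het <- sum(x[obs] == 1L)
    n_hom_minor <- sum(x[obs] == 2L)
    n_hom_major <- n - n_het - n_hom_minor
    mono <- maf == 0 || maf == 1
    hwe <- if (mono) 1 else hwe_exact_p(n_hom_major, n_het, n_hom_minor)
    het_ratio <- if (mono) NA_real_ else n_het / (2 * n * maf * (1 - maf))

    if (mono) {
      assoc <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      yo <- y[obs]; xo <- x[obs]
      a <- sum(xo[yo == 1]); b <- 2 * sum(yo == 1 & !is.na(yo)) - a
      c_ <- sum(xo[yo == 0]); d_ <- 2 * sum(yo == 0 & !is.na(yo)) - c_
      p_f <- fisher.test(matrix(c(a, c_, b, d_), 2))$p.value
      if (all(c(a, b, c_, d_) > 0)) {
        lor <- log(a * d_ / (b * c_))
        se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_)
        assoc <- c(exp(lor), exp(lor - qnorm(0.975) * se),
                   exp(lor + qnorm(0.975) * se), p_f)
      } else {
        assoc <- c(NA_real_, NA_real_, NA_real_, p_f)
      }
    }
    tibble::tibble(call_rate = call_rate, cohort_maf = maf, hwe_p = hwe,
                   het_ratio = het_ratio, assoc_or = assoc[1],
                   assoc_ci_low = assoc[2], assoc_ci_high = assoc[3],
                   assoc_p = assoc[4])
  })
  v$cohort_maf <- NULL # recomputed here over non-missing genotypes
  dplyr::bind_cols(v, res)
}

align_phenotype <- function(phenotype, samples) {
  if (is.data.frame(phenotype)) {
    assert_that(all(c("participant_id", "group") %in% names(phenotype)),
                "phenotype tibble needs participant_id and group")
    m <- match(samples, phenotype$participant_id)
    assert_that(!anyNA(m), "samples missing from the phenotype table")
    y <- as.numeric(phenotype$group[m] == "GOOD")
  } else {
    assert_that(length(phenotype) == length(samples),
                "phenotype length must match samples")
    y <- as.numeric(phenotype)
  }
  assert_that(all(y %in% c(0, 1)), "phenotype must be binary")
  y
}
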