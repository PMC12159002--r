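# ---- seeded synthetic cohort generator ----

#' Default ancestry mixture of the emulated cohort
#'
#' Admixed pediatric exome cohort proportions: 62% Admixed American,
#' 23% European, 8% East Asian, 5% African, 2% South Asian.
#' @export
default_ancestry_proportions <- function() {
  c(AFR = 0.05, AMR = 0.62, EAS = 0.08, EUR = 0.23, SAS = 0.02)
}

#' Default per-ancestry HLA risk-allele carrier frequencies
#'
#' Carrier (not allele) frequencies for the actionable alleles, chosen to
#' be realistic for the respective super-populations; under the default
#' ancestry mixture roughly 8% of samples carry at least one.
#'
#' @return tibble `allele`, `AFR`, `AMR`, `EAS`, `EUR`, `SAS`.
#' @export
default_hla_carrier_freqs <- function() {
  tibble::tribble(
    ~allele,   ~AFR,   ~AMR,   ~EAS,   ~EUR,    ~SAS,
    "B*57:01", 0.025,  0.020,  0.010,  0.060,   0.060,
    "B*58:01", 0.060,  0.020,  0.060,  0.010,   0.040,
    "A*31:01", 0.020,  0.040,  0.040,  0.030,   0.020,
    "B*15:11", 0.001,  0.001,  0.010,  0.0005,  0.001,
    "B*15:02", 0.0005, 0.002,  0.040,  0.0005,  0.020
  )
}

#' Simulation configuration
#'
#' Collects the study conditions the generator emulates: cohort size and
#' ancestry mixture, the allele catalog with per-ancestry frequencies
#' (Hardy-Weinberg diplotype draws within each stratum), a truncated-normal
#' exome depth model (mean 162X) with explicit capture-gap positions, a
#' per-gene duplication rate (whole-gene deletions arise through the
#' catalog's deletion-allele frequency), and per-ancestry HLA carrier
#' frequencies.
#'
#' @param n_samples cohort size (default 1777 probands).
#' @param ancestry_proportions named fractions summing to 1.
#' @param catalog a `pgx_catalog`.
#' @param depth_mean,depth_sd truncated-normal depth model (reads).
#' @param capture_gaps tibble `gene`, `chrom`, `pos`, `gap_mean`.
#' @param duplication_rates named per-gene duplication probabilities.
#' @param hla_carrier_freqs per-ancestry carrier frequency tibble.
#' @param seed integer seed; every random draw is governed by it.
#' @return list of class `pgx_sim_config`.
#' @export
simulation_config <- function(n_samples = 1777,
                              ancestry_proportions = default_ancestry_proportions(),
                              catalog = example_catalog(),
                              depth_mean = 162, depth_sd = 30,
                              capture_gaps = default_capture_gaps(),
                              duplication_rates = c(CYP2D6 = 0.01),
                              hla_carrier_freqs = default_hla_carrier_freqs(),
                              seed = 1L) {
  if (abs(sum(ancestry_proportions) - 1) > 1e-9) {
    stop("ancestry proportions must sum to 1")
  }
  structure(list(
    n_samples = n_samples, ancestry_proportions = ancestry_proportions,
    catalog = catalog, depth_mean = depth_mean, depth_sd = depth_sd,
    capture_gaps = capture_gaps, duplication_rates = duplication_rates,
    hla_carrier_freqs = hla_carrier_freqs, seed = as.integer(seed)
  ), class = "pgx_sim_config")
}

# normalized allele frequencies of one gene for one ancestry
gene_freqs_for <- function(catalog, gene, ancestry) {
  al <- gene_alleles(catalog, gene)
  al <- al[!grepl("x2$", al$allele), ]
  f <- al[[paste0("freq_", ancestry)]]
  if (all(is.na(f)) || sum(f, na.rm = TRUE) <= 0) {
    stop("no usable frequencies for gene ", gene, " ancestry ", ancestry)
  }
  f[is.na(f)] <- 0
  setNames(f / sum(f), al$allele)
}

#' Simulate a cohort with truth tables and pipeline input files
#'
#' Draws ancestry labels from the configured mixture, per gene two star
#' alleles per sample from the ancestry's frequencies (Hardy-Weinberg),
#' converts drawn haplotypes to unphased genotype dosages at the
#' haplotype-defining positions, applies duplication events at the
#' configured rates, simulates per-sample depth (capture gaps override the
#' exome mean), and draws HLA risk-allele carriers. Deterministic given
#' the seed: the truth table is consistent with the emitted VCF, depth,
#' copy-number and HLA files by construction.
#'
#' @param cfg a `pgx_sim_config`.
#' @param out_dir directory for the emitted files (created if needed);
#'   `NULL` skips file emission and returns tables only.
#' @return list: `truth` (sample x gene tibble: ancestry, diplotype,
#'   total_copies, phenotype), `ancestry`, `cn`, `hla`, `depth` tibbles,
#'   and `paths` when files were written (`vcf`, `depth`, `cn`, `hla`,
#'   `ancestry`, `truth`).
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pgx_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  catalog <- cfg$catalog
  sample_ids <- sprintf("S%04d", seq_len(n))
  ancs <- names(cfg$ancestry_proportions)
  ancestry <- if (n > 0) {
    sample(ancs, n, replace = TRUE, prob = cfg$ancestry_proportions)
  } else character(0)

  genes <- unique(catalog$variants$gene)
  defs_all <- lapply(genes, function(g) haplotype_defining_positions(catalog, g))
  names(defs_all) <- genes

  truth_rows <- list()
  cn_rows <- list()
  # per-position dosage accumulator
  all_defs <- dplyr::bind_rows(defs_all)
  vids <- variant_id(all_defs$chrom, all_defs$pos, all_defs$ref, all_defs$alt)
  dosage <- matrix(0L, nrow = nrow(all_defs), ncol = n,
                   dimnames = list(vids, sample_ids))

  for (g in genes) {
    m <- allele_dosage_matrix(catalog, g)
    del <- deletion_allele_name(g)
    dup_rate <- cfg$duplication_rates[g]
    dup_rate <- if (length(dup_rate) == 0 || is.na(dup_rate)) 0 else dup_rate
    freq_cache <- lapply(setNames(ancs, ancs), function(a) {
      gene_freqs_for(catalog, g, a)
    })
    a1 <- character(n); a2 <- character(n)
    for (a in ancs) {
      idx <- which(ancestry == a)
      if (length(idx) == 0) next
      f <- freq_cache[[a]]
      a1[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
      a2[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
    }
    # duplication events (only for samples without a deleted haplotype)
    dup <- if (n > 0) runif(n) < dup_rate & a1 != del & a2 != del else logical(0)
    copies <- 2L - (a1 == del) - (a2 == del) + dup
    truth_dip <- character(n)
    for (i in seq_len(n)) {
      h1 <- a1[i]; h2 <- a2[i]
      # genotype dosage comes from the base haplotypes (a duplicated
      # haplotype still contributes a single chromosome's alleles)
      d <- rep(0L, ncol(m))
      if (h1 %in% rownames(m)) d <- d + m[h1, ]
      if (h2 %in% rownames(m)) d <- d + m[h2, ]
      if (length(d) > 0 && ncol(m) > 0) {
        dosage[colnames(m), sample_ids[i]] <- as.integer(d)
      }
      if (dup[i]) h1 <- paste0(h1, "x2")
      truth_dip[i] <- pair_string(h1, h2)
    }
    # genes without a shipped translation rule get no truth phenotype
    has_rule <- g %in% default_gene_rules()$gene
    ph <- if (has_rule) {
      vapply(seq_len(n), function(i) {
        translate_diplotype(g, truth_dip[i], catalog)$label
      }, "")
    } else rep(NA_character_, n)
    truth_rows[[g]] <- tibble::tibble(
      sample_id = sample_ids, ancestry = ancestry, gene = g,
      diplotype = truth_dip, total_copies = as.integer(copies),
      phenotype = ph)
    nc2 <- which(copies != 2L)
    if (length(nc2) > 0) {
      cn_rows[[g]] <- tibble::tibble(
        sample_id = sample_ids[nc2], gene = g,
        total_copies = as.integer(copies[nc2]),
        duplicated_allele_hint = ifelse(dup[nc2], sub("x2$", "", a1[nc2]),
                                        NA_character_))
    }
  }
  truth <- dplyr::bind_rows(truth_rows)
  cn <- if (length(cn_rows) > 0) dplyr::bind_rows(cn_rows) else
    tibble::tibble(sample_id = character(), gene = character(),
                   total_copies = integer(),
                   duplicated_allele_hint = character())

  # depth: truncated normal per sample x position; gaps override the mean
  gap_key <- paste(cfg$capture_gaps$chrom, cfg$capture_gaps$pos)
  pos_key <- paste(all_defs$chrom, all_defs$pos)
  gap_idx <- match(pos_key, gap_key)
  mean_vec <- ifelse(is.na(gap_idx), cfg$depth_mean,
                     cfg$capture_gaps$gap_mean[gap_idx])
  sd_vec <- ifelse(is.na(gap_idx), cfg$depth_sd,
                   pmax(cfg$capture_gaps$gap_mean[gap_idx] / 3, 0.5))
  depth <- tibble::tibble(
    sample_id = rep(sample_ids, each = nrow(all_defs)),
    chrom = rep(all_defs$chrom, n),
    pos = rep(all_defs$pos, n),
    depth = pmax(0, round(rnorm(nrow(all_defs) * n,
                                mean = rep(mean_vec, n),
                                sd = rep(sd_vec, n))))
  )

  # HLA: carrier draws per ancestry; non-carriers get common background
  hf <- cfg$hla_carrier_freqs
  background <- list(A = c("A*02:01", "A*03:01"), B = c("B*44:02", "B*07:02"))
  hla_rows <- lapply(seq_len(n), function(i) {
    pr <- hf[[ancestry[i]]]
    carried <- hf$allele[runif(nrow(hf)) < pr]
    a_all <- c(carried[grepl("^A\\*", carried)], background$A)[1:2]
    b_all <- c(carried[grepl("^B\\*", carried)], background$B)[1:2]
    tibble::tibble(sample_id = sample_ids[i],
                   locus = c("HLA-A", "HLA-B"),
                   allele1 = c(a_all[1], b_all[1]),
                   allele2 = c(a_all[2], b_all[2]))
  })
  hla <- dplyr::bind_rows(hla_rows)
  ancestry_tbl <- tibble::tibble(sample_id = sample_ids, ancestry = ancestry)

  out <- list(truth = truth, ancestry = ancestry_tbl, cn = cn, hla = hla,
              depth = depth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vcf_path <- file.path(out_dir, "cohort.vcf.gz")
    write_cohort_vcf(all_defs, dosage, vcf_path)
    paths <- list(
      vcf = vcf_path,
      depth = file.path(out_dir, "depth.tsv"),
      cn = file.path(out_dir, "copy_number.tsv"),
      hla = file.path(out_dir, "hla_calls.tsv"),
      ancestry = file.path(out_dir, "ancestry.tsv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    readr::write_tsv(depth, paths$depth)
    readr::write_tsv(cn, paths$cn, na = "")
    readr::write_tsv(hla, paths$hla)
    readr::write_tsv(ancestry_tbl, paths$ancestry)
    readr::write_tsv(truth, paths$truth)
    out$paths <- paths
  }
  out
}

# emit a minimal VCF v4.2 with GT fields through vcfR
write_cohort_vcf <- function(defs, dosage, path) {
  ord <- order(defs$chrom, defs$pos)
  defs <- defs[ord, ]
  dosage <- dosage[ord, , drop = FALSE]
  gt_str <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L],
                   nrow = nrow(dosage), dimnames = dimnames(dosage))
  fix <- cbind(
    CHROM = defs$chrom, POS = as.character(defs$pos),
    ID = ifelse(is.na(defs$rsid), ".", defs$rsid),
    REF = defs$ref, ALT = defs$alt,
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  meta <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", unique(defs$chrom), ">")
  )
  gt <- cbind(FORMAT = "GT", gt_str)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Simulate phenotype labels directly from a frequency table
#'
#' The fast, genotype-free simulation level: ancestry labels are drawn
#' from the mixture and per-gene phenotype labels from the stratum's
#' frequency table, for exercising actionability scoring and cohort
#' reporting without a frequency-consistent allele catalog.
#'
#' @param freqs tibble `gene`, `ancestry`, `phenotype`, `pct` with
#'   per-stratum percentages summing to ~100.
#' @param n number of samples (0 gives an empty truth table).
#' @param seed integer seed.
#' @param ancestry_proportions named mixture (default cohort mixture).
#' @return tibble `sample_id`, `ancestry`, `gene`, `phenotype`.
#' @export
simulate_from_phenotype_freqs <- function(freqs, n, seed = 1L,
                                          ancestry_proportions =
                                            default_ancestry_proportions()) {
  if (any(freqs$pct < 0)) stop("negative phenotype frequency")
  sums <- freqs |>
    dplyr::group_by(.data$gene, .data$ancestry) |>
    dplyr::summarise(s = sum(.data$pct), .groups = "drop")
  if (any(abs(sums$s - 100) > 0.5)) {
    stop("per-stratum frequencies must sum to ~100; offending strata: ",
         paste(head(paste0(sums$gene, "/", sums$ancestry)[abs(sums$s - 100) > 0.5], 3),
               collapse = ", "))
  }
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), ancestry = character(),
                          gene = character(), phenotype = character()))
  }
  set.seed(seed)
  sample_ids <- sprintf("P%04d", seq_len(n))
  ancestry <- sample(names(ancestry_proportions), n, replace = TRUE,
                     prob = ancestry_proportions)
  genes <- unique(freqs$gene)
  rows <- lapply(genes, function(g) {
    lab <- character(n)
    for (a in unique(ancestry)) {
      idx <- which(ancestry == a)
      sub <- freqs[freqs$gene == g & freqs$ancestry == a, ]
      if (nrow(sub) == 0) {
        stop("no phenotype frequencies for gene ", g, " ancestry ", a)
      }
      lab[idx] <- sample(sub$phenotype, length(idx), replace = TRUE,
                         prob = sub$pct)
    }
    tibble::tibble(sample_id = sample_ids, ancestry = ancestry, gene = g,
                   phenotype = lab)
  })
  dplyr::bind_rows(rows)
}
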