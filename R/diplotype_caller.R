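# ---- star-allele diplotype calling from unphased genotypes ----

# order a pair of allele names canonically (by star number, then name)
sort_pair <- function(a, b) {
  p <- c(a, b)
  p[order(star_key(p), p)]
}

pair_string <- function(a, b) paste(sort_pair(a, b), collapse = "/")

parse_diplotype <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("unparseable diplotype string: ", x)
  sort_pair(parts[1], parts[2])
}

#' Enumerate candidate diplotypes consistent with unphased dosages
#'
#' All unordered pairs (A, B) of non-structural catalog alleles whose
#' summed per-position dosages reproduce the observed alt-allele dosages
#' at every haplotype-defining position of the gene. Unphased genotypes
#' cannot distinguish, e.g., `*1`/`*6` from `*4`/`*9` when `*6` carries the
#' union of the `*4` and `*9` variants — both pairs are returned.
#'
#' @param dosages named numeric vector of alt-allele dosages in 0/1/2,
#'   named by `chrom:pos:ref:alt`; positions of the gene absent from the
#'   vector are treated as dosage 0 (covered-but-absent = reference).
#' @param gene gene symbol.
#' @param catalog a `pgx_catalog`.
#' @return list of length-2 character vectors (allele pairs), ordered
#'   lexicographically by star number; empty list if no pair explains the
#'   dosage vector.
#' @export
enumerate_candidates <- function(dosages, gene, catalog) {
  m <- allele_dosage_matrix(catalog, gene)
  keep <- !is_structural_allele(gene, rownames(m))
  m <- m[keep, , drop = FALSE]
  obs <- setNames(rep(0, ncol(m)), colnames(m))
  known <- intersect(names(dosages), colnames(m))
  obs[known] <- dosages[known]
  alleles <- rownames(m)
  n <- length(alleles)
  cands <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(m[i, ] + m[j, ] == obs)) {
        cands[[length(cands) + 1L]] <- sort_pair(alleles[i], alleles[j])
      }
    }
  }
  if (length(cands) > 1) {
    ord <- order(star_key(vapply(cands, `[`, "", 1)),
                 star_key(vapply(cands, `[`, "", 2)),
                 vapply(cands, paste, "", collapse = "/"))
    cands <- cands[ord]
  }
  cands
}

#' Resolve phasing ambiguity by population frequency
#'
#' Among candidate pairs, selects the pair maximizing the product of the
#' two alleles' frequencies in the sample's ancestry — the behavior of
#' resolvers that report the most commonly observed diplotype when phase
#' is unknown. Ties and all-zero frequencies fall back deterministically
#' to the pair containing the lowest star number, flagged
#' `low_confidence`; a single candidate is `unambiguous`.
#'
#' @param candidates nonempty list of allele pairs.
#' @param ancestry ancestry code (AFR/AMR/EAS/EUR/SAS).
#' @param gene gene symbol.
#' @param catalog a `pgx_catalog`.
#' @return list with `selected` (character length-2) and `resolution`.
#' @export
resolve_by_frequency <- function(candidates, ancestry, gene, catalog) {
  if (length(candidates) == 0) stop("no candidates to resolve")
  if (length(candidates) == 1) {
    return(list(selected = candidates[[1]], resolution = "unambiguous"))
  }
  score <- vapply(candidates, function(p) {
    allele_freq(catalog, gene, p[1], ancestry) *
      allele_freq(catalog, gene, p[2], ancestry)
  }, numeric(1))
  if (all(score == 0)) {
    return(list(selected = candidates[[1]], resolution = "low_confidence"))
  }
  best <- which(score == max(score))
  if (length(best) > 1) {
    # tie: candidates are already ordered by star number, take the first
    return(list(selected = candidates[[best[1]]],
                resolution = "low_confidence"))
  }
  list(selected = candidates[[best]], resolution = "frequency_resolved")
}

#' Adjust a diplotype call for gene copy number
#'
#' Copy number arrives as an input (exome read-depth CNV estimation is
#' unreliable for these genes): 1 copy pairs the single explained
#' haplotype with the deletion allele (e.g. `*1/*5`), 0 copies is a
#' homozygous deletion, 3 copies appends `x2` to the hinted allele (or,
#' absent a hint, to the higher-frequency allele of the selected pair,
#' flagged `low_confidence`), and 2 copies leaves the call unchanged.
#'
#' @param call one-row diplotype call (as produced by [call_cohort()]).
#' @param total_copies integer gene copy number >= 0.
#' @param catalog a `pgx_catalog`.
#' @param duplicated_allele_hint optional allele name carried twice.
#' @param ancestry ancestry code used for the hint-free duplication choice.
#' @param dosages the observed dosage vector (used to re-derive the single
#'   haplotype under a deletion).
#' @return the adjusted one-row call.
#' @export
apply_copy_number <- function(call, total_copies, catalog,
                              duplicated_allele_hint = NA,
                              ancestry = "AMR", dosages = NULL) {
  gene <- call$gene
  del <- deletion_allele_name(gene)
  has_del <- del %in% catalog$alleles$allele[catalog$alleles$gene == gene]
  if (total_copies == 2L) return(call)
  if (total_copies <= 1L && !has_del) {
    call$selected <- NA_character_
    call$resolution <- "no_call"
    call$notes <- paste0("copy number ", total_copies, " but no deletion ",
                         "allele (", del, ") defined for ", gene)
    return(call)
  }
  if (total_copies == 0L) {
    call$selected <- pair_string(del, del)
    call$candidates <- call$selected
    call$resolution <- "unambiguous"
    return(call)
  }
  if (total_copies == 1L) {
    hap <- NA_character_
    if (!is.null(dosages)) {
      # single remaining haplotype: the allele whose defining dosage
      # pattern equals the observed vector read as haploid
      m <- allele_dosage_matrix(catalog, gene)
      m <- m[!is_structural_allele(gene, rownames(m)), , drop = FALSE]
      obs <- setNames(rep(0, ncol(m)), colnames(m))
      known <- intersect(names(dosages), colnames(m))
      obs[known] <- dosages[known]
      hit <- which(apply(m, 1, function(r) all(r == obs)))
      if (length(hit) == 1) hap <- rownames(m)[hit]
    }
    if (is.na(hap)) {
      sel <- if (!is.na(call$selected)) parse_diplotype(call$selected)
             else c("*1", "*1")
      hap <- sel[1]
      call$resolution <- "low_confidence"
    }
    call$selected <- pair_string(hap, del)
    call$candidates <- call$selected
    if (call$resolution %in% c("multi_reported", "no_call")) {
      call$resolution <- "low_confidence"
    }
    return(call)
  }
  # total_copies >= 3: duplication
  if (is.na(call$selected)) return(call)
  sel <- parse_diplotype(call$selected)
  if (!is.na(duplicated_allele_hint) &&
      duplicated_allele_hint %in% sel) {
    dup_idx <- match(duplicated_allele_hint, sel)
  } else {
    f <- c(allele_freq(catalog, gene, sel[1], ancestry),
           allele_freq(catalog, gene, sel[2], ancestry))
    dup_idx <- which.max(f)
    call$resolution <- "low_confidence"
  }
  sel[dup_idx] <- paste0(sel[dup_idx], "x2")
  call$selected <- pair_string(sel[1], sel[2])
  call
}

# GT string -> alt dosage (unphased or phased separators accepted)
gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
}

#' Call star-allele diplotypes for a cohort from a VCF
#'
#' Reads unphased genotypes at the catalog's haplotype-defining positions,
#' enumerates candidate diplotypes per sample x gene, and either resolves
#' ambiguity by ancestry-specific population frequency (`single_call`) or
#' reports all candidates with no selection (`multi_report`). Copy-number
#' input (deletions/duplications) and per-sample depth flags are applied
#' when provided; positions below the per-sample depth threshold downgrade
#' the call to `low_confidence` rather than silently passing as reference.
#'
#' @param vcf path to a VCF v4.2 file (GT fields; unphased accepted).
#' @param catalog a `pgx_catalog`.
#' @param ancestry tibble `sample_id`, `ancestry` sidecar.
#' @param genes genes to call (default: all catalog genes with defining
#'   variants).
#' @param cn optional tibble `sample_id`, `gene`, `total_copies`,
#'   `duplicated_allele_hint`.
#' @param depth optional per-sample depth tibble (`sample_id`, `chrom`,
#'   `pos`, `depth`) for covered-position logic.
#' @param mode `"single_call"` or `"multi_report"`.
#' @param depth_threshold per-sample covered-position threshold (reads).
#' @return tibble: `sample_id`, `gene`, `candidates` (semicolon-joined),
#'   `selected`, `resolution`, `notes`.
#' @export
call_cohort <- function(vcf, catalog, ancestry, genes = NULL, cn = NULL,
                        depth = NULL, mode = c("single_call", "multi_report"),
                        depth_threshold = 20) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  vcf_ids <- variant_id(fix[, "CHROM"], as.numeric(fix[, "POS"]),
                        fix[, "REF"], fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (is.null(genes)) {
    genes <- unique(catalog$variants$gene)
  }
  # contig sanity: every catalog contig for the requested genes must
  # appear in the VCF (unless the gene has no defining variants)
  cat_chrom <- unique(catalog$variants$chrom[catalog$variants$gene %in% genes])
  missing_contig <- setdiff(cat_chrom, unique(fix[, "CHROM"]))
  if (length(missing_contig) > 0) {
    stop("VCF/catalog contig mismatch; catalog contigs absent from VCF: ",
         paste(missing_contig, collapse = ", "))
  }
  dosage_mat <- matrix(NA_real_, nrow = length(vcf_ids), ncol = length(samples),
                       dimnames = list(vcf_ids, samples))
  for (s in samples) dosage_mat[, s] <- gt_to_dosage(gt[, s])
  anc <- setNames(ancestry$ancestry, ancestry$sample_id)
  anc_of <- function(s) {
    a <- unname(anc[s])
    if (length(a) == 0 || is.na(a)) "AMR" else a
  }

  cov_lookup <- NULL
  if (!is.null(depth)) {
    cov <- per_sample_coverage(depth, threshold = depth_threshold)
    cov_lookup <- setNames(cov$covered,
                           paste(cov$sample_id, cov$chrom, cov$pos))
  }
  cn_key <- if (!is.null(cn)) paste(cn$sample_id, cn$gene) else character()

  rows <- vector("list", length(samples) * length(genes))
  k <- 0L
  for (g in genes) {
    defs <- haplotype_defining_positions(catalog, g)
    ids <- variant_id(defs$chrom, defs$pos, defs$ref, defs$alt)
    present <- intersect(ids, vcf_ids)
    for (s in samples) {
      d <- dosage_mat[present, s]
      names(d) <- present
      d[is.na(d)] <- 0  # missing genotype at covered position -> reference
      cands <- enumerate_candidates(d, g, catalog)
      notes <- NA_character_
      if (length(cands) == 0) {
        row <- tibble::tibble(sample_id = s, gene = g,
                              candidates = NA_character_,
                              selected = NA_character_,
                              resolution = "no_call",
                              notes = paste0("no allele pair explains dosages at ",
                                             paste(names(d)[d > 0], collapse = ",")))
      } else if (mode == "multi_report" && length(cands) > 1) {
        row <- tibble::tibble(
          sample_id = s, gene = g,
          candidates = paste(vapply(cands, paste, "", collapse = "/"),
                             collapse = ";"),
          selected = NA_character_, resolution = "multi_reported",
          notes = notes)
      } else {
        res <- resolve_by_frequency(cands, anc_of(s), g, catalog)
        row <- tibble::tibble(
          sample_id = s, gene = g,
          candidates = paste(vapply(cands, paste, "", collapse = "/"),
                             collapse = ";"),
          selected = pair_string(res$selected[1], res$selected[2]),
          resolution = res$resolution, notes = notes)
      }
      # per-sample coverage gate: uncovered defining position -> low confidence
      if (!is.null(cov_lookup) && length(ids) > 0) {
        keys <- paste(s, defs$chrom, defs$pos)
        covered <- cov_lookup[keys]
        if (any(!is.na(covered) & !covered)) {
          if (!row$resolution %in% c("no_call")) {
            row$resolution <- "low_confidence"
          }
          row$notes <- paste0("uncovered defining position(s): ",
                              paste(defs$pos[!is.na(covered) & !covered],
                                    collapse = ","))
        }
      }
      # copy-number adjustment
      if (!is.null(cn)) {
        hit <- match(paste(s, g), cn_key)
        if (!is.na(hit) && mode == "single_call") {
          row <- apply_copy_number(
            row, cn$total_copies[hit], catalog,
            duplicated_allele_hint = cn$duplicated_allele_hint[hit] %||% NA,
            ancestry = anc_of(s), dosages = d)
        }
      }
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
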