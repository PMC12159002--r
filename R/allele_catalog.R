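#' @importFrom rlang .data
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head modifyList
#' @importFrom methods new
#' @importClassesFrom vcfR vcfR
NULL

#' 1000 Genomes super-population codes used throughout the package
#'
#' Ordered ancestry codes: African (AFR), Admixed American (AMR),
#' East Asian (EAS), European (EUR), South Asian (SAS).
#'
#' @export
pgx_ancestries <- function() c("AFR", "AMR", "EAS", "EUR", "SAS")

freq_cols <- function() paste0("freq_", pgx_ancestries())

# canonical string id for a variant (1-based GRCh38 VCF convention)
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a star-allele catalog from allele and variant tables
#'
#' A catalog holds, per gene, the named star alleles (haplotypes), their
#' defining variants, assigned function class, activity value and
#' ancestry-specific population frequencies. It is the source of
#' haplotype-defining positions for coverage QC, diplotype calling and
#' simulation.
#'
#' @param alleles tibble with columns `gene`, `allele`, `function_class`
#'   (one of normal, decreased, no_function, increased, uncertain, unknown),
#'   `activity` (numeric, may be `NA`), `freq_AFR` .. `freq_SAS`.
#' @param variants tibble with columns `gene`, `allele`, `chrom`, `pos`,
#'   `ref`, `alt`, `rsid` — one row per defining variant of an allele.
#'   Reference alleles (e.g. `*1`) have no rows here.
#' @return An object of class `pgx_catalog`.
#' @export
pgx_catalog <- function(alleles, variants) {
  alleles <- tibble::as_tibble(alleles)
  variants <- tibble::as_tibble(variants)
  obj <- structure(list(alleles = alleles, variants = variants),
                   class = "pgx_catalog")
  validate_catalog(obj)
  obj
}

#' @exportS3Method base::print
print.pgx_catalog <- function(x, ...) {
  cat(sprintf("<pgx_catalog> %d genes, %d alleles, %d defining variants\n",
              length(unique(x$alleles$gene)), nrow(x$alleles),
              nrow(unique(x$variants[, c("chrom", "pos", "ref", "alt")]))))
  invisible(x)
}

function_classes <- function() {
  c("normal", "decreased", "no_function", "increased", "uncertain", "unknown")
}

validate_catalog <- function(cat) {
  al <- cat$alleles
  vr <- cat$variants
  need <- c("gene", "allele", "function_class", "activity", freq_cols())
  miss <- setdiff(need, names(al))
  if (length(miss) > 0) {
    stop("catalog allele table missing columns: ", paste(miss, collapse = ", "))
  }
  dup <- al[duplicated(al[, c("gene", "allele")]), ]
  if (nrow(dup) > 0) {
    stop("duplicate allele definition: ",
         paste(unique(paste0(dup$gene, dup$allele)), collapse = ", "))
  }
  ref_missing <- setdiff(unique(al$gene),
                         al$gene[al$allele %in% c("*1", "Reference")])
  if (length(ref_missing) > 0) {
    stop("gene(s) without a reference allele (*1): ",
         paste(ref_missing, collapse = ", "))
  }
  for (fc in freq_cols()) {
    bad <- !is.na(al[[fc]]) & (al[[fc]] < 0 | al[[fc]] > 1)
    if (any(bad)) stop("frequencies outside [0,1] in ", fc)
  }
  # per-ancestry frequency mass per gene must not exceed 1 (small tolerance)
  for (g in unique(al$gene)) {
    sub <- al[al$gene == g, ]
    for (fc in freq_cols()) {
      s <- sum(sub[[fc]], na.rm = TRUE)
      if (s > 1 + 0.01) {
        stop(sprintf("frequencies for gene %s ancestry %s sum to %.3f > 1",
                     g, sub("freq_", "", fc), s))
      }
    }
  }
  if (nrow(vr) > 0) {
    if (any(vr$pos <= 0)) stop("variant pos must be positive")
    badseq <- !grepl("^[ACGT]+$", vr$ref) | !grepl("^[ACGT]+$", vr$alt) |
      vr$ref == vr$alt
    if (any(badseq)) {
      stop("invalid ref/alt at rows: ",
           paste(which(badseq), collapse = ", "))
    }
    orphan <- !paste0(vr$gene, vr$allele) %in% paste0(al$gene, al$allele)
    if (any(orphan)) {
      stop("variant rows for undefined alleles: ",
           paste(unique(paste0(vr$gene, vr$allele)[orphan]), collapse = ", "))
    }
    # a position must map to a single ref/alt within one gene
    key <- unique(vr[, c("gene", "chrom", "pos", "ref", "alt")])
    if (anyDuplicated(key[, c("gene", "chrom", "pos")]) > 0) {
      stop("a genomic position maps to more than one ref/alt within a gene")
    }
  }
  invisible(cat)
}

#' Load a star-allele catalog from a flat TSV
#'
#' One row per allele x defining-variant; reference alleles appear as a
#' single row with empty `chrom`/`pos`/`ref`/`alt`. Function strings
#' outside the known vocabulary are parsed as `unknown` with a warning;
#' duplicate (gene, allele, variant) definitions are a hard error.
#'
#' @param path TSV with columns `gene`, `allele`, `chrom`, `pos`, `ref`,
#'   `alt`, `rsid`, `function`, `activity`, `freq_AFR` .. `freq_SAS`.
#' @return A `pgx_catalog`.
#' @export
load_catalog <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", allele = "c", chrom = "c", pos = "d", ref = "c", alt = "c",
    rsid = "c", `function` = "c", activity = "d",
    .default = readr::col_double()
  ), na = c("", "NA"))
  need <- c("gene", "allele", "chrom", "pos", "ref", "alt", "function",
            "activity", freq_cols())
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) stop("catalog TSV missing columns: ",
                             paste(miss, collapse = ", "))
  if (!"rsid" %in% names(raw)) raw$rsid <- NA_character_
  bad_fun <- !is.na(raw$`function`) & !raw$`function` %in% function_classes()
  if (any(bad_fun)) {
    warning("unknown function string(s) at line(s) ",
            paste(which(bad_fun) + 1L, collapse = ", "),
            "; parsed as 'unknown'")
    raw$`function`[bad_fun] <- "unknown"
  }
  raw$`function`[is.na(raw$`function`)] <- "unknown"
  # structural validation with line numbers (header is line 1)
  has_var <- !is.na(raw$pos)
  bad <- has_var & (is.na(raw$chrom) | is.na(raw$ref) | is.na(raw$alt))
  if (any(bad)) {
    stop("malformed variant row(s) at line(s) ",
         paste(which(bad) + 1L, collapse = ", "))
  }
  vtab <- raw[has_var, c("gene", "allele", "chrom", "pos", "ref", "alt", "rsid")]
  if (anyDuplicated(vtab[, c("gene", "allele", "chrom", "pos")]) > 0) {
    stop("duplicate allele definition rows in ", path)
  }
  atab <- raw |>
    dplyr::distinct(.data$gene, .data$allele, .keep_all = TRUE) |>
    dplyr::select("gene", "allele",
                  function_class = "function", "activity",
                  dplyr::all_of(freq_cols()))
  pgx_catalog(atab, tibble::as_tibble(vtab))
}

#' Write a catalog back to the flat TSV format
#'
#' Inverse of [load_catalog()]: content round-trips up to row order.
#'
#' @param catalog a `pgx_catalog`.
#' @param path output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  al <- catalog$alleles
  vr <- catalog$variants
  rows <- dplyr::left_join(al, vr, by = c("gene", "allele"))
  if (!"rsid" %in% names(rows)) rows$rsid <- NA_character_
  out <- rows |>
    dplyr::select("gene", "allele", "chrom", "pos", "ref", "alt", "rsid",
                  `function` = "function_class", "activity",
                  dplyr::all_of(freq_cols())) |>
    dplyr::arrange(.data$gene, .data$allele, .data$pos)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Haplotype-defining positions of a gene
#'
#' Deduplicated union of the defining variants of all star alleles of
#' `gene`, sorted by genomic position. Missing coverage at these positions
#' is what makes exome diplotype calls unreliable.
#'
#' @param catalog a `pgx_catalog`.
#' @param gene gene symbol present in the catalog.
#' @return tibble with columns `gene`, `chrom`, `pos`, `ref`, `alt`, `rsid`.
#' @export
haplotype_defining_positions <- function(catalog, gene) {
  if (!gene %in% catalog$alleles$gene) {
    stop("gene not in catalog: ", gene)
  }
  vr <- catalog$variants[catalog$variants$gene == gene, ]
  if (nrow(vr) == 0) {
    return(tibble::tibble(gene = character(), chrom = character(),
                          pos = numeric(), ref = character(),
                          alt = character(), rsid = character()))
  }
  vr |>
    dplyr::distinct(.data$gene, .data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$rsid) |>
    dplyr::arrange(.data$pos)
}

#' Alleles of one gene
#' @param catalog a `pgx_catalog`.
#' @param gene gene symbol.
#' @return allele tibble restricted to `gene`.
#' @export
gene_alleles <- function(catalog, gene) {
  if (!gene %in% catalog$alleles$gene) stop("gene not in catalog: ", gene)
  catalog$alleles[catalog$alleles$gene == gene, ]
}

# numeric sort key for star-allele names: *1 < *2 < *2x2 < *10 < *DEL
star_key <- function(allele) {
  num <- suppressWarnings(as.numeric(sub("^\\*([0-9]+).*$", "\\1", allele)))
  dup <- grepl("x2$", allele)
  num[is.na(num)] <- 1e6  # *DEL and other non-numeric names sort last
  num + ifelse(dup, 0.5, 0)
}

# 0/1 dosage matrix (allele x variant id) for a gene's defining positions
allele_dosage_matrix <- function(catalog, gene) {
  defs <- haplotype_defining_positions(catalog, gene)
  alleles <- gene_alleles(catalog, gene)$allele
  alleles <- alleles[order(star_key(alleles), alleles)]
  vids <- variant_id(defs$chrom, defs$pos, defs$ref, defs$alt)
  m <- matrix(0L, nrow = length(alleles), ncol = length(vids),
              dimnames = list(alleles, vids))
  vr <- catalog$variants[catalog$variants$gene == gene, ]
  if (nrow(vr) > 0) {
    ids <- variant_id(vr$chrom, vr$pos, vr$ref, vr$alt)
    for (i in seq_len(nrow(vr))) m[vr$allele[i], ids[i]] <- 1L
  }
  m
}

# ancestry-specific allele frequency lookup; missing -> 0
allele_freq <- function(catalog, gene, allele, ancestry) {
  al <- catalog$alleles
  # duplication suffix inherits the base allele's frequency
  base <- sub("x2$", "", allele)
  f <- al[[paste0("freq_", ancestry)]][al$gene == gene & al$allele == base]
  if (length(f) == 0 || is.na(f)) 0 else f
}
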