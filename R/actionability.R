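# ---- binary actionability scoring of phenotypes and HLA alleles ----

#' The phenotype -> 0/1 actionability map
#'
#' The complete binary map over the phenotype vocabulary: a label scores 1
#' when prescribing guidance recommends a change from standard therapy.
#' Rapid Metabolizer is scored 1 exactly as the map prescribes even though
#' some guidelines treat RM as non-actionable for some genes; the map is
#' configuration users can edit. `NA` (no call) and `Indeterminate` score
#' 0.
#'
#' @return tibble `label`, `score`.
#' @export
actionability_map <- function() {
  tibble::tribble(
    ~label,                                                   ~score,
    "Normal Function",                                        0,
    "Decreased Function",                                     1,
    "Poor Function",                                          1,
    "Uncertain Susceptibility",                               0,
    "NA",                                                     0,
    "Indeterminate",                                          0,
    "Intermediate Metabolizer",                               1,
    "Normal Metabolizer",                                     0,
    "Poor Metabolizer",                                       1,
    "Rapid Metabolizer",                                      1,
    "Normal",                                                 0,
    "Possible Decreased Function",                            0,
    "Increased Function",                                     1,
    "Favorable Response",                                     0,
    "Ultra Rapid Metabolizer",                                1,
    "Ultrarapid Metabolizer",                                 1,
    "Possible Intermediate Metabolizer",                      0,
    "Malignant Hyperthermia Susceptibility",                  1,
    "Normal Risk",                                            0,
    "increased risk of aminoglycoside-induced hearing loss",  1,
    "uncertain risk of aminoglycoside-induced hearing loss",  0,
    "normal risk of aminoglycoside-induced hearing loss",     0,
    "moderate deficiency (BCHE)",                             1,
    "mild deficiency or normal activity (BCHE)",              0,
    "G6PD variable or deficient",                             1,
    "G6PD deficient with CNSHA",                              1,
    "G6PD Normal",                                            0
  )
}

#' HLA risk-allele -> drug rules
#'
#' The actionable two-field HLA alleles and the drugs each governs.
#'
#' @return tibble `allele`, `drug`.
#' @export
hla_rules <- function() {
  tibble::tribble(
    ~allele,    ~drug,
    "B*57:01",  "abacavir",
    "B*57:01",  "flucloxacillin",
    "B*58:01",  "allopurinol",
    "A*31:01",  "carbamazepine",
    "B*15:11",  "carbamazepine",
    "B*15:02",  "carbamazepine",
    "B*15:02",  "oxcarbazepine",
    "B*15:02",  "lamotrigine",
    "B*15:02",  "phenytoin",
    "B*15:02",  "fosphenytoin"
  )
}

#' Default gene scope for actionability counting
#'
#' The 18 loci counted (HLA-A and HLA-B scored from HLA calls, the rest
#' from phenotype labels). Genes excluded by coverage QC are dropped from
#' this scope before counting.
#' @export
actionability_scope <- function() c(
  "ABCG2", "CACNA1S", "CFTR", "CYP2B6", "CYP2C9", "CYP2D6", "CYP4F2",
  "DPYD", "G6PD", "BCHE", "NAT2", "NUDT15", "RYR1", "SLCO1B1", "TPMT",
  "MT-RNR1", "HLA-A", "HLA-B"
)

#' Score a phenotype label 0/1
#'
#' @param label character vector of phenotype labels.
#' @param map the actionability map (default [actionability_map()]).
#' @return integer vector of 0/1. Unknown labels are a hard error — never
#'   silently 0.
#' @export
score_phenotype <- function(label, map = actionability_map()) {
  idx <- match(label, map$label)
  if (anyNA(idx)) {
    stop("phenotype label(s) not in actionability map: ",
         paste(unique(label[is.na(idx)]), collapse = "; "))
  }
  as.integer(map$score[idx])
}

# truncate an HLA allele string to two-field resolution
hla_two_field <- function(allele) {
  parts <- strsplit(allele, ":", fixed = TRUE)
  trunc <- vapply(parts, function(p) paste(p[seq_len(min(2, length(p)))],
                                           collapse = ":"), "")
  if (any(vapply(parts, length, 1L) > 2)) {
    warning("HLA allele(s) above two-field resolution truncated")
  }
  trunc
}

#' Score HLA calls per locus
#'
#' HLA-A scores 1 iff A*31:01 is carried; HLA-B scores 1 iff any of
#' B*57:01, B*58:01, B*15:11, B*15:02 is carried. Zygosity is ignored
#' (carrier = actionable). Returns the union of governed drugs.
#'
#' @param alleles character vector of a sample's HLA alleles (two-field,
#'   e.g. `"B*57:01"`; higher resolution is truncated with a warning).
#' @param rules the HLA rule table.
#' @return list with `score_A`, `score_B` (0/1) and `drugs`.
#' @export
score_hla <- function(alleles, rules = hla_rules()) {
  alleles <- hla_two_field(alleles)
  risk <- unique(rules$allele)
  carried <- intersect(alleles, risk)
  list(
    score_A = as.integer(any(grepl("^A\\*", carried))),
    score_B = as.integer(any(grepl("^B\\*", carried))),
    drugs = sort(unique(rules$drug[rules$allele %in% carried]))
  )
}

#' Per-sample actionability profiles
#'
#' Joins phenotype-derived gene scores with HLA locus scores over the gene
#' scope and totals them per sample.
#'
#' @param phenotypes tibble `sample_id`, `gene`, `phenotype`.
#' @param hla optional tibble `sample_id`, `locus`, `allele1`, `allele2`.
#' @param scope gene scope (default [actionability_scope()]); genes
#'   excluded upstream should already be removed.
#' @param map actionability map.
#' @param rules HLA rule table.
#' @return tibble `sample_id`, `gene`, `score` plus an attached per-sample
#'   `total` via [cohort_actionability()]; one row per sample x in-scope
#'   gene.
#' @export
actionability_profiles <- function(phenotypes, hla = NULL,
                                   scope = actionability_scope(),
                                   map = actionability_map(),
                                   rules = hla_rules()) {
  ph <- phenotypes[phenotypes$gene %in% scope, ]
  prof <- tibble::tibble(
    sample_id = ph$sample_id, gene = ph$gene,
    score = score_phenotype(ph$phenotype, map)
  )
  if (!is.null(hla) && any(c("HLA-A", "HLA-B") %in% scope)) {
    hrows <- lapply(unique(hla$sample_id), function(s) {
      al <- c(hla$allele1[hla$sample_id == s], hla$allele2[hla$sample_id == s])
      al <- al[!is.na(al)]
      sc <- score_hla(al, rules)
      tibble::tibble(sample_id = s,
                     gene = c("HLA-A", "HLA-B"),
                     score = c(sc$score_A, sc$score_B))
    })
    hrows <- dplyr::bind_rows(hrows)
    prof <- dplyr::bind_rows(prof, hrows[hrows$gene %in% scope, ])
  }
  prof
}

#' Cohort-level actionability summary
#'
#' @param profiles long tibble `sample_id`, `gene`, `score` (0/1).
#' @return list: `n` samples, `fraction_ge1`, `fraction_ge3` (fractions of
#'   samples with >= 1 and >= 3 actionable loci), `totals` per-sample
#'   tibble, `gene_counts` per-gene actionable counts ranked descending.
#' @export
cohort_actionability <- function(profiles) {
  if (nrow(profiles) == 0) stop("no actionability profiles supplied")
  totals <- profiles |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$score), .groups = "drop")
  gene_counts <- profiles |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_actionable = sum(.data$score),
                     pct = 100 * mean(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_actionable))
  list(
    n = nrow(totals),
    fraction_ge1 = mean(totals$total >= 1),
    fraction_ge3 = mean(totals$total >= 3),
    totals = totals,
    gene_counts = gene_counts
  )
}
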