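# ---- bundled phenotype frequency tables ----

#' Default per-gene, per-ancestry phenotype frequencies
#'
#' The phenotype-level study conditions of the emulated cohort: for each
#' in-scope gene and ancestry stratum, the percentage of each phenotype
#' label. CYP2B6 rows reproduce an observed exome-cohort frequency table;
#' CYP2D6 and CYP2C9 Admixed American values follow reported cohort
#' figures; the remaining cells are realistic values in line with public
#' frequency resources, fixed once as the generator's defaults.
#' Percentages per gene x ancestry sum to 100 (one-decimal rounding).
#'
#' @return tibble `gene`, `ancestry`, `phenotype`, `pct`.
#' @export
default_phenotype_freqs <- function() {
  g <- function(gene, labels, ...) {
    per_anc <- list(...)
    dplyr::bind_rows(lapply(names(per_anc), function(a) {
      tibble::tibble(gene = gene, ancestry = a, phenotype = labels,
                     pct = per_anc[[a]])
    }))
  }
  met <- c("Normal Metabolizer", "Intermediate Metabolizer",
           "Poor Metabolizer", "Rapid Metabolizer", "Ultrarapid Metabolizer",
           "Indeterminate")
  dplyr::bind_rows(
    g("CYP2B6", met,
      AFR = c(22, 54.9, 20.9, 1.1, 0, 1.1),
      AMR = c(34.2, 42.1, 13.2, 5.3, 2.6, 2.6),
      EAS = c(54.5, 26.9, 7.1, 10.3, 0, 1.2),
      EUR = c(48.2, 37.1, 6.2, 5.2, 0.2, 3.1),
      SAS = c(34.2, 42.1, 13.2, 5.3, 2.6, 2.6)),
    g("CYP2D6", met,
      AFR = c(50, 35, 3, 5, 2, 5),
      AMR = c(64.3, 25.5, 5.5, 2.0, 0.2, 2.5),
      EAS = c(45, 45, 1, 1, 1, 7),
      EUR = c(55, 32, 6, 2, 2, 3),
      SAS = c(55, 35, 2, 3, 2, 3)),
    g("CYP2C9", c("Normal Metabolizer", "Intermediate Metabolizer",
                  "Poor Metabolizer", "Indeterminate"),
      AFR = c(80, 17, 1, 2),
      AMR = c(76.6, 20.7, 0.2, 2.5),
      EAS = c(85, 13, 1, 1),
      EUR = c(63, 33, 3, 1),
      SAS = c(70, 26, 3, 1)),
    g("ABCG2", c("Normal Function", "Decreased Function", "Poor Function"),
      AFR = c(96, 3.5, 0.5),
      AMR = c(80, 14.5, 5.5),
      EAS = c(55, 35, 10),
      EUR = c(78, 20, 2),
      SAS = c(70, 25, 5)),
    g("SLCO1B1", c("Normal Function", "Decreased Function", "Poor Function",
                   "Indeterminate"),
      AFR = c(90, 8, 1, 1),
      AMR = c(72, 22, 2, 4),
      EAS = c(75, 21, 2, 2),
      EUR = c(70, 25, 3, 2),
      SAS = c(80, 16, 2, 2)),
    g("CYP4F2", c("Normal Function", "Decreased Function", "Indeterminate"),
      AFR = c(95, 3, 2),
      AMR = c(89, 8, 3),
      EAS = c(90, 8, 2),
      EUR = c(85, 12, 3),
      SAS = c(80, 17, 3)),
    g("DPYD", c("Normal Function", "Decreased Function", "Poor Function"),
      AFR = c(96, 3.5, 0.5),
      AMR = c(95.5, 4, 0.5),
      EAS = c(98, 1.8, 0.2),
      EUR = c(94, 5.5, 0.5),
      SAS = c(96, 3.7, 0.3)),
    g("TPMT", c("Normal Metabolizer", "Intermediate Metabolizer",
                "Poor Metabolizer"),
      AFR = c(92, 7.6, 0.4),
      AMR = c(91, 8.7, 0.3),
      EAS = c(95, 4.8, 0.2),
      EUR = c(90, 9.7, 0.3),
      SAS = c(95, 4.8, 0.2)),
    g("NUDT15", c("Normal Metabolizer", "Intermediate Metabolizer",
                  "Poor Metabolizer"),
      AFR = c(99, 1, 0),
      AMR = c(90, 9.5, 0.5),
      EAS = c(80, 19, 1),
      EUR = c(99.5, 0.5, 0),
      SAS = c(87, 12.5, 0.5)),
    g("NAT2", c("Normal Metabolizer", "Intermediate Metabolizer",
                "Poor Metabolizer", "Indeterminate"),
      AFR = c(20, 12, 8, 60),
      AMR = c(25, 10, 5, 60),
      EAS = c(35, 8, 2, 55),
      EUR = c(18, 15, 10, 57),
      SAS = c(22, 12, 8, 58)),
    g("G6PD", c("G6PD Normal", "G6PD variable or deficient",
                "G6PD deficient with CNSHA"),
      AFR = c(88, 11.5, 0.5),
      AMR = c(97, 2.8, 0.2),
      EAS = c(97.5, 2.3, 0.2),
      EUR = c(98.5, 1.4, 0.1),
      SAS = c(96, 3.8, 0.2)),
    g("BCHE", c("mild deficiency or normal activity (BCHE)",
                "moderate deficiency (BCHE)"),
      AFR = c(98.5, 1.5),
      AMR = c(97.5, 2.5),
      EAS = c(99, 1),
      EUR = c(96, 4),
      SAS = c(97, 3)),
    g("MT-RNR1", c("normal risk of aminoglycoside-induced hearing loss",
                   "uncertain risk of aminoglycoside-induced hearing loss",
                   "increased risk of aminoglycoside-induced hearing loss"),
      AFR = c(99.3, 0.4, 0.3),
      AMR = c(99.3, 0.4, 0.3),
      EAS = c(99.1, 0.4, 0.5),
      EUR = c(99.4, 0.4, 0.2),
      SAS = c(99.2, 0.4, 0.4)),
    g("RYR1", c("Uncertain Susceptibility",
                "Malignant Hyperthermia Susceptibility"),
      AFR = c(99.6, 0.4), AMR = c(99.6, 0.4), EAS = c(99.6, 0.4),
      EUR = c(99.5, 0.5), SAS = c(99.6, 0.4)),
    g("CACNA1S", c("Uncertain Susceptibility",
                   "Malignant Hyperthermia Susceptibility"),
      AFR = c(99.8, 0.2), AMR = c(99.8, 0.2), EAS = c(99.8, 0.2),
      EUR = c(99.8, 0.2), SAS = c(99.8, 0.2)),
    g("CFTR", c("Normal", "Favorable Response"),
      AFR = c(99.6, 0.4), AMR = c(99.6, 0.4), EAS = c(99.8, 0.2),
      EUR = c(99.2, 0.8), SAS = c(99.6, 0.4))
  )
}

#' Bundled reference phenotype frequency table (CYP2B6)
#'
#' A PharmGKB-style long reference table for CYP2B6 metabolizer
#' frequencies from two published sources (`PGKB`, a curated database
#' aggregate keyed by LAT for the Latino population, and `LIT`, a
#' literature analysis of 1000 Genomes data), for side-by-side comparison
#' against cohort tables. Blank cells in the originals are absent rows.
#'
#' @return tibble `gene`, `population`, `phenotype`, `source`, `pct`.
#' @export
reference_phenotype_freqs <- function() {
  path <- system.file("extdata", "reference_phenotype_freqs.tsv",
                      package = "pgxcohort")
  readr::read_tsv(path, col_types = "ccccd")
}
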