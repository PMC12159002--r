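#' Bundled illustrative star-allele catalog
#'
#' A compact, synthetic-but-realistic catalog covering the pharmacogenes
#' this package's workflow targets. Star-allele definitions, GRCh38
#' positions, function classes, CYP2D6 activity values and ancestry-specific
#' frequencies are illustrative: they follow the shape and magnitude of
#' public PharmVar/CPIC/PharmGKB resources closely enough to exercise every
#' pipeline stage, but are not a clinical reference. Users supply their own
#' catalog TSV for real cohorts.
#'
#' Notable structure deliberately included:
#' * `CYP2B6*6` is the union of the `*4` and `*9` defining variants, so an
#'   unphased `*4`/`*9` double heterozygote is ambiguous with `*1`/`*6` —
#'   the classic phasing ambiguity the frequency resolver must handle.
#' * `TPMT*3A` is likewise the union of `*3B` and `*3C`.
#' * `CYP2D6*5` is the whole-gene deletion (no defining variants; assigned
#'   only through copy-number input); duplications use the `x2` suffix.
#' * `CYP2C19*17` (promoter), `CYP3A5*3` (intron boundary, chr7:99672916),
#'   `UGT1A1*80`, the `VKORC1` promoter variant and three `IFNL3` variants
#'   sit outside typical exome capture designs; the default depth model
#'   places capture gaps there.
#'
#' @return A `pgx_catalog`.
#' @export
example_catalog <- function() {
  # helper: one allele row; freqs in AFR, AMR, EAS, EUR, SAS order
  A <- function(gene, allele, fun, act, f) {
    tibble::tibble(gene = gene, allele = allele, function_class = fun,
                   activity = act,
                   freq_AFR = f[1], freq_AMR = f[2], freq_EAS = f[3],
                   freq_EUR = f[4], freq_SAS = f[5])
  }
  V <- function(gene, allele, chrom, pos, ref, alt, rsid) {
    tibble::tibble(gene = gene, allele = allele, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, rsid = rsid)
  }

  alleles <- dplyr::bind_rows(
    A("CYP2B6", "*1", "normal",      NA, c(0.55, 0.70, 0.75, 0.68, 0.55)),
    A("CYP2B6", "*4", "increased",   NA, c(0.02, 0.03, 0.02, 0.04, 0.02)),
    A("CYP2B6", "*6", "decreased",   NA, c(0.38, 0.22, 0.18, 0.22, 0.38)),
    A("CYP2B6", "*9", "decreased",   NA, c(0.05, 0.05, 0.05, 0.06, 0.05)),

    A("CYP2D6", "*1",  "normal",      1.00, c(0.40, 0.55, 0.35, 0.50, 0.45)),
    A("CYP2D6", "*2",  "normal",      1.00, c(0.25, 0.25, 0.12, 0.27, 0.30)),
    A("CYP2D6", "*4",  "no_function", 0.00, c(0.08, 0.10, 0.005, 0.17, 0.10)),
    A("CYP2D6", "*5",  "no_function", 0.00, c(0.03, 0.02, 0.05, 0.03, 0.02)),
    A("CYP2D6", "*10", "decreased",   0.25, c(0.08, 0.05, 0.40, 0.02, 0.08)),

    A("CYP2C9", "*1", "normal",      NA, c(0.97, 0.86, 0.963, 0.805, 0.85)),
    A("CYP2C9", "*2", "decreased",   NA, c(0.02, 0.10, 0.001, 0.125, 0.05)),
    A("CYP2C9", "*3", "no_function", NA, c(0.01, 0.04, 0.035, 0.07, 0.10)),

    A("CYP2C19", "*1",  "normal",      NA, c(0.60, 0.75, 0.64, 0.70, 0.55)),
    A("CYP2C19", "*2",  "no_function", NA, c(0.17, 0.12, 0.30, 0.15, 0.30)),
    A("CYP2C19", "*17", "increased",   NA, c(0.22, 0.12, 0.02, 0.15, 0.14)),

    A("CYP3A5", "*1", "normal",      NA, c(0.70, 0.25, 0.29, 0.06, 0.33)),
    A("CYP3A5", "*3", "no_function", NA, c(0.30, 0.75, 0.71, 0.94, 0.67)),

    A("CYP4F2", "*1", "normal",    NA, c(0.91, 0.75, 0.78, 0.70, 0.58)),
    A("CYP4F2", "*3", "decreased", NA, c(0.09, 0.25, 0.22, 0.30, 0.42)),

    A("SLCO1B1", "*1", "normal",    NA, c(0.98, 0.87, 0.88, 0.84, 0.91)),
    A("SLCO1B1", "*5", "decreased", NA, c(0.02, 0.13, 0.12, 0.16, 0.09)),

    A("TPMT", "*1",  "normal",      NA, c(0.965, 0.949, 0.96, 0.9595, 0.97)),
    A("TPMT", "*3A", "no_function", NA, c(0.010, 0.030, 0.000, 0.030, 0.010)),
    A("TPMT", "*3B", "no_function", NA, c(0.005, 0.001, 0.000, 0.0005, 0.000)),
    A("TPMT", "*3C", "no_function", NA, c(0.020, 0.020, 0.020, 0.010, 0.020)),

    A("NUDT15", "*1", "normal",      NA, c(1.00, 0.95, 0.90, 0.998, 0.93)),
    A("NUDT15", "*3", "no_function", NA, c(0.00, 0.05, 0.10, 0.002, 0.07)),

    A("DPYD", "*1",  "normal",      NA, c(0.95, 0.97, 0.985, 0.96, 0.97)),
    A("DPYD", "*2A", "no_function", NA, c(0.001, 0.005, 0.000, 0.010, 0.005)),
    A("DPYD", "*9",  "normal",      NA, c(0.049, 0.025, 0.015, 0.030, 0.025)),

    A("UGT1A1", "*1",  "normal",    NA, c(0.56, 0.62, 0.84, 0.68, 0.60)),
    A("UGT1A1", "*80", "decreased", NA, c(0.44, 0.38, 0.16, 0.32, 0.40)),

    A("VKORC1", "*1", "normal",    NA, c(0.90, 0.55, 0.12, 0.61, 0.85)),
    A("VKORC1", "*2", "decreased", NA, c(0.10, 0.45, 0.88, 0.39, 0.15)),

    A("IFNL3", "*1", "normal",    NA, c(0.40, 0.55, 0.88, 0.65, 0.70)),
    A("IFNL3", "*2", "uncertain", NA, c(0.35, 0.25, 0.06, 0.20, 0.15)),
    A("IFNL3", "*3", "uncertain", NA, c(0.15, 0.12, 0.03, 0.10, 0.10)),
    A("IFNL3", "*4", "uncertain", NA, c(0.10, 0.08, 0.03, 0.05, 0.05)),

    A("ABCG2", "*1", "normal",    NA, c(0.99, 0.86, 0.71, 0.91, 0.91)),
    A("ABCG2", "*2", "decreased", NA, c(0.01, 0.14, 0.29, 0.09, 0.09)),

    A("NAT2", "*1", "normal",    NA, c(0.45, 0.45, 0.60, 0.30, 0.35)),
    A("NAT2", "*5", "decreased", NA, c(0.30, 0.35, 0.05, 0.45, 0.35)),
    A("NAT2", "*6", "decreased", NA, c(0.25, 0.20, 0.35, 0.25, 0.30)),

    A("G6PD", "*1",   "normal",      NA, c(0.87, 0.985, 0.995, 0.988, 0.975)),
    A("G6PD", "*A-",  "decreased",   NA, c(0.12, 0.005, 0.000, 0.002, 0.005)),
    A("G6PD", "*Med", "no_function", NA, c(0.01, 0.010, 0.005, 0.010, 0.020)),

    A("BCHE", "*1", "normal",    NA, c(0.985, 0.975, 0.995, 0.96, 0.97)),
    A("BCHE", "*A", "decreased", NA, c(0.005, 0.010, 0.000, 0.015, 0.010)),
    A("BCHE", "*K", "decreased", NA, c(0.010, 0.015, 0.005, 0.025, 0.020)),

    A("MT-RNR1", "*1",     "normal",    NA, c(0.997, 0.997, 0.995, 0.998, 0.996)),
    A("MT-RNR1", "*1555G", "increased", NA, c(0.003, 0.003, 0.005, 0.002, 0.004)),

    A("RYR1",    "*1",   "normal",    NA, c(0.998, 0.998, 0.998, 0.997, 0.998)),
    A("RYR1",    "*MH1", "increased", NA, c(0.002, 0.002, 0.002, 0.003, 0.002)),
    A("CACNA1S", "*1",   "normal",    NA, c(0.999, 0.999, 0.999, 0.999, 0.999)),
    A("CACNA1S", "*MH1", "increased", NA, c(0.001, 0.001, 0.001, 0.001, 0.001)),

    A("CFTR", "*1",     "normal",    NA, c(0.999, 0.998, 0.999, 0.995, 0.999)),
    A("CFTR", "*G551D", "increased", NA, c(0.001, 0.002, 0.001, 0.005, 0.001))
  )

  variants <- dplyr::bind_rows(
    V("CYP2B6", "*4", "chr19", 41512841, "A", "G", "rs2279343"),
    V("CYP2B6", "*9", "chr19", 41512541, "G", "T", "rs3745274"),
    V("CYP2B6", "*6", "chr19", 41512541, "G", "T", "rs3745274"),
    V("CYP2B6", "*6", "chr19", 41512841, "A", "G", "rs2279343"),

    V("CYP2D6", "*2",  "chr22", 42127941, "C", "T", "rs16947"),
    V("CYP2D6", "*4",  "chr22", 42128945, "C", "T", "rs3892097"),
    V("CYP2D6", "*10", "chr22", 42130692, "G", "A", "rs1065852"),

    V("CYP2C9", "*2", "chr10", 94942290, "C", "T", "rs1799853"),
    V("CYP2C9", "*3", "chr10", 94981296, "A", "C", "rs1057910"),

    V("CYP2C19", "*2",  "chr10", 94781859, "G", "A", "rs4244285"),
    V("CYP2C19", "*17", "chr10", 94761900, "C", "T", "rs12248560"),

    V("CYP3A5", "*3", "chr7", 99672916, "T", "C", "rs776746"),

    V("CYP4F2", "*3", "chr19", 15879621, "C", "T", "rs2108622"),

    V("SLCO1B1", "*5", "chr12", 21178615, "T", "C", "rs4149056"),

    V("TPMT", "*3A", "chr6", 18139228, "C", "T", "rs1800460"),
    V("TPMT", "*3A", "chr6", 18130918, "T", "C", "rs1142345"),
    V("TPMT", "*3B", "chr6", 18139228, "C", "T", "rs1800460"),
    V("TPMT", "*3C", "chr6", 18130918, "T", "C", "rs1142345"),

    V("NUDT15", "*3", "chr13", 48037782, "C", "T", "rs116855232"),

    V("DPYD", "*2A", "chr1", 97450058, "C", "T", "rs3918290"),
    V("DPYD", "*9",  "chr1", 97883329, "A", "G", "rs1801265"),

    V("UGT1A1", "*80", "chr2", 233759924, "C", "T", "rs887829"),

    V("VKORC1", "*2", "chr16", 31096368, "G", "A", "rs9923231"),

    V("IFNL3", "*2", "chr19", 39248147, "C", "T", "rs12979860"),
    V("IFNL3", "*3", "chr19", 39252525, "T", "G", "rs8099917"),
    V("IFNL3", "*4", "chr19", 39239220, "A", "G", "rs12980275"),

    V("ABCG2", "*2", "chr4", 88131171, "G", "T", "rs2231142"),

    V("NAT2", "*5", "chr8", 18400344, "T", "C", "rs1801280"),
    V("NAT2", "*6", "chr8", 18400806, "G", "A", "rs1799930"),

    V("G6PD", "*A-",  "chrX", 154536002, "C", "T", "rs1050829"),
    V("G6PD", "*Med", "chrX", 154532439, "C", "T", "rs5030868"),

    V("BCHE", "*A", "chr3", 165830741, "T", "G", "rs1799807"),
    V("BCHE", "*K", "chr3", 165773492, "C", "T", "rs1803274"),

    V("MT-RNR1", "*1555G", "chrM", 1555, "A", "G", "rs267606617"),

    V("RYR1",    "*MH1", "chr19", 38455420, "C", "T", "rs118192172"),
    V("CACNA1S", "*MH1", "chr1",  201091993, "C", "T", "rs772226819"),

    V("CFTR", "*G551D", "chr7", 117587806, "G", "A", "rs75527207")
  )

  pgx_catalog(alleles, variants)
}

#' Default capture-gap depth model positions
#'
#' Haplotype-defining positions the default exome depth model treats as
#' capture gaps, with their gap mean depths: the `CYP2C19*17` promoter SNP
#' (near zero), `CYP3A5*3` one base before an exon boundary (~15X),
#' `UGT1A1*80`, the `VKORC1` promoter variant and three `IFNL3` variants.
#' At a 20X gate these exclude exactly five genes.
#'
#' @return tibble with columns `gene`, `chrom`, `pos`, `gap_mean`.
#' @export
default_capture_gaps <- function() {
  tibble::tribble(
    ~gene,      ~chrom,  ~pos,      ~gap_mean,
    "CYP2C19",  "chr10", 94761900,  0.5,
    "CYP3A5",   "chr7",  99672916,  15,
    "UGT1A1",   "chr2",  233759924, 8,
    "VKORC1",   "chr16", 31096368,  10,
    "IFNL3",    "chr19", 39248147,  12,
    "IFNL3",    "chr19", 39252525,  18,
    "IFNL3",    "chr19", 39239220,  6
  )
}

#' Deletion allele name for a gene
#'
#' Whole-gene deletions are the literal `*5` for CYP2D6 and the generic
#' `*DEL` elsewhere.
#' @param gene gene symbol.
#' @export
deletion_allele_name <- function(gene) {
  if (gene == "CYP2D6") "*5" else "*DEL"
}

# alleles that never enter unphased candidate enumeration: whole-gene
# deletions (no defining variants; assigned only via copy-number input)
# and explicit xN duplication names
is_structural_allele <- function(gene, allele) {
  allele == deletion_allele_name(gene) | grepl("x2$", allele)
}
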