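# ---- diplotype -> phenotype translation ----

#' Closed phenotype vocabulary
#'
#' Every label a translation rule may emit; actionability scoring is total
#' over this set.
#' @export
phenotype_vocabulary <- function() c(
  "Normal Metabolizer", "Intermediate Metabolizer", "Poor Metabolizer",
  "Rapid Metabolizer", "Ultrarapid Metabolizer", "Ultra Rapid Metabolizer",
  "Possible Intermediate Metabolizer", "Indeterminate",
  "Normal Function", "Decreased Function", "Possible Decreased Function",
  "Poor Function", "Increased Function",
  "Uncertain Susceptibility", "Malignant Hyperthermia Susceptibility",
  "Normal Risk",
  "increased risk of aminoglycoside-induced hearing loss",
  "uncertain risk of aminoglycoside-induced hearing loss",
  "normal risk of aminoglycoside-induced hearing loss",
  "moderate deficiency (BCHE)", "mild deficiency or normal activity (BCHE)",
  "G6PD Normal", "G6PD variable or deficient", "G6PD deficient with CNSHA",
  "Favorable Response", "Normal", "NA"
)

#' Default function-pair lookup tables
#'
#' Editable tables mapping an unordered pair of allele function classes to
#' a phenotype label: one for metabolizer-class genes and one for
#' function-class (transporter-style) genes. Pairs are keyed with function
#' classes in sorted order. Pairs involving `uncertain`/`unknown` are
#' handled upstream (always Indeterminate) and do not appear here.
#'
#' @param kind `"metabolizer"` or `"function"`.
#' @return tibble `fun_a`, `fun_b`, `label`.
#' @export
function_pair_table <- function(kind = c("metabolizer", "function")) {
  kind <- match.arg(kind)
  if (kind == "metabolizer") {
    tibble::tribble(
      ~fun_a,        ~fun_b,        ~label,
      "normal",      "normal",      "Normal Metabolizer",
      "normal",      "decreased",   "Intermediate Metabolizer",
      "normal",      "no_function", "Intermediate Metabolizer",
      "decreased",   "decreased",   "Intermediate Metabolizer",
      "decreased",   "no_function", "Poor Metabolizer",
      "no_function", "no_function", "Poor Metabolizer",
      "increased",   "normal",      "Rapid Metabolizer",
      "increased",   "increased",   "Ultrarapid Metabolizer",
      "increased",   "decreased",   "Intermediate Metabolizer",
      "increased",   "no_function", "Intermediate Metabolizer"
    )
  } else {
    tibble::tribble(
      ~fun_a,        ~fun_b,        ~label,
      "normal",      "normal",      "Normal Function",
      "normal",      "decreased",   "Decreased Function",
      "normal",      "no_function", "Decreased Function",
      "decreased",   "decreased",   "Poor Function",
      "decreased",   "no_function", "Poor Function",
      "no_function", "no_function", "Poor Function",
      "increased",   "normal",      "Increased Function",
      "increased",   "increased",   "Increased Function",
      "increased",   "decreased",   "Normal Function",
      "increased",   "no_function", "Decreased Function"
    )
  }
}

#' Default per-gene translation rules
#'
#' One rule per gene in scope. Rule kinds: `function_pair_metabolizer`,
#' `function_pair_function`, `activity_score` (CYP2D6), `carrier_risk`
#' (risk-allele screening genes), `g6pd_class` and `bche_class`. Activity
#' score thresholds follow the consensus convention (0 poor, (0, 1]
#' intermediate, (1, 2.25] normal, > 2.25 ultrarapid) and are
#' configuration, not hard-coded.
#'
#' @return tibble `gene`, `rule_kind`, `risk_label`, `else_label`.
#' @export
default_gene_rules <- function() {
  tibble::tribble(
    ~gene,      ~rule_kind,                  ~risk_label,                ~else_label,
    "CYP2B6",   "function_pair_metabolizer", NA,                         NA,
    "CYP2C9",   "function_pair_metabolizer", NA,                         NA,
    "CYP2C19",  "function_pair_metabolizer", NA,                         NA,
    "CYP3A5",   "function_pair_metabolizer", NA,                         NA,
    "NAT2",     "function_pair_metabolizer", NA,                         NA,
    "TPMT",     "function_pair_metabolizer", NA,                         NA,
    "NUDT15",   "function_pair_metabolizer", NA,                         NA,
    "IFNL3",    "function_pair_metabolizer", NA,                         NA,
    "CYP2D6",   "activity_score",            NA,                         NA,
    "SLCO1B1",  "function_pair_function",    NA,                         NA,
    "DPYD",     "function_pair_function",    NA,                         NA,
    "CYP4F2",   "function_pair_function",    NA,                         NA,
    "ABCG2",    "function_pair_function",    NA,                         NA,
    "UGT1A1",   "function_pair_function",    NA,                         NA,
    "VKORC1",   "function_pair_function",    NA,                         NA,
    "RYR1",     "carrier_risk", "Malignant Hyperthermia Susceptibility", "Uncertain Susceptibility",
    "CACNA1S",  "carrier_risk", "Malignant Hyperthermia Susceptibility", "Uncertain Susceptibility",
    "MT-RNR1",  "carrier_risk", "increased risk of aminoglycoside-induced hearing loss",
                                "normal risk of aminoglycoside-induced hearing loss",
    "CFTR",     "carrier_risk", "Favorable Response",                    "Normal",
    "G6PD",     "g6pd_class",                NA,                         NA,
    "BCHE",     "bche_class",                NA,                         NA
  )
}

#' Activity-score thresholds for metabolizer binning
#'
#' @return named numeric vector of upper bounds: scores of 0 are Poor,
#'   (0, im] Intermediate, (im, nm] Normal, above nm Ultrarapid.
#' @export
activity_score_thresholds <- function() c(im = 1, nm = 2.25)

# function class of one allele name (x2 duplication inherits the base
# allele's class; whole-gene deletion is no_function)
allele_function <- function(catalog, gene, allele) {
  if (allele == deletion_allele_name(gene)) {
    al <- catalog$alleles
    f <- al$function_class[al$gene == gene & al$allele == allele]
    if (length(f) == 1) return(f)
    return("no_function")
  }
  base <- sub("x2$", "", allele)
  al <- catalog$alleles
  f <- al$function_class[al$gene == gene & al$allele == base]
  if (length(f) == 0) NA_character_ else f
}

# activity value contributed by one allele name; x2 doubles the base value
allele_activity <- function(catalog, gene, allele) {
  if (allele == deletion_allele_name(gene)) return(0)
  dup <- grepl("x2$", allele)
  base <- sub("x2$", "", allele)
  al <- catalog$alleles
  a <- al$activity[al$gene == gene & al$allele == base]
  if (length(a) == 0 || is.na(a)) return(NA_real_)
  if (dup) 2 * a else a
}

lookup_pair <- function(tbl, fa, fb) {
  fs <- sort(c(fa, fb))
  hit <- tbl$label[(tbl$fun_a == fs[1] & tbl$fun_b == fs[2]) |
                   (tbl$fun_a == fs[2] & tbl$fun_b == fs[1])]
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Translate one diplotype to a phenotype label
#'
#' Applies the gene's rule: function-pair lookup for metabolizer- and
#' function-class genes, summed activity score for CYP2D6 (deletion
#' contributes 0, a duplication twice the base value), risk-allele carrier
#' logic for RYR1/CACNA1S/MT-RNR1/CFTR, and WHO-class/activity lookups for
#' G6PD and BCHE. Any allele of uncertain or unknown function yields
#' `Indeterminate`; a missing selected diplotype yields `NA`.
#'
#' @param gene gene symbol.
#' @param diplotype diplotype string (e.g. `"*1/*6"`) or `NA`.
#' @param catalog a `pgx_catalog`.
#' @param rules rule table (default [default_gene_rules()]).
#' @param pair_tables list with `metabolizer` and `function` lookup tables.
#' @param as_thresholds activity-score bin bounds.
#' @return list with `label` and `activity_score` (NA unless the gene uses
#'   activity scoring).
#' @export
translate_diplotype <- function(gene, diplotype, catalog,
                                rules = default_gene_rules(),
                                pair_tables = list(
                                  metabolizer = function_pair_table("metabolizer"),
                                  `function` = function_pair_table("function")),
                                as_thresholds = activity_score_thresholds()) {
  rule <- rules[rules$gene == gene, ]
  if (nrow(rule) == 0) stop("no translation rule for gene ", gene)
  if (is.na(diplotype)) return(list(label = "NA", activity_score = NA_real_))
  pair <- parse_diplotype(diplotype)
  funs <- vapply(pair, function(a) allele_function(catalog, gene, a), "")
  if (any(is.na(funs))) {
    stop("allele(s) not in catalog for ", gene, ": ",
         paste(pair[is.na(funs)], collapse = ", "))
  }
  kind <- rule$rule_kind

  if (kind == "activity_score") {
    acts <- vapply(pair, function(a) allele_activity(catalog, gene, a),
                   numeric(1))
    if (any(funs %in% c("uncertain", "unknown")) || any(is.na(acts))) {
      return(list(label = "Indeterminate", activity_score = NA_real_))
    }
    s <- sum(acts)
    label <- if (s == 0) "Poor Metabolizer"
      else if (s <= as_thresholds[["im"]]) "Intermediate Metabolizer"
      else if (s <= as_thresholds[["nm"]]) "Normal Metabolizer"
      else "Ultrarapid Metabolizer"
    return(list(label = label, activity_score = s))
  }

  if (any(funs %in% c("uncertain", "unknown"))) {
    return(list(label = "Indeterminate", activity_score = NA_real_))
  }

  if (kind == "function_pair_metabolizer") {
    lab <- lookup_pair(pair_tables$metabolizer, funs[1], funs[2])
    if (is.na(lab)) lab <- "Indeterminate"
    return(list(label = lab, activity_score = NA_real_))
  }
  if (kind == "function_pair_function") {
    lab <- lookup_pair(pair_tables$`function`, funs[1], funs[2])
    if (is.na(lab)) lab <- "Indeterminate"
    return(list(label = lab, activity_score = NA_real_))
  }
  if (kind == "carrier_risk") {
    carrier <- any(funs %in% c("increased", "no_function") &
                     pair != "*1")
    lab <- if (carrier) rule$risk_label else rule$else_label
    return(list(label = lab, activity_score = NA_real_))
  }
  if (kind == "g6pd_class") {
    return(list(label = translate_g6pd(funs), activity_score = NA_real_))
  }
  if (kind == "bche_class") {
    return(list(label = translate_bche(funs), activity_score = NA_real_))
  }
  stop("unknown rule kind: ", kind)
}

#' G6PD phenotype from the function classes of the two reported alleles
#'
#' `no_function` alleles stand for WHO class I (chronic non-spherocytic
#' hemolytic anemia when not balanced by a normal allele), `decreased` for
#' the class II/III deficient range. Without chrX copy information the
#' reported genotype is taken at face value (hemizygotes arrive as
#' homozygous-looking calls).
#'
#' @param funs character vector of two function classes.
#' @return phenotype label.
#' @export
translate_g6pd <- function(funs) {
  deficient <- funs %in% c("decreased", "no_function")
  if (!any(deficient)) return("G6PD Normal")
  if (all(funs == "no_function")) return("G6PD deficient with CNSHA")
  "G6PD variable or deficient"
}

#' BCHE phenotype from the function classes of the two reported alleles
#'
#' Two reduced-activity alleles give moderate deficiency; anything else is
#' mild deficiency or normal activity.
#'
#' @param funs character vector of two function classes.
#' @return phenotype label.
#' @export
translate_bche <- function(funs) {
  reduced <- funs %in% c("decreased", "no_function")
  if (all(reduced)) "moderate deficiency (BCHE)"
  else "mild deficiency or normal activity (BCHE)"
}

#' MT-RNR1 phenotype from risk-variant presence
#'
#' @param risk_variant_present logical.
#' @return phenotype label.
#' @export
translate_mtrnr1 <- function(risk_variant_present) {
  if (isTRUE(risk_variant_present)) {
    "increased risk of aminoglycoside-induced hearing loss"
  } else {
    "normal risk of aminoglycoside-induced hearing loss"
  }
}

#' Translate a table of diplotype calls to phenotypes
#'
#' @param calls output of [call_cohort()] (uses `selected`).
#' @param catalog a `pgx_catalog`.
#' @param rules rule table (default [default_gene_rules()]).
#' @return tibble `sample_id`, `gene`, `phenotype`, `activity_score`.
#' @export
translate_calls <- function(calls, catalog, rules = default_gene_rules()) {
  pt <- list(metabolizer = function_pair_table("metabolizer"),
             `function` = function_pair_table("function"))
  res <- mapply(function(g, d) {
    translate_diplotype(g, d, catalog, rules, pair_tables = pt)
  }, calls$gene, calls$selected, SIMPLIFY = FALSE)
  tibble::tibble(
    sample_id = calls$sample_id,
    gene = calls$gene,
    phenotype = vapply(res, `[[`, "", "label"),
    activity_score = vapply(res, `[[`, numeric(1), "activity_score")
  )
}
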