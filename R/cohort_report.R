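# ---- ancestry-stratified frequency tables and reference comparison ----

#' Ancestry-stratified phenotype frequency tables
#'
#' Per gene and ancestry stratum, the percentage of each phenotype label
#' (Indeterminate and no-call retained in the denominator). Percentages
#' are reported both unrounded and at the one-decimal presentation
#' precision.
#'
#' @param phenotypes tibble `sample_id`, `gene`, `phenotype`.
#' @param ancestry tibble `sample_id`, `ancestry`.
#' @return tibble `gene`, `ancestry`, `phenotype`, `n` (label count),
#'   `n_stratum`, `pct` (unrounded), `pct_rounded`.
#' @export
phenotype_frequencies <- function(phenotypes, ancestry) {
  ph <- dplyr::inner_join(tibble::as_tibble(phenotypes),
                          tibble::as_tibble(ancestry), by = "sample_id")
  if (nrow(ph) < nrow(phenotypes)) {
    stop("sample(s) missing an ancestry label")
  }
  ph |>
    dplyr::count(.data$gene, .data$ancestry, .data$phenotype, name = "n") |>
    dplyr::group_by(.data$gene, .data$ancestry) |>
    dplyr::mutate(n_stratum = sum(.data$n),
                  pct = 100 * .data$n / .data$n_stratum,
                  pct_rounded = round(.data$pct, 1)) |>
    dplyr::ungroup()
}

#' Compare cohort phenotype frequencies against reference tables
#'
#' Produces a wide gene x label x population table with one column per
#' source and the cohort-minus-reference differences. No statistical
#' testing is performed — only effect-size columns. Population codes are
#' reconciled through an alias map (a cohort AMR stratum is compared to a
#' reference LAT column, the usual biogeographical mismatch).
#'
#' @param cohort output of [phenotype_frequencies()] (uses `pct_rounded`).
#' @param reference long tibble `gene`, `population`, `phenotype`, `source`,
#'   `pct`; missing cells permitted.
#' @param population_alias named character vector mapping cohort ancestry
#'   codes to reference population codes (default `c(AMR = "LAT")`).
#' @return tibble `gene`, `ancestry`, `phenotype`, `cohort_pct`, one
#'   `<source>_pct` column per reference source and matching `diff_<source>`
#'   columns (cohort minus reference; NA where the reference is blank).
#' @export
compare_to_reference <- function(cohort, reference,
                                 population_alias = c(AMR = "LAT")) {
  ref <- tibble::as_tibble(reference)
  coh <- cohort |>
    dplyr::select("gene", "ancestry", "phenotype",
                  cohort_pct = "pct_rounded")
  coh$ref_population <- ifelse(coh$ancestry %in% names(population_alias),
                               population_alias[coh$ancestry], coh$ancestry)
  # also allow references keyed directly by the cohort code
  out <- coh
  for (src in unique(ref$source)) {
    sub <- ref[ref$source == src, c("gene", "population", "phenotype", "pct")]
    hit1 <- dplyr::left_join(
      out[, c("gene", "ref_population", "phenotype")],
      sub, by = c(gene = "gene", ref_population = "population",
                  phenotype = "phenotype"))
    hit2 <- dplyr::left_join(
      out[, c("gene", "ancestry", "phenotype")],
      sub, by = c(gene = "gene", ancestry = "population",
                  phenotype = "phenotype"))
    pct <- dplyr::coalesce(hit1$pct, hit2$pct)
    out[[paste0(src, "_pct")]] <- pct
    out[[paste0("diff_", src)]] <- out$cohort_pct - pct
  }
  out$ref_population <- NULL
  out
}

#' HLA risk-allele carrier prevalence
#'
#' @param hla tibble `sample_id`, `locus`, `allele1`, `allele2`.
#' @param rules HLA rule table (default [hla_rules()]).
#' @return list: `per_allele` tibble (`allele`, `n_carriers`, `pct`) over
#'   the actionable alleles and `fraction_any` — the fraction of samples
#'   carrying at least one actionable allele.
#' @export
hla_prevalence <- function(hla, rules = hla_rules()) {
  samples <- unique(hla$sample_id)
  if (length(samples) == 0) stop("no HLA calls supplied")
  risk <- unique(rules$allele)
  carried <- lapply(samples, function(s) {
    al <- c(hla$allele1[hla$sample_id == s], hla$allele2[hla$sample_id == s])
    intersect(hla_two_field(al[!is.na(al)]), risk)
  })
  per_allele <- tibble::tibble(
    allele = risk,
    n_carriers = vapply(risk, function(a) {
      sum(vapply(carried, function(x) a %in% x, logical(1)))
    }, integer(1), USE.NAMES = FALSE)
  )
  per_allele$pct <- 100 * per_allele$n_carriers / length(samples)
  list(
    per_allele = per_allele,
    fraction_any = mean(vapply(carried, length, 1L) > 0)
  )
}

#' Expected fraction of prescriptions impacted per drug
#'
#' For each drug, the probability that a random patient carries at least
#' one of its governing HLA risk alleles, assuming carrier independence
#' across loci (inclusion-exclusion: `1 - prod(1 - f_allele)`).
#'
#' @param carrier_fractions named numeric vector of per-allele carrier
#'   fractions in `[0, 1]` (names are two-field HLA alleles).
#' @param rules HLA rule table.
#' @param drugs optional drug subset; drugs with no governing rule are
#'   skipped with a note.
#' @return tibble `drug`, `expected_impacted_fraction`.
#' @export
expected_medication_impact <- function(carrier_fractions, rules = hla_rules(),
                                       drugs = NULL) {
  if (is.null(drugs)) drugs <- unique(rules$drug)
  known <- drugs %in% rules$drug
  if (any(!known)) {
    message("drug(s) with no governing HLA rule skipped: ",
            paste(drugs[!known], collapse = ", "))
    drugs <- drugs[known]
  }
  frac <- vapply(drugs, function(d) {
    al <- rules$allele[rules$drug == d]
    f <- carrier_fractions[al]
    f[is.na(f)] <- 0
    1 - prod(1 - f)
  }, numeric(1))
  tibble::tibble(drug = drugs, expected_impacted_fraction = unname(frac))
}
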