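# ---- concordance of diplotype calls against consensus truth ----

#' Default gene set for concordance comparison
#' @export
concordance_genes <- function() c(
  "CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A5", "CYP4F2", "DPYD",
  "SLCO1B1"
)

# canonical form of a diplotype string; NA passes through
canon_diplotype <- function(x) {
  vapply(x, function(d) {
    if (is.na(d)) return(NA_character_)
    p <- parse_diplotype(d)
    paste(p, collapse = "/")
  }, "", USE.NAMES = FALSE)
}

#' Categorize one discordant call
#'
#' `cnv_misassignment` when the pair differs from truth only in
#' duplication/deletion status (the typical exome failure for structural
#' alleles), `phase_ambiguity` when the truth was among the candidates but
#' a different pair was selected, `no_call` when no candidates were
#' produced, `allele_miss` otherwise.
#'
#' @param selected selected diplotype string or `NA`.
#' @param candidates semicolon-joined candidate string or `NA`.
#' @param truth consensus diplotype string.
#' @param gene gene symbol (for deletion-allele naming).
#' @return category string.
#' @export
categorize_discordance <- function(selected, candidates, truth, gene) {
  cands <- if (is.na(candidates)) character(0)
           else strsplit(candidates, ";", fixed = TRUE)[[1]]
  if (is.na(selected) && length(cands) == 0) return("no_call")
  truth_c <- canon_diplotype(truth)
  if (!is.na(selected)) {
    strip <- function(d) {
      p <- parse_diplotype(d)
      p <- sub("x2$", "", p)
      del <- deletion_allele_name(gene)
      # collapse duplication/deletion structure: compare the distinct
      # non-deleted base alleles only
      paste(sort(unique(p[p != del])), collapse = "/")
    }
    if (strip(selected) == strip(truth) &&
        canon_diplotype(selected) != truth_c) {
      return("cnv_misassignment")
    }
  }
  if (truth_c %in% canon_diplotype(cands)) return("phase_ambiguity")
  "allele_miss"
}

#' Compare diplotype calls to consensus truth
#'
#' Computes accuracy per caller in two modes: `strict` (the selected pair
#' must equal the consensus, unordered; a multi-candidate call with no
#' selection is incorrect) and `any_match` (a call is correct when the
#' consensus appears among its candidates). Both are reported, with the
#' denominator, since published accuracy figures rarely state how
#' multi-candidate output was counted. Truth cells with no corresponding
#' call count as incorrect no-calls.
#'
#' @param calls tibble `sample_id`, `gene`, `candidates`, `selected`.
#' @param truth tibble `sample_id`, `gene`, `diplotype`.
#' @param genes genes to compare (default [concordance_genes()] restricted
#'   to genes present in `truth`).
#' @return list: `n_cells`, `strict_accuracy`, `any_match_accuracy`,
#'   `per_gene` tibble, `discordances` tibble with categories.
#' @export
compare_calls <- function(calls, truth, genes = NULL) {
  truth <- tibble::as_tibble(truth)
  if (is.null(genes)) genes <- intersect(concordance_genes(),
                                         unique(truth$gene))
  truth <- truth[truth$gene %in% genes, ]
  if (anyDuplicated(truth[, c("sample_id", "gene")]) > 0) {
    stop("truth table has duplicate sample x gene records")
  }
  key <- paste(calls$sample_id, calls$gene)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    s <- truth$sample_id[i]; g <- truth$gene[i]
    tr <- canon_diplotype(truth$diplotype[i])
    hit <- match(paste(s, g), key)
    if (is.na(hit)) {
      return(tibble::tibble(sample_id = s, gene = g, truth = tr,
                            selected = NA_character_,
                            candidates = NA_character_,
                            strict = FALSE, any_match = FALSE,
                            category = "no_call"))
    }
    sel <- calls$selected[hit]
    cand <- calls$candidates[hit]
    sel_c <- if (is.na(sel)) NA_character_ else
      tryCatch(canon_diplotype(sel), error = function(e) "unparseable")
    cands <- if (is.na(cand)) character(0)
             else strsplit(cand, ";", fixed = TRUE)[[1]]
    cands_c <- tryCatch(canon_diplotype(cands), error = function(e) character(0))
    strict <- !is.na(sel_c) && sel_c == tr
    anym <- strict || tr %in% cands_c ||
      (!is.na(sel_c) && sel_c == tr)
    cat <- if (strict) NA_character_
           else categorize_discordance(sel, cand, truth$diplotype[i], g)
    tibble::tibble(sample_id = s, gene = g, truth = tr, selected = sel,
                   candidates = cand, strict = strict, any_match = anym,
                   category = cat)
  })
  cells <- dplyr::bind_rows(rows)
  per_gene <- cells |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n = dplyr::n(),
                     strict_accuracy = mean(.data$strict),
                     any_match_accuracy = mean(.data$any_match),
                     .groups = "drop")
  list(
    n_cells = nrow(cells),
    strict_accuracy = mean(cells$strict),
    any_match_accuracy = mean(cells$any_match),
    per_gene = per_gene,
    discordances = cells[!cells$strict, ]
  )
}
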