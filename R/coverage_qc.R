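#' Summarize sequencing depth at haplotype-defining positions
#'
#' Computes, per position, the arithmetic mean and sample standard
#' deviation of read depth across samples — the cohort-level view used to
#' decide whether an exome capture design supports diplotyping a gene.
#'
#' @param records depth table with columns `sample_id`, `chrom`, `pos`,
#'   `depth` (non-negative integer reads). Negative depths are rejected
#'   with a diagnostic.
#' @param positions tibble of positions (`chrom`, `pos`, optionally `gene`)
#'   to summarize; positions with no records are reported with
#'   `n_samples = 0` and `flagged = TRUE`.
#' @return tibble: `chrom`, `pos`, `mean_depth`, `sd_depth`, `n_samples`,
#'   `flagged` (plus `gene` when supplied).
#' @export
summarize_depth <- function(records, positions) {
  records <- tibble::as_tibble(records)
  if (any(records$depth < 0)) {
    bad <- which(records$depth < 0)
    stop("negative depth in records at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  pos_keys <- paste(positions$chrom, positions$pos)
  records <- records[paste(records$chrom, records$pos) %in% pos_keys, ]
  summ <- records |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      mean_depth = mean(.data$depth),
      sd_depth = if (dplyr::n() > 1) stats::sd(.data$depth) else 0,
      n_samples = dplyr::n(),
      .groups = "drop"
    )
  out <- dplyr::left_join(tibble::as_tibble(positions), summ,
                          by = c("chrom", "pos"))
  out$n_samples[is.na(out$n_samples)] <- 0L
  out$flagged <- out$n_samples == 0L
  out
}

#' Gene-exclusion rule for inadequately covered pharmacogenes
#'
#' A gene is excluded when ANY of its core haplotype-defining positions has
#' a cohort mean depth below `min_mean` reads (reason `low_mean`) or a
#' coefficient of variation (sd/mean) above `max_cv` (reason
#' `high_variability`). Exome capture gaps at promoter or intron-boundary
#' variants are the typical trigger.
#'
#' @param summaries output of [summarize_depth()] carrying a `gene` column,
#'   or a separate `gene_positions` mapping.
#' @param gene_positions optional tibble `gene`, `chrom`, `pos` mapping
#'   core positions to genes (unneeded if `summaries` has `gene`).
#' @param min_mean minimum acceptable mean depth (default 20 reads, the
#'   usual diagnostic threshold).
#' @param max_cv maximum acceptable sd/mean ratio (default 1.0).
#' @return tibble `gene`, `status` (`pass`/`excluded`) plus a
#'   `failing_positions` list-column of (chrom, pos, mean_depth, reason).
#' @export
apply_exclusion_rule <- function(summaries, gene_positions = NULL,
                                 min_mean = 20, max_cv = 1.0) {
  if (!"gene" %in% names(summaries)) {
    if (is.null(gene_positions)) {
      stop("summaries lack a gene column and no gene_positions mapping given")
    }
    summaries <- dplyr::inner_join(summaries,
                                   gene_positions[, c("gene", "chrom", "pos")],
                                   by = c("chrom", "pos"))
  }
  genes <- unique(summaries$gene)
  out <- lapply(genes, function(g) {
    sub <- summaries[summaries$gene == g, ]
    if (nrow(sub) == 0) {
      warning("gene ", g, " has no core positions; passing by default")
      return(tibble::tibble(gene = g, status = "pass",
                            failing_positions = list(tibble::tibble())))
    }
    cv <- ifelse(sub$mean_depth > 0, sub$sd_depth / sub$mean_depth, Inf)
    low <- sub$mean_depth < min_mean | sub$n_samples == 0
    varh <- !low & cv > max_cv
    fails <- tibble::tibble(
      chrom = sub$chrom[low | varh], pos = sub$pos[low | varh],
      mean_depth = sub$mean_depth[low | varh],
      reason = ifelse(low[low | varh], "low_mean", "high_variability")
    )
    tibble::tibble(gene = g,
                   status = if (nrow(fails) > 0) "excluded" else "pass",
                   failing_positions = list(fails))
  })
  dplyr::bind_rows(out)
}

#' Fraction of positions covered at a diagnostic depth threshold
#'
#' @param summaries output of [summarize_depth()].
#' @param threshold mean-depth threshold in reads (default 20).
#' @return fraction in `[0, 1]` of positions with `mean_depth >= threshold`.
#' @export
coverage_fraction <- function(summaries, threshold = 20) {
  if (nrow(summaries) == 0) stop("no coverage summaries supplied")
  md <- summaries$mean_depth
  md[is.na(md)] <- 0
  mean(md >= threshold)
}

#' Per-sample coverage flags at haplotype-defining positions
#'
#' Marks, for each sample and position, whether depth reaches the
#' per-sample threshold; used to downgrade diplotype calls to
#' `low_confidence` rather than silently treating uncovered positions as
#' reference. Does not affect gene exclusion (a cohort-level decision).
#'
#' @param records depth table (`sample_id`, `chrom`, `pos`, `depth`).
#' @param threshold per-sample depth threshold (default 20 reads).
#' @return tibble `sample_id`, `chrom`, `pos`, `covered` (logical).
#' @export
per_sample_coverage <- function(records, threshold = 20) {
  tibble::tibble(sample_id = records$sample_id, chrom = records$chrom,
                 pos = records$pos, covered = records$depth >= threshold)
}
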