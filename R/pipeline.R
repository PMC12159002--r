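# ---- end-to-end pipeline orchestration ----

#' Run the full pharmacogenomic extraction pipeline
#'
#' Orchestrates coverage QC at haplotype-defining positions, gene-scope
#' pruning, diplotype calling, phenotype translation, actionability
#' scoring and cohort reporting, writing per-stage TSV/JSON outputs plus a
#' run manifest (package version, seed, thresholds, excluded genes).
#' Identical inputs and configuration produce identical outputs.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `vcf`, `depth`, `ancestry`, `catalog` (path or `pgx_catalog`; default
#'   the bundled example catalog), optional `cn`, `hla`, `reference`
#'   paths; `out_dir`; `min_mean` (default 20), `max_cv` (default 1),
#'   `mode` (`single_call`/`multi_report`), `seed`.
#' @return invisible list with every stage's tables plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(min_mean = 20, max_cv = 1.0, mode = "single_call",
                         seed = 1L, depth_threshold = 20), config)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  catalog <- cfg$catalog
  if (is.null(catalog)) catalog <- example_catalog()
  if (is.character(catalog)) catalog <- load_catalog(catalog)
  out_dir <- cfg$out_dir %||% tempfile("pgx_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  depth <- stage("read-depth", readr::read_tsv(cfg$depth, col_types = "ccdd") |>
                   dplyr::mutate(pos = as.numeric(.data$pos)))
  ancestry <- stage("read-ancestry", readr::read_tsv(cfg$ancestry,
                                                     col_types = "cc"))
  cn <- if (!is.null(cfg$cn) && file.exists(cfg$cn)) {
    readr::read_tsv(cfg$cn, col_types = "ccic")
  } else NULL
  hla <- if (!is.null(cfg$hla) && file.exists(cfg$hla)) {
    readr::read_tsv(cfg$hla, col_types = "cccc")
  } else NULL

  genes <- unique(catalog$variants$gene)
  core <- dplyr::bind_rows(lapply(genes, function(g) {
    haplotype_defining_positions(catalog, g)
  }))
  summaries <- stage("coverage-qc", summarize_depth(depth, core))
  verdicts <- apply_exclusion_rule(summaries, min_mean = cfg$min_mean,
                                   max_cv = cfg$max_cv)
  excluded <- verdicts$gene[verdicts$status == "excluded"]
  kept_genes <- setdiff(genes, excluded)
  if (length(kept_genes) == 0) {
    warning("all genes excluded by coverage QC; downstream stages empty")
  }

  calls <- stage("diplotype-calling",
                 call_cohort(cfg$vcf, catalog, ancestry, genes = kept_genes,
                             cn = cn, depth = depth, mode = cfg$mode,
                             depth_threshold = cfg$depth_threshold))
  phenotypes <- stage("phenotype-translation",
                      translate_calls(calls, catalog))
  scope <- setdiff(actionability_scope(), excluded)
  profiles <- stage("actionability",
                    actionability_profiles(phenotypes, hla = hla,
                                           scope = scope))
  summary <- if (nrow(profiles) > 0) cohort_actionability(profiles) else {
    warning("empty actionability section (no in-scope genes)")
    list(n = 0, fraction_ge1 = NA, fraction_ge3 = NA,
         totals = tibble::tibble(), gene_counts = tibble::tibble())
  }
  freqs <- stage("cohort-report", phenotype_frequencies(phenotypes, ancestry))
  hla_prev <- if (!is.null(hla)) hla_prevalence(hla) else NULL
  comparison <- if (!is.null(cfg$reference)) {
    ref <- readr::read_tsv(cfg$reference, col_types = "ccccd")
    compare_to_reference(freqs, ref)
  } else NULL

  manifest <- list(
    package = "pgxcohort",
    version = as.character(utils::packageVersion("pgxcohort")),
    seed = cfg$seed,
    mode = cfg$mode,
    thresholds = list(min_mean = cfg$min_mean, max_cv = cfg$max_cv,
                      depth_threshold = cfg$depth_threshold),
    excluded_genes = as.list(excluded),
    actionability_scope = as.list(scope),
    n_samples = length(unique(ancestry$sample_id))
  )

  readr::write_tsv(summaries, file.path(out_dir, "coverage_summary.tsv"))
  readr::write_tsv(verdicts[, c("gene", "status")],
                   file.path(out_dir, "coverage_verdicts.tsv"))
  readr::write_tsv(calls, file.path(out_dir, "diplotype_calls.tsv"), na = "")
  readr::write_tsv(phenotypes, file.path(out_dir, "phenotypes.tsv"), na = "")
  readr::write_tsv(profiles, file.path(out_dir, "actionability_profiles.tsv"))
  readr::write_tsv(freqs, file.path(out_dir, "phenotype_frequencies.tsv"))
  if (!is.null(comparison)) {
    readr::write_tsv(comparison, file.path(out_dir, "reference_comparison.tsv"),
                     na = "")
  }
  report <- list(
    manifest = manifest,
    actionability = list(
      fraction_ge1 = summary$fraction_ge1,
      fraction_ge3 = summary$fraction_ge3,
      gene_counts = summary$gene_counts
    ),
    hla = if (!is.null(hla_prev)) list(
      fraction_any = hla_prev$fraction_any,
      per_allele = hla_prev$per_allele
    ) else NULL,
    samples = convert_calls_to_records(calls, phenotypes, profiles)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summaries = summaries, verdicts = verdicts,
                 excluded = excluded, calls = calls, phenotypes = phenotypes,
                 profiles = profiles, actionability = summary, freqs = freqs,
                 hla_prevalence = hla_prev, comparison = comparison,
                 manifest = manifest, out_dir = out_dir))
}

# nested per-sample records for the JSON report
convert_calls_to_records <- function(calls, phenotypes, profiles) {
  merged <- calls |>
    dplyr::left_join(phenotypes, by = c("sample_id", "gene")) |>
    dplyr::left_join(profiles, by = c("sample_id", "gene"))
  split_rows <- split(merged, merged$sample_id)
  lapply(split_rows, function(df) {
    list(sample_id = df$sample_id[1],
         genes = lapply(seq_len(nrow(df)), function(i) {
           list(gene = df$gene[i], candidates = df$candidates[i],
                selected = df$selected[i], resolution = df$resolution[i],
                phenotype = df$phenotype[i],
                actionability = df$score[i])
         }))
  })
}

#' Flatten a JSON pipeline report to a table
#'
#' One row per sample x gene with genotype, phenotype and actionability
#' columns; multi-candidate calls stay semicolon-joined in one cell. An
#' empty report yields a header-only table.
#'
#' @param path path to a `report.json` written by [run_pipeline()].
#' @return tibble `sample_id`, `gene`, `candidates`, `selected`,
#'   `resolution`, `phenotype`, `actionability`.
#' @export
convert_report <- function(path) {
  rep <- jsonlite::read_json(path)
  if (is.null(rep$samples)) {
    stop("schema violation at $samples: missing per-sample records")
  }
  rows <- lapply(rep$samples, function(s) {
    if (is.null(s$sample_id)) {
      stop("schema violation at $samples[]/sample_id")
    }
    dplyr::bind_rows(lapply(s$genes, function(g) {
      tibble::tibble(
        sample_id = s$sample_id,
        gene = g$gene %||% NA_character_,
        candidates = g$candidates %||% NA_character_,
        selected = g$selected %||% NA_character_,
        resolution = g$resolution %||% NA_character_,
        phenotype = g$phenotype %||% NA_character_,
        actionability = g$actionability %||% NA_integer_
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(sample_id = character(), gene = character(),
                          candidates = character(), selected = character(),
                          resolution = character(), phenotype = character(),
                          actionability = integer())
  }
  out
}
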