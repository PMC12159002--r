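# shared fixtures built in code

# minimal three-allele toy gene: *1 reference, *2 one SNV, *3 two SNVs
# (positions distinct from *2's so the catalog has three defining positions)
toy_catalog <- function(freqs = c(`*1` = 0.7, `*2` = 0.2, `*3` = 0.1)) {
  alleles <- tibble::tibble(
    gene = "TOY", allele = names(freqs),
    function_class = c("normal", "decreased", "no_function"),
    activity = NA_real_,
    freq_AFR = unname(freqs), freq_AMR = unname(freqs),
    freq_EAS = unname(freqs), freq_EUR = unname(freqs),
    freq_SAS = unname(freqs)
  )
  variants <- tibble::tibble(
    gene = "TOY",
    allele = c("*2", "*3", "*3"),
    chrom = "chr1", pos = c(100, 200, 300),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    rsid = NA_character_
  )
  pgx_catalog(alleles, variants)
}

# random catalog for one gene with n_alleles single/multi-SNV alleles;
# returns the catalog plus the defining sets for the brute-force oracle
random_gene_catalog <- function(n_alleles = 4, n_positions = 3, seed = 1) {
  set.seed(seed)
  positions <- 100 * seq_len(n_positions)
  sets <- list(`*1` = integer(0))
  k <- 2
  while (length(sets) < n_alleles) {
    s <- sort(sample(seq_len(n_positions), sample(1:n_positions, 1)))
    if (!any(vapply(sets, function(x) identical(x, s), TRUE))) {
      sets[[paste0("*", k)]] <- s
      k <- k + 1
    }
  }
  f <- runif(n_alleles); f <- f / sum(f)
  alleles <- tibble::tibble(
    gene = "RND", allele = names(sets),
    function_class = "normal", activity = NA_real_,
    freq_AFR = f, freq_AMR = f, freq_EAS = f, freq_EUR = f, freq_SAS = f
  )
  vrows <- do.call(rbind, lapply(names(sets), function(a) {
    s <- sets[[a]]
    if (length(s) == 0) return(NULL)
    data.frame(gene = "RND", allele = a, chrom = "chr9",
               pos = positions[s], ref = "A", alt = "T",
               rsid = NA_character_)
  }))
  list(catalog = pgx_catalog(alleles, tibble::as_tibble(vrows)),
       sets = sets, positions = positions)
}

# independent brute-force oracle: all unordered allele pairs whose summed
# per-position indicator dosages reproduce the observed vector, computed
# from the defining sets directly (not via the package's dosage matrix)
oracle_pairs <- function(sets, positions, dosage_by_pos) {
  alleles <- names(sets)
  out <- character(0)
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      ok <- TRUE
      for (p in seq_along(positions)) {
        d <- (p %in% sets[[alleles[i]]]) + (p %in% sets[[alleles[j]]])
        if (d != dosage_by_pos[p]) { ok <- FALSE; break }
      }
      if (ok) {
        pr <- sort(c(alleles[i], alleles[j]))
        out <- c(out, paste(pr, collapse = "/"))
      }
    }
  }
  sort(out)
}

# one-row diplotype call for unit tests
fake_call <- function(gene, selected, candidates = selected,
                      resolution = "unambiguous", sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, gene = gene,
                 candidates = candidates, selected = selected,
                 resolution = resolution, notes = NA_character_)
}
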