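test_that("phenotype frequencies stratify by ancestry with conserved counts", {
  ph <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10), gene = "CYP2B6",
    phenotype = c(rep("Normal Metabolizer", 4),
                  rep("Intermediate Metabolizer", 3),
                  rep("Poor Metabolizer", 2), "Indeterminate"))
  anc <- tibble::tibble(sample_id = ph$sample_id, ancestry = "AMR")
  f <- phenotype_frequencies(ph, anc)
  expect_equal(f$pct[f$phenotype == "Normal Metabolizer"], 40)
  expect_equal(f$pct[f$phenotype == "Intermediate Metabolizer"], 30)
  expect_equal(f$pct[f$phenotype == "Poor Metabolizer"], 20)
  expect_equal(f$pct[f$phenotype == "Indeterminate"], 10)
  expect_equal(sum(f$n), 10)

  # single-sample stratum
  f1 <- phenotype_frequencies(ph[1, ], anc[1, ])
  expect_equal(f1$pct, 100)

  # missing ancestry label is an error
  expect_error(phenotype_frequencies(ph, anc[-1, ]), "ancestry")

  # percentages per stratum sum to 100 within rounding tolerance
  set.seed(5)
  ph2 <- tibble::tibble(
    sample_id = rep(sprintf("s%03d", 1:200), 2),
    gene = rep(c("A1", "B2"), each = 200),
    phenotype = sample(c("Normal Metabolizer", "Poor Metabolizer",
                         "Indeterminate"), 400, replace = TRUE))
  anc2 <- tibble::tibble(sample_id = sprintf("s%03d", 1:200),
                         ancestry = sample(pgx_ancestries(), 200, TRUE))
  f2 <- phenotype_frequencies(ph2, anc2)
  sums <- f2 |>
    dplyr::group_by(gene, ancestry) |>
    dplyr::summarise(s = sum(pct_rounded), n = sum(n),
                     nst = dplyr::first(n_stratum), .groups = "drop")
  expect_true(all(abs(sums$s - 100) <= 0.2))
  expect_true(all(sums$n == sums$nst))
})

test_that("phenotype-level simulation recovers configured stratum frequencies", {
  freqs <- default_phenotype_freqs()
  cy <- freqs[freqs$gene == "CYP2B6" & freqs$ancestry == "AMR", ]
  n <- 1102
  truth <- simulate_from_phenotype_freqs(cy, n = n, seed = 17,
                                         ancestry_proportions = c(AMR = 1))
  f <- phenotype_frequencies(truth[, c("sample_id", "gene", "phenotype")],
                             truth[!duplicated(truth$sample_id),
                                   c("sample_id", "ancestry")])
  for (i in seq_len(nrow(cy))) {
    p <- cy$pct[i] / 100
    se <- sqrt(p * (1 - p) / n) * 100
    got <- f$pct[f$phenotype == cy$phenotype[i]]
    if (length(got) == 0) got <- 0
    expect_lt(abs(got - cy$pct[i]), max(3 * se, 1e-9),
              label = paste("CYP2B6 AMR", cy$phenotype[i], got))
  }
})

test_that("reference comparison joins by population alias and leaves blanks", {
  cohort <- tibble::tibble(
    gene = "CYP2B6", ancestry = "AMR",
    phenotype = c("Poor Metabolizer", "Rapid Metabolizer"),
    n = c(13, 5), n_stratum = 100, pct = c(13.2, 5.3),
    pct_rounded = c(13.2, 5.3))
  ref <- reference_phenotype_freqs()
  cmp <- compare_to_reference(cohort, ref)
  # cohort AMR compared against the reference LAT column
  expect_equal(cmp$diff_PGKB[cmp$phenotype == "Poor Metabolizer"],
               13.2 - 9.5)
  expect_equal(cmp$PGKB_pct[cmp$phenotype == "Rapid Metabolizer"], 12.3)
  # LIT source keyed directly by AMR
  expect_equal(cmp$LIT_pct[cmp$phenotype == "Poor Metabolizer"], 16.4)

  # identical tables give all-zero differences
  self_ref <- tibble::tibble(gene = cohort$gene, population = "LAT",
                             phenotype = cohort$phenotype, source = "SELF",
                             pct = cohort$pct_rounded)
  cmp2 <- compare_to_reference(cohort, self_ref)
  expect_true(all(cmp2$diff_SELF == 0))

  # missing reference cell -> blank difference, not an error
  cmp3 <- compare_to_reference(
    tibble::tibble(gene = "CYP2B6", ancestry = "AMR",
                   phenotype = "Possible Intermediate Metabolizer",
                   n = 1, n_stratum = 100, pct = 1, pct_rounded = 1),
    ref)
  expect_true(is.na(cmp3$diff_PGKB))
})

test_that("HLA carrier prevalence counts carriers of actionable alleles", {
  n <- 100
  hla <- tibble::tibble(
    sample_id = rep(sprintf("s%03d", 1:n), each = 2),
    locus = rep(c("HLA-A", "HLA-B"), n),
    allele1 = rep(c("A*02:01", "B*44:02"), n),
    allele2 = rep(c("A*03:01", "B*07:02"), n))
  # make exactly 8 samples carriers
  hla$allele1[hla$locus == "HLA-B"][1:8] <- "B*57:01"
  prev <- hla_prevalence(hla)
  expect_equal(prev$fraction_any, 0.08)
  expect_equal(prev$per_allele$pct[prev$per_allele$allele == "B*57:01"], 8)

  # no carriers
  hla0 <- hla
  hla0$allele1[hla0$locus == "HLA-B"] <- "B*44:02"
  expect_equal(hla_prevalence(hla0)$fraction_any, 0)

  # seeded simulation recovers the configured carrier prevalence within 3 SE
  cfg <- simulation_config(n_samples = 1500, seed = 23)
  sim <- simulate_cohort(cfg)
  prev <- hla_prevalence(sim$hla)
  hf <- default_hla_carrier_freqs()
  mix <- default_ancestry_proportions()
  p_any <- sum(vapply(names(mix), function(a) {
    mix[[a]] * (1 - prod(1 - hf[[a]]))
  }, numeric(1)))
  se <- sqrt(p_any * (1 - p_any) / 1500)
  expect_lt(abs(prev$fraction_any - p_any), 3 * se)
})

test_that("expected medication impact combines carriers by inclusion-exclusion", {
  cf <- c("A*31:01" = 0.05, "B*15:11" = 0.01, "B*15:02" = 0.02,
          "B*57:01" = 0, "B*58:01" = 0.03)
  imp <- expected_medication_impact(cf)
  cbz <- imp$expected_impacted_fraction[imp$drug == "carbamazepine"]
  expect_equal(cbz, 1 - 0.95 * 0.99 * 0.98, tolerance = 1e-12)
  expect_equal(imp$expected_impacted_fraction[imp$drug == "abacavir"], 0)
  expect_equal(imp$expected_impacted_fraction[imp$drug == "allopurinol"],
               0.03)
  # a drug with no governing rule is skipped with a note
  expect_message(imp2 <- expected_medication_impact(cf, drugs = c("aspirin",
                                                                  "abacavir")),
                 "skipped")
  expect_equal(imp2$drug, "abacavir")
})
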