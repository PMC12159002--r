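test_that("the actionability map reproduces the published 0/1 assignments", {
  # golden assignments: label -> score
  golden <- c(
    "Normal Function" = 0, "Decreased Function" = 1, "Poor Function" = 1,
    "Uncertain Susceptibility" = 0, "NA" = 0,
    "Intermediate Metabolizer" = 1, "Normal Metabolizer" = 0,
    "Poor Metabolizer" = 1, "Rapid Metabolizer" = 1, "Normal" = 0,
    "Possible Decreased Function" = 0, "Increased Function" = 1,
    "Favorable Response" = 0, "Ultra Rapid Metabolizer" = 1,
    "Possible Intermediate Metabolizer" = 0,
    "Malignant Hyperthermia Susceptibility" = 1, "Normal Risk" = 0,
    "increased risk of aminoglycoside-induced hearing loss" = 1,
    "uncertain risk of aminoglycoside-induced hearing loss" = 0,
    "normal risk of aminoglycoside-induced hearing loss" = 0,
    "moderate deficiency (BCHE)" = 1,
    "mild deficiency or normal activity (BCHE)" = 0,
    "G6PD variable or deficient" = 1, "G6PD deficient with CNSHA" = 1,
    "G6PD Normal" = 0
  )
  expect_identical(score_phenotype(names(golden)), unname(as.integer(golden)))
  # unknown labels are a hard error, never silently 0
  expect_error(score_phenotype("Mystery Metabolizer"), "not in actionability")
})

test_that("HLA risk alleles score per locus with the published drug lists", {
  s <- score_hla(c("B*57:01", "B*44:02"))
  expect_equal(s$score_B, 1L)
  expect_equal(s$score_A, 0L)
  expect_setequal(s$drugs, c("abacavir", "flucloxacillin"))

  expect_equal(score_hla(c("A*02:01", "A*03:01"))$score_A, 0L)
  expect_equal(score_hla(c("A*31:01", "A*02:01"))$score_A, 1L)

  s <- score_hla(c("B*15:02", "B*07:02"))
  expect_setequal(s$drugs, c("carbamazepine", "oxcarbazepine", "lamotrigine",
                             "phenytoin", "fosphenytoin"))

  # all five risk alleles score 1 at their locus
  for (a in c("B*57:01", "B*58:01", "B*15:11", "B*15:02")) {
    expect_equal(score_hla(a)$score_B, 1L, info = a)
  }
  expect_equal(score_hla("A*31:01")$score_A, 1L)

  # four-field input truncates to two fields with a warning
  expect_warning(s <- score_hla("B*57:01:01:02"), "truncated")
  expect_equal(s$score_B, 1L)
})

test_that("cohort summaries count actionable loci per sample", {
  prof <- tibble::tibble(
    sample_id = rep(c("a", "b", "c", "d"), each = 5),
    gene = rep(sprintf("G%d", 1:5), 4),
    score = c(0, 0, 0, 0, 0,  1, 0, 0, 0, 0,  1, 1, 1, 0, 0,  1, 1, 1, 1, 1)
  )
  s <- cohort_actionability(prof)
  expect_equal(s$fraction_ge1, 0.75)
  expect_equal(s$fraction_ge3, 0.5)
  expect_equal(s$totals$total[s$totals$sample_id == "d"], 5)

  allnorm <- tibble::tibble(sample_id = c("a", "b"), gene = "G1", score = 0)
  s0 <- cohort_actionability(allnorm)
  expect_equal(s0$fraction_ge1, 0)
  expect_equal(s0$fraction_ge3, 0)
  expect_equal(sum(s0$gene_counts$n_actionable), 0)
})

test_that("summaries agree with an independent recount on random cohorts", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    genes <- sprintf("G%d", 1:sample(3:18, 1))
    prof <- tibble::tibble(
      sample_id = rep(sprintf("s%02d", 1:n), each = length(genes)),
      gene = rep(genes, n),
      score = sample(0:1, n * length(genes), replace = TRUE, prob = c(.8, .2))
    )
    s <- cohort_actionability(prof)
    # brute-force recount from the raw score matrix
    m <- matrix(prof$score, nrow = n, byrow = TRUE)
    expect_equal(s$fraction_ge1, sum(rowSums(m) >= 1) / n)
    expect_equal(s$fraction_ge3, sum(rowSums(m) >= 3) / n)
    expect_lte(s$fraction_ge3, s$fraction_ge1)
    for (g in genes) {
      expect_equal(s$gene_counts$n_actionable[s$gene_counts$gene == g],
                   sum(prof$score[prof$gene == g]))
    }
    # permuting sample order changes nothing
    s2 <- cohort_actionability(prof[sample(nrow(prof)), ])
    expect_equal(s2$fraction_ge1, s$fraction_ge1)
    expect_equal(s2$fraction_ge3, s$fraction_ge3)
    # dropping a gene never increases a sample total
    s3 <- cohort_actionability(prof[prof$gene != genes[1], ])
    j <- dplyr::inner_join(s$totals, s3$totals, by = "sample_id")
    expect_true(all(j$total.y <= j$total.x))
  }
})

test_that("profiles join phenotype and HLA scores over the gene scope", {
  ph <- tibble::tibble(
    sample_id = c("a", "a", "b", "b"),
    gene = c("CYP2B6", "TPMT", "CYP2B6", "TPMT"),
    phenotype = c("Poor Metabolizer", "Normal Metabolizer",
                  "Normal Metabolizer", "Normal Metabolizer"))
  hla <- tibble::tibble(sample_id = c("a", "a", "b", "b"),
                        locus = c("HLA-A", "HLA-B", "HLA-A", "HLA-B"),
                        allele1 = c("A*31:01", "B*44:02", "A*02:01", "B*07:02"),
                        allele2 = c("A*02:01", "B*07:02", "A*03:01", "B*44:02"))
  prof <- actionability_profiles(ph, hla = hla)
  s <- cohort_actionability(prof)
  expect_equal(s$totals$total[s$totals$sample_id == "a"], 2)  # PM + HLA-A
  expect_equal(s$totals$total[s$totals$sample_id == "b"], 0)
  # out-of-scope genes are ignored
  ph2 <- rbind(ph, tibble::tibble(sample_id = "a", gene = "CYP3A5",
                                  phenotype = "Poor Metabolizer"))
  prof2 <- actionability_profiles(ph2, hla = hla,
                                  scope = setdiff(actionability_scope(),
                                                  "CYP3A5"))
  expect_false("CYP3A5" %in% prof2$gene)
})
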