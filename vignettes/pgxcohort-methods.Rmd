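---
title: "Methods: star-allele diplotyping and actionability scoring for exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: star-allele diplotyping and actionability scoring for exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxcohort)
```

## The problem

Clinical exome sequencing performed for rare-disease diagnosis contains,
as a by-product, most of the information needed to genotype the major
pharmacogenes. `pgxcohort` implements the secondary-use analysis: starting
from unphased germline genotypes (VCF), per-position sequencing depth, and
HLA typing results, it calls star-allele diplotypes, translates them to
CPIC-style phenotypes, scores each phenotype as actionable or not, and
reports ancestry-stratified phenotype frequencies side by side with
reference populations. The emulated setting is a large admixed pediatric
cohort (1,777 probands; 62% Admixed American, 23% European, 8% East
Asian, 5% African, 2% South Asian) sequenced with a standard exome
capture at a mean depth of about 162X.

Two properties of exome data drive the design:

1. **Capture gaps.** Several haplotype-defining variants sit in promoters
   or at intron boundaries that exome probes do not cover (the classic
   examples bundled here: the `CYP2C19*17` promoter SNP at near-zero
   depth and the `CYP3A5*3` intron-boundary SNP at roughly 15X). A
   genotype of "reference" at an uncovered position is not evidence, so
   genes whose core positions are inadequately covered must be excluded
   before phenotype assignment, and per-sample coverage shortfalls must
   downgrade call confidence rather than silently pass as reference.
2. **Phasing ambiguity.** Unphased genotypes cannot distinguish a
   haplotype carrying the union of two variant sets from the two
   haplotypes carrying them separately — the textbook case being
   `CYP2B6 *1/*6` versus `*4/*9`. A caller must either report all
   consistent pairs or resolve the ambiguity explicitly by population
   frequency.

## The model and procedure

### Diplotype calling

For a gene with star alleles $A_1,\dots,A_k$ (each a set of defining
variants) and an observed alt-dosage vector $d$ over the gene's
haplotype-defining positions, the candidate set is

$$C(d) = \{\,\{A_i, A_j\} : \mathbf{1}_{A_i} + \mathbf{1}_{A_j} = d\,\}$$

— every unordered pair whose summed per-position indicators reproduce the
observed dosages exactly. This is computed by exhaustive pair
enumeration, which is exact and cheap at catalog scale (tens of alleles).
Partial matches are never accepted: a dosage vector no pair explains is a
no-call listing the unexplained positions, and novel-allele inference is
out of scope.

In `single_call` mode, ambiguity is resolved by selecting the pair
maximizing $f_a(A_i) \cdot f_a(A_j)$ under the sample's ancestry $a$,
mirroring resolvers that report the most commonly observed diplotype when
phase is unknown. Ties and all-zero-frequency candidate sets fall back
deterministically to the pair containing the lowest star number and are
flagged `low_confidence` — never silent. In `multi_report` mode all
candidates are reported and no selection is made.

Copy number is an *input*, not an estimate: read-depth CNV calling from
exomes is unreliable for these genes, so deletions and duplications
arrive as a per-sample table. One copy pairs the single explained
haplotype (re-derived from the dosage vector read as haploid) with the
deletion allele (`*5` for CYP2D6, `*DEL` elsewhere); three copies append
`x2` to the hinted allele, or to the higher-frequency allele of the pair
when no hint is given (flagged `low_confidence`).

### Coverage gating

Per position, the cohort mean and standard deviation of depth are
computed across samples. A gene is excluded when any core position has
mean depth below `min_mean` (default 20 reads, the usual diagnostic
threshold) or a coefficient of variation above `max_cv` (default 1.0).
"Variable coverage" has no standard quantitative definition; the CV
criterion is this package's operationalization, recorded as a distinct
exclusion reason (`high_variability`) so it can be audited, and both
thresholds are configurable. Gene exclusion is a cohort-level decision
(per-position cohort means); per-sample coverage flags are additionally
emitted and downgrade individual calls, but do not affect exclusion.
Under the default capture-gap model exactly five genes are excluded
(CYP2C19, CYP3A5, UGT1A1, VKORC1, IFNL3), and they are removed from the
actionability scope before counting.

### Phenotype translation

Each gene carries one rule:

* **Function-pair lookup** (CYP2B6, CYP2C9, CYP2C19, CYP3A5, NAT2, TPMT,
  NUDT15, IFNL3 for metabolizer labels; SLCO1B1, DPYD, CYP4F2, ABCG2,
  UGT1A1, VKORC1 for function labels). The mapping from an unordered pair
  of allele function classes to a label is an editable table, so a
  deployment can attach "Possible Intermediate Metabolizer"-style labels
  exactly as its guideline version dictates. The shipped defaults follow
  the consensus convention (e.g. normal/no-function and
  decreased/decreased pairs are Intermediate Metabolizers;
  decreased/no-function pairs are Poor Metabolizers).
* **Activity score** (CYP2D6): the sum of per-allele activity values,
  with the deletion contributing 0 and a duplication twice its base
  value. Bin bounds default to 0 (Poor), (0, 1] (Intermediate), (1, 2.25]
  (Normal), above 2.25 (Ultrarapid); they are configuration, since
  guideline revisions have moved them.
* **Carrier risk** (RYR1, CACNA1S, MT-RNR1, CFTR): carrying a risk allele
  yields the risk label (Malignant Hyperthermia Susceptibility; increased
  risk of aminoglycoside-induced hearing loss; Favorable Response for
  ivacaftor-responsive CFTR variants), zygosity ignored.
* **G6PD / BCHE class lookups**: G6PD deficient-class alleles map to
  "G6PD variable or deficient", homozygous class-I to "G6PD deficient
  with CNSHA"; two reduced-activity BCHE alleles give moderate
  deficiency. Without chrX copy information, G6PD is computed under
  reported-genotype semantics.

Any diplotype containing an allele of uncertain or unknown function is
`Indeterminate`, and a missing call is the first-class label `NA`, so
downstream scoring can apply its "no call scores 0" rule. Translation is
total: every resolvable diplotype over the bundled catalog maps to
exactly one vocabulary label (tested exhaustively).

### Actionability

The phenotype-to-0/1 map is applied exactly as printed in its source
convention — including `Rapid Metabolizer = 1`, which some guidelines
would treat as non-actionable for some genes; fidelity to the published
map takes precedence and the map is a config table users can edit.
Unknown labels are a hard error, never silently 0. HLA loci score 1 when
any of B\*57:01, B\*58:01, A\*31:01, B\*15:11, B\*15:02 is carried, with the
drug list as the union of the carried alleles' rules; counting is
per-locus (HLA-A, HLA-B), which makes the scope exactly 18 loci. A
sample's total is the sum over in-scope genes; the cohort summary reports
the fractions of samples with at least one and at least three actionable
loci and the per-gene ranking.

### Reporting

Frequencies are percentages per gene and ancestry stratum with
Indeterminate retained in the denominator; one-decimal rounding matches
the usual presentation, with unrounded values kept in machine output.
Reference comparison joins through a population alias map (cohort AMR
against a reference LAT column) and emits only differences — no
statistical tests, deliberately, since cohort and reference datasets
differ in ascertainment and pipeline. The expected medication impact per
drug assumes carrier independence across HLA loci
($1 - \prod_\text{alleles}(1 - f)$), a documented approximation.

### Caller concordance

Accuracy against consensus-truth tables is reported in two modes because
published figures rarely state how multi-candidate output was counted:
`strict` (the selected pair must equal the consensus, unordered) and
`any_match` (the consensus may sit anywhere in the candidate list);
`any_match` dominates `strict` by construction. Discordances are
categorized as `cnv_misassignment` (pairs differing only in
duplication/deletion structure), `phase_ambiguity` (truth among
candidates, different selection), `no_call`, or `allele_miss`, and every
accuracy is reported with its denominator.

## The synthetic generator

The generator defines the study conditions rather than adapting to them.
Two levels exist so reporting-stage tests do not require a
frequency-consistent allele catalog:

* **Genotype level** (`simulate_cohort()`): ancestry from the 62/23/8/5/2
  mixture; per gene, two star alleles drawn independently from the
  stratum's catalog frequencies (Hardy–Weinberg within strata; admixture
  within an individual is not modeled, matching the single-ancestry-code
  assumption of the caller); dosages derived from the drawn pair; depth
  from a truncated Normal(162, 30) with explicit capture-gap positions
  overriding the mean; CYP2D6 duplications at rate 0.01 and deletions
  through the `*5` allele frequency, both reflected in the CN table; HLA
  carriers drawn per ancestry at realistic frequencies yielding roughly
  8% any-carrier prevalence under the default mixture. Outputs (VCF v4.2,
  depth/CN/HLA/ancestry TSVs) are byte-deterministic given the seed.
* **Phenotype level** (`simulate_from_phenotype_freqs()`): labels drawn
  directly from a per-gene, per-ancestry frequency table. The bundled
  defaults use observed exome-cohort values where published (all CYP2B6
  strata; CYP2D6 and CYP2C9 Admixed American cells) and once-chosen,
  field-realistic values elsewhere (e.g. NAT2 left largely Indeterminate,
  as exome pipelines with limited NAT2 star coverage report it; NUDT15
  intermediate metabolizers concentrated in East Asian strata).

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: linkage between genes, within-person
admixture, genotyping error, read-level artifacts, allele catalogs beyond
the bundled illustrative one, and correlation between phenotypes across
genes. The last point matters for multi-hit summaries: because genes are
drawn independently, the simulated fraction of samples with three or more
actionable loci (about 42% at the default conditions) is higher than
values reported from real cohorts of this composition (about 22%), where
phenotypes are not independent and several genes' calls fail together.
The fraction with at least one actionable locus (about 94% simulated) is
insensitive to this and lands close to reported values (about 93%).

## Numerical choices and degenerate inputs

* Candidate enumeration and its ordering are fully deterministic
  (lexicographic by star number); ties in frequency resolution are broken
  toward the lowest star number and flagged.
* Depth summaries use the sample standard deviation (n − 1); a
  single-sample position has SD 0; positions with no records are reported
  with `n_samples = 0` and flagged, and count as failing the gate.
* Frequencies missing for an ancestry are treated as 0 during resolution
  (flagged when all candidates are 0) but are an error during simulation,
  where they would silently bias draws.
* Coordinates are 1-based GRCh38 VCF convention; indels left-normalized
  as in VCF; a genomic position maps to exactly one ref/alt per gene.
* The bundled catalog is illustrative: star-allele definitions are
  simplified to one or two tag SNVs, and frequencies are
  realistic-by-magnitude, not authoritative. Users supply their own
  catalog TSV for real cohorts.
* Problem sizes in the test suite and acceptance script (cohorts of
  500–1,777 samples, 1,000-vector oracle sweeps, 100–200 randomized
  property iterations) were chosen to give the statistical checks 3-SE
  headroom while keeping a full run inside a few minutes on one core.

## Known limitations

* Suballele resolution, novel-allele inference, and read-backed phasing
  are out of scope; gVCF semantics are approximated by plain VCF plus the
  depth table.
* HLA typing and ancestry estimation are inputs, not computations.
* CYP2D6 hybrid/tandem arrangements beyond simple deletion and
  duplication are not modeled.
* MT-RNR1 is treated as a diploid locus by the generator for uniformity;
  only carrier status is interpreted, so homoplasmy is not represented.
* The medication-impact calculator is an expected-fraction computation
  under carrier independence, not a prescription-linked analysis.
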