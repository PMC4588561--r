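---
title: "Consensus high functional impact variant analysis of targeted kinome panels"
author: "kinomeHFI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus high functional impact variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomeHFI)
```

# Scope and model

`kinomeHFI` analyzes annotated variant calls from targeted kinome
sequencing of tumor biopsies — the stage *after* alignment, variant
calling and functional annotation. The interchange unit is one
annotated call in one sample: genomic coordinate (GRCh37 naming,
1-based), consequence class, read depth, three functional-predictor
annotations (a Mutation Assessor category, a SIFT score, a
kinase-specific deleteriousness verdict), and dbSNP/COSMIC membership
flags that proxy for germline and somatic status when no matched
normal is available.

The scientific core is a consensus prioritization rule. A call is
**high functional impact (HFI)** when

* Mutation Assessor places it in the *high* or *medium*
  functional-importance category **and** at least one of the other two
  predictors concurs (SIFT strictly below 0.05, or a kinase-specific
  verdict of *yes*); **or**
* it is a stop-gain, stop-loss, or frame-shifting indel, regardless of
  predictor scores.

Missing predictor annotations count as non-deleterious — they can
never satisfy a clause — so structural classes are the only route to
HFI for score-less calls. Synonymous calls are never HFI through the
consensus clause, and in-frame indels have no structural route. The
analysis set then keeps the non-synonymous HFI calls whose read depth
strictly exceeds 20 (so depth 21 is the first retained value).

Two readings of the coverage filter are possible: per call in the
carrying sample, or as the median depth across all carriers of the
same unique variant. Because per-sample depth is the only coverage
field in the interchange format, the per-call reading is the default;
`filterAnalysisSet(..., coverageMode = "median")` switches to the
median-across-carriers reading.

A gene is **affected** ("variant kinase") in a sample when it carries
at least one analysis-set HFI call there. The `HFIMatrix` class — a
`SummarizedExperiment` with `counts` and `affected` assays — holds the
gene-by-sample aggregation, clinical covariates in `colData` and gene
annotation in `rowData`. Rows are ordered by descending total count,
columns by the clinical hierarchy ER, HER2, grade, N stage, T stage,
response (negatives before positives, lower grades first, unknowns
last); the ordering is purely presentational but fixed, so pipeline
outputs are byte-reproducible.

# Statistics

**Subgroup contrasts.** For each gene affected in at least one
included sample, `compareGroups()` forms the 2x2 table of affected
counts against the two group sizes and computes a two-sided Fisher
exact p-value under the minimum-likelihood convention: the sum of the
hypergeometric probabilities of all tables with the observed margins
whose probability does not exceed that of the observed table. This is
the convention of `fisher.test()`, and it reproduces the
hand-checkable published values the test suite asserts (for example,
3/24 affected vs 0/44 gives 0.04; 7/43 vs 1/39 gives 0.06). The
implementation is the package's own; `fisher.test()` and a
combinatorial enumeration oracle serve as independent cross-checks in
the tests. Samples whose covariate value is unknown are excluded from
a contrast, which is why a 92-sample cohort can yield a 43-versus-39
receptor-status comparison. Bonferroni correction uses the number of
genes actually tested in that contrast as the family size; unadjusted
values are reported alongside, since the published tables print
unadjusted p-values.

**Variant loads.** The load of a gene is its pooled analysis-set HFI
count across the included samples divided by the gene's nucleotide
length (caller-supplied; the field does not standardize CDS versus
targeted-region length, so the denominator is an explicit input). The
load of a kinase group is the mean over the group's *expressed* genes
— genes whose log2 expression is at or above 6.0, with
missing-expression genes retained because the filter's purpose is
removing demonstrably unexpressed genes. Zero-count expressed genes
contribute zero loads to the group mean; excluding them would bias
loads upward. Pooling across samples is the default because a gene's
load is a single number; `perSampleGroupLoads()` computes the
per-sample version that `compareGroupLoads()` feeds to the unpaired
two-sided Wilcoxon rank-sum test (exact by enumeration when both
groups have at most ten observations and no ties, otherwise the
normal approximation with tie and continuity correction) for the
primary-versus-metastatic comparison, Bonferroni over the ten groups.

**Co-occurrence.** `cooccurrenceScreen()` pairs every known somatic
variant (COSMIC-flagged) with every known germline variant
(dbSNP-flagged) at unique-variant resolution — `chrom:pos:ref:alt`,
not gene — builds each pair's joint presence/absence table over all
samples, and applies the same exact test with Bonferroni over all
pairs. Pairs with an empty margin are reported with p = 1 and a
degeneracy flag rather than dropped.

**Replicate concordance.** Concordance between two call sets of the
same DNA is the Jaccard index of their keyed calls, overall and
stratified by coverage bin (binning by the minimum of the two
replicate depths). Jaccard is a design choice — no standard formula
exists for call-level concordance — and an asymmetric recall variant
(`metric = "recall"`) is available.

**Probe-set collapsing.** When expression comes from microarrays with
several probe sets per gene, `collapseProbesets()` keeps the probe
with the highest mean expression, breaking ties by greater variance
and then by probe identifier order so the selection is deterministic.

# The synthetic cohort generator

No patient-level sequencing data accompany the analysis, so
`simulateCohort()` generates cohorts with the statistical structure
the pipeline assumes; all tests and the acceptance study run on it.
Default parameters are the study conditions the package models:

* 92 samples, 19 of them metastatic; receptor status, grade, and
  stage frequencies matching a neoadjuvant breast-cancer series
  (about half ER-negative, HER2 status unknown for roughly 40%,
  three in five grade 3); a 35% pathologic complete response rate
  among primaries, a typical neoadjuvant figure.
* Negative-binomial variant counts per sample with mean 1052 and size
  28, giving an observed range of roughly 500–1550; 97% of calls
  carry a dbSNP or COSMIC identifier; negative-binomial coverage with
  mean 369 and size 2.
* Consequence-class frequencies with 26% synonymous and about 14%
  protein-altering calls (median ~150 non-synonymous per sample), the
  remainder non-coding panel calls.
* Predictor annotations drawn conditionally on a latent
  "truly deleterious" flag (2% of scorable calls; structural classes
  are deleterious by construction). Sensitivities and benign-positive
  rates are set so that predictor disagreement is substantial — about
  40% of unique non-synonymous variants reach two-predictor consensus
  — and the resulting analysis set averages ~24 HFI calls per sample.
  Because predictors are conditionally independent given the latent
  flag, the three-set Venn structure of predictor agreement is
  reproducible by construction, and with noiseless predictor settings
  the pipeline's matrix equals the recorded ground-truth counts
  exactly (a test asserts this).

Planted effects define their target quantity directly. A planted
enrichment (gene, covariate level, odds ratio, baseline prevalence)
draws each sample's affected status from the odds-shifted prevalence
and injects a guaranteed analysis-set call for affected samples; the
planted gene is excluded from background variant placement so the
realized odds ratio is the configured one, not an attenuated mixture.
Planted somatic–germline pairs draw the per-sample joint cell from the
2x2 distribution with the configured margins and odds ratio (the
standard quadratic solution; infeasible combinations error before
anything is written). Site-specific load multipliers add Poisson extra
HFI calls to metastatic samples, apportioned by gene length within the
group. Positions are uniform within genes; there is no
mutational-signature or sequence-context model, no linkage between
samples (each sample's calls are an independent stream), and no
recurrent-variant structure beyond the planted effects — so
cohort-level unique-variant counts are not comparable to a real
cohort's, and passing tests say nothing about those.

Determinism: the cohort is a pure function of configuration and seed.
Per-sample streams use substream seeds `(seed + 77777 * i) mod
(2^31 - 1)`, so one sample's calls do not depend on how many samples
precede it; planted effects use a separate offset stream.

# Verification design

The test suite pairs every exact computation with an independent
oracle: the Fisher p against full-support enumeration with binomial
coefficients on every 2x2 table with row margins up to 15 (and
against `fisher.test()` on random larger tables); the rank-sum p
against `combn` enumeration of all rank configurations up to total
size 8 (and against `wilcox.test()` on both the exact and the
tie-corrected normal path); the HFI rule against an independently
coded predicate on the exhaustive grid of category, score bucket,
verdict and class, including the SIFT = 0.05 and coverage = 20
boundaries. The end-to-end study runs 200 simulated cohorts with one
enrichment planted at odds ratio 8 over baseline prevalence 0.1
(recovery criterion: the planted gene ranks first in at least 90% of
cohorts) and 200 null cohorts (at most 10% of cohorts may show any
Bonferroni-significant gene). Those problem sizes — 92 samples, ~1050
calls per sample, 200 seeds per arm — are the package's reference
study design and run in a few minutes on one CPU.

# Numerical and degenerate-input choices

* Fisher tie detection uses a `1e-7` relative tolerance when comparing
  table probabilities, matching common practice; the all-zero table
  returns p = 1 with a `degenerate` attribute rather than an error.
* The rank-sum exact path refuses ties (the tie-corrected normal
  approximation takes over); when every observation is identical the
  variance is zero and p = 1.
* Probabilities are never computed via chi-square approximations.
* Readers reject invalid rows with row-number diagnostics instead of
  silently coercing; missing predictor scores map to an explicit
  `missing` category and never to a numeric default.
* An empty variant table flows through the whole pipeline (empty
  matrix, empty comparisons) with a warning rather than an error.

# Known limitations

* Predictor scores are consumed, not computed; re-annotation,
  transcript models and liftover are out of scope.
* Without matched normals, dbSNP/COSMIC membership is an imperfect
  proxy for germline/somatic status; the co-occurrence screen inherits
  that approximation.
* The 2x2-per-gene design treats genes independently; no joint or
  regression modeling is attempted, and only Bonferroni (no FDR)
  correction is provided, mirroring the published analysis style.
* The generator's clinical covariates are sampled independently;
  real subtype correlations (e.g. grade with receptor status) are not
  modeled, so contrasts that rely on such correlations should not be
  calibrated against it.
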