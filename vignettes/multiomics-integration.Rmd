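---
title: "Three-level multi-omics integration: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-level multi-omics integration: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomix)
```

## The scientific problem

Developmental exposures — here, maternal inflammation modelled by perinatal
IL-6 administration in mice — can reprogram gene regulation in fetal organs
without altering the DNA sequence. Detecting such programming requires
looking at several regulatory layers at once: promoter DNA methylation can
silence or license transcription, and miRNAs tune transcript abundance
post-transcriptionally. A gene that is differentially expressed, carries a
differentially methylated promoter, *and* is targeted by an inversely
changed miRNA is a far stronger candidate for durable regulation than a hit
in any single assay.

`triomix` implements this three-level integration for a standard two-group
(control vs treated) design with three data types: mRNA counts, miRNA
counts, and whole-genome bisulfite methylation counts.

## Per-layer differential models

**Counts (genes and miRNAs).** Libraries are normalized by median-of-ratios
size factors. Features with normalized mean below 1 are removed before
testing (an independent filter; it does not look at group labels). For each
remaining feature the log2 fold-change is
$\log_2\frac{\bar{y}_T + 0.5}{\bar{y}_C + 0.5}$ on normalized means, and
significance comes from a Wald statistic on the log mean ratio under the
negative-binomial model, whose delta-method variance is
$(1/\mu_C + \alpha)/n_C + (1/\mu_T + \alpha)/n_T$. The dispersion $\alpha$
is a per-feature method-of-moments estimate shrunk 70% towards the
across-feature median and floored at 0.01. Moderation matters: with 5
replicates per group the raw moment estimator is so noisy that the naive z
reference is anti-conservative (empirical type-I error $\approx$ 0.07 at
nominal 0.05) while a $t_{n_1+n_2-2}$ reference over-corrects. Because the
shrunk dispersion carries information from the whole matrix, the statistic
is referred to a t distribution with $2(n_1+n_2-2)$ degrees of freedom; at
the package's default simulation conditions this yields empirical type-I
error of 0.03–0.05 and approximately uniform null p-values. FDR is
Benjamini–Hochberg. Default calling thresholds: $|\mathrm{log_2FC}| \ge
0.5$ and FDR $\le 0.05$ for both genes and miRNAs (the miRNA fold-change
cutoff is configurable through `threshold_set()`, since reasonable analyses
also use 0).

**Methylation.** Per-position coverage records (Bismark-style, 1-based
inclusive on disk, converted to 0-based half-open internally) are
aggregated into fixed-width tiles (default 100 bp) or supplied directly as
regions. Two coverage filters mirror common WGBS practice: a region is
dropped when half or more of the samples have fewer than 4 reads, and
retained only if some replicate in *each* group has coverage strictly
exceeding 5 reads. Counts are then pooled within groups; the effect size is
the log2 odds ratio of methylation (treated vs control) with a 0.5
pseudocount on all four cells of the pooled table, and the p-value is a
1-df likelihood-ratio test of a two-group binomial-logistic model against
the pooled model. Region calling uses the raw p-value ($\le 0.05$) with
$|\mathrm{log_2FC}| \ge 1$ — FDR is reported but deliberately not used for
calling, making the (common) convention explicit and configurable. Pooling
reads within groups ignores replicate-level overdispersion; under the
generator's binomial model the test is exactly calibrated, but on real WGBS
data with biological replicate variability it will be liberal — a known
limitation shared by pooled-count DMR callers.

## Promoter assignment

A promoter is the window $[\mathrm{TSS} - 2000, \mathrm{TSS} + 2000)$ —
2 kb upstream and downstream, strand-aware only in the sign of the reported
distance. Every region gets exactly one feature class with precedence
promoter > exon > intron > intergenic. Membership needs at least 1 bp of
window overlap; among overlapping windows the gene with the smallest
absolute midpoint-to-TSS distance wins, ties broken lexicographically so
reruns are stable. Because membership is by overlap but distance is by
midpoint, a promoter region's |distance| can exceed 2000 by up to half a
region width. Intergenic regions still report their nearest gene, which is
useful for review but never used by the integration (only `promoter`
regions feed triples).

## Integration and the four categories

Anti-correlation filtering computes, for each (miRNA, target gene) pair of
the user-supplied interaction table whose two features were called in
*opposite* directions, the Pearson correlation of normalized expression
(FPKM for genes, CPM for miRNAs — the correlation is invariant to the
per-feature length scaling) across **all** samples, both groups pooled;
pooling is what makes a planted differential relationship visible as
negative correlation. Pairs are retained iff PCC $< -0.5$ and p $< 0.05$
(strict, unlike the inclusive differential thresholds — both conventions
follow the respective notation of the field). A gene with several
significant promoter DMRs contributes the one with the smallest p-value.

Each (gene, miRNA) combination with all three layers of evidence becomes a
triple, classified purely by its sign pattern:

| promoter | gene | miRNA | category | reading |
|---|---|---|---|---|
| hyper | down | up | red | consistent: methylation and miRNA both repress |
| hypo | up | down | blue | consistent: both permissive |
| hyper | up | down | green | inconsistent methylation |
| hypo | down | up | orange | inconsistent methylation |

The remaining four sign patterns have the miRNA moving *with* the gene and
are excluded upstream by the anti-correlation precondition, so the
classifier is total on its admissible inputs and errors on the rest.

The network layer reuses the same machinery at permissive cutoffs (PCC
$< -0.1$, p $< 0.1$), optionally retaining non-significant edges flagged
rather than dropped, hub miRNAs ranked by out-degree with lexicographic
ties. Over-representation of gene sets is an upper-tail hypergeometric
test over a user-supplied universe with BH or Bonferroni adjustment.

## The exact rank test

Small immunofluorescence validation experiments (n = 5 per group) need an
exact test. `mann_whitney_exact()` computes $U = \#\{(x_i, y_j): x_i <
y_j\}$, folds it to $\min(U, n_1 n_2 - U)$ and doubles the exact lower-tail
mass (capped at 1), with the null distribution built by the count recursion
$N(u; m, n) = N(u - n; m-1, n) + N(u; m, n-1)$. At $n_1 = n_2 = 5$ this
yields the familiar ladder 0.008 (complete separation), 0.032 ($U = 2$),
0.095 ($U = 4$). Ties switch to midranks with full enumeration of all
$\binom{n_1+n_2}{n_1}$ label assignments; more than 20 observations fall
back to a flagged normal approximation with continuity correction.

## What the generator emulates — and what it does not

`simulate_counts()` draws negative-binomial counts (gamma-mixture
parameterization, the model underlying the standard RNA-seq callers) with
log-normal per-feature baselines (sdlog 1 by default) and log-normal
library sizes (sdlog 0.1) to exercise normalization.
`simulate_methylation()` draws Poisson coverage (mean 30) and binomial
methylated counts whose logit is a context-dependent baseline plus a
planted treated-group shift; contexts are assigned CpG/CHG/CHH at
74/12/14%, the split typical of mammalian WGBS. `build_scenario()` plants
whole regulatory stories: each category gene receives its own miRNA, a
promoter region shifted by 10 log2-odds units, and expression effects of
|log2FC| = 5 — ten times the calling thresholds — at dispersion 0.02, with
5 expression and 6 methylation replicates per group, mirroring the design
scale of the motivating study. Planted promoter regions sit wholly inside
the 2 kb window (centred on the TSS) to avoid partial-overlap ambiguity,
and use a 0.5 baseline fraction so hyper- and hypo-shifts are symmetric.

What passing tests on these simulations show: the pipeline's logic,
thresholds, and calibration behave as specified under the assumed
generative models. What they do not show: robustness to replicate-level
methylation overdispersion, sequencing artefacts, mappability and
annotation error, or the correlated dropout structure of real miRNA data.
Genome-wide result counts from any real study depend on the deposited
reads and external interaction databases and are deliberately not
reproduction targets; the package instead validates against a printed
worked example (21 associations over 19 genes) and against planted truth.

## Numerical choices and degenerate inputs

* Seeds: every generator takes an explicit seed and restores the RNG state
  (`withr::with_seed`); `build_scenario` fans one master seed out to
  per-stage child seeds so stages are independently reproducible.
* Zero-coverage positions keep an `NA` methylation fraction — never 0.
* Constant expression vectors have no defined correlation: `NA` from
  `pearson_with_p()`, dropped with a warning in co-expression scoring.
* All-zero count features are removed by the independent filter; an
  all-zero matrix is an error, as is a group with fewer than 2 samples or
  zero pooled reads.
* Threshold comparisons are inclusive for differential calling and strict
  for correlation cutoffs; both are centralized (`threshold_set`,
  `pipeline_config`) so the conventions are visible and changeable.
* Problem sizes in the test-suite simulations (2000 null features and 10
  seeds for calibration; 20 seeds for scenario recovery; $10^5$ sites for
  context proportions) were chosen as the smallest sizes at which the
  checked proportions are stable to well within the asserted tolerances.

## Worked example

The package ships a worked example
(`inst/extdata/il6_kidney_multiomics_records.tsv`): the 21 printed
promoter-DMR/DEG/DEmiR associations over 19 genes from a perinatal IL-6
newborn mouse kidney study. Running them through the integration:

```{r}
rec <- read_multiomics_records(
  system.file("extdata", "il6_kidney_multiomics_records.tsv",
              package = "triomix"))
inputs <- records_as_integration_inputs(rec)
triples <- integrate_three_level(inputs$promoter_dmrs, inputs$degs,
                                 inputs$anticorr)
nrow(triples)
genes <- unique(triples[c("gene_id", "category")])
table(genes$category)
sum(genes$category %in% c("red", "blue"))
```

21 triples over 19 genes; 11 genes are consistently regulated (red + blue)
and 8 inconsistently (green + orange).

## Known limitations

* The DMR test is calibrated for within-group binomial variation only (see
  above); a beta-binomial extension would be the natural next step.
* miRNA host-locus methylation linking (`link_dmr_demir`) requires miRNA
  loci in the annotation; the synthetic scenarios do not exercise it end
  to end beyond unit level.
* Enhancer-range (5–10 kb) regulation is out of scope: regions beyond the
  2 kb promoter window are reported as intergenic/genic, never linked.
* The hypergeometric ORA treats gene sets as given; no term-term
  clustering or ontology redundancy reduction is performed.
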