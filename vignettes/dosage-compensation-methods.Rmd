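---
title: "Methods: measuring dosage compensation on young sex chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring dosage compensation on young sex chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When a Y chromosome stops recombining with its X partner, Y-linked
alleles accumulate deleterious mutations and their expression decays.
Males then face a dose problem: for an XY gene pair they carry one
functional X copy plus a degenerating Y copy, whereas females carry two
X copies. *Dosage compensation* is any regulatory response that restores
male expression towards the female (two-copy) level. On evolutionarily
young sex chromosomes — such as those of dioecious plants, where the
male-specific region arose only a few million years ago — the open
question is whether compensation exists at all and, if so, whether it
acts gene-by-gene or chromosome-wide.

This package implements an analysis built entirely from bulk RNA-Seq of
males and females of a dioecious species, plus a closely related
monoecious (hermaphroditic) outgroup. The three key quantities, for each
XY gene pair, are:

* **mX** — expression of the X allele in males,
* **mY** — expression of the Y allele in males,
* **fXX** — total (two-copy) X expression in females.

Under *no* compensation and no Y decay, each allele is expressed at the
same per-copy rate, so the null expectation is

$$ \frac{mX}{fXX} = \frac{mY}{fXX} = \tfrac12, \qquad
   \frac{mX + mY}{fXX} = 1 . $$

Departures are informative in both directions: `mY/fXX < 0.5` indicates
Y degeneration; `mX/fXX > 0.5` indicates up-regulation of the male X,
i.e. gene-level dosage compensation.

## Pipeline overview

`run_pipeline()` chains the following stages; each is exported and
individually testable.

1. **Expression filter** (`filter_expressed()`): keep genes whose TPM
   exceeds a strict threshold (default 1) in at least one sample.
2. **Outgroup calibration** (`calibrate_by_outgroup()`): divide each
   focal gene's TPM by its one-to-one ortholog's TPM in the
   tissue-matched outgroup sample. This converts absolute expression
   into a ratio relative to the ancestral (pre-sex-chromosome) state,
   controlling for gene-specific expression level.
3. **Regional summaries** (`region_summary()`): per sample, compare
   sex-linked versus autosomal calibrated expression by both
   ratio-of-medians and ratio-of-means, with a Wilcoxon rank-sum test.
   `percent_reduction()` expresses the male deficit relative to females.
4. **Diagnostic SNPs** (`snps_from_alignment()`, `validate_snps()`):
   sites where the X and Y coding sequences differ are candidate
   diagnostic SNPs. A site is *validated* only if every female genotype
   is homozygous reference (X/X) and every male genotype is
   heterozygous (X/Y) — the segregation pattern forced by strict
   X/Y linkage.
5. **Allele read counting** (`count_allele_reads()`): per sample and
   gene, sum reference (X) and alternate (Y) read depths over validated
   SNPs inside the annotated ORF only, and record the number of sites.
6. **Normalization** (`tmm_factors()`,
   `normalize_allele_expression()`): allele expression is
   `reads / n_snps / (library_size × TMM factor) × 1e6`, i.e. depth per
   diagnostic site scaled to a common effective library size. TMM
   factors are computed on the full gene-level count matrix (see below).
7. **Ratios and classification** (`compute_ratios()`,
   `classify_gene()`): per tissue and per gene (median across tissues),
   form `mX/fXX`, `mY/mX`, `(mX+mY)/fXX`; classify each gene as
   `compensated` (`mX/fXX ≥ 0.9`), `partial` (`≥ 0.75`), or
   `uncompensated`.
8. **Distributional evidence** (`ratio_density_peaks()`): kernel density
   of the per-gene ratios; the mode locations are the population-level
   readout (a mode at 0.5 means most genes are uncompensated; a
   secondary mode near 0.7 reveals a partially compensated
   subpopulation).
9. **Evolutionary context** (`strata_compare()`, `ks_correlation()`,
   `silenced_fraction()`): compare ratio distributions across
   evolutionary strata (older versus younger inversions versus
   collinear region), correlate per-gene ratios with synonymous
   divergence (Ks) as a proxy for time since recombination stopped, and
   report the silenced fraction of X-specific (Y-absent) genes.

## Why each numerical choice

**TMM normalization, implemented in-package.** The trimmed mean of
M-values is the standard between-library scaling for count data. It is
re-implemented here (rather than imported) because the primitive is
central to the method: factors are computed from pairwise log-ratios
(M) trimmed 30% on each side and log-abundances (A) trimmed 5%, with
inverse-variance precision weights, against a reference library whose
upper-quartile expression is closest to the mean. Factors are rescaled
to geometric mean 1. The implementation is cross-checked against
`edgeR::calcNormFactors()` to 1e-10 in the test suite (edgeR is only a
`Suggests` dependency for this check).

TMM assumes most genes are unchanged between libraries. Sex-linked
genes violate this in males (reads split between X and Y alleles), so
the factors must be computed on the *full* gene-level matrix in which
autosomes dominate — not on the sex-linked subset. The simulator's
default of 2000 autosomal genes against ≤ 45 sex-linked pairs exists
precisely so this assumption holds, as it does in real genomes where
sex-linked genes are well under 1% of the transcriptome.

**Kernel density peaks.** `ratio_density_peaks()` uses a Gaussian
kernel with Silverman's rule-of-thumb bandwidth (`bw.nrd0`) on ratios
clipped to [0, 2] (ratios beyond 2 are biologically implausible and
would only stretch the support). Strict local maxima — plus the support
boundaries when the density increases into them — are reported, with
locations rounded to a 0.1 grid. The rounding acknowledges the true
resolution of the estimate: with per-gene ratio standard errors of
0.03–0.05 (see the noise budget below), reporting a mode as 0.51 versus
0.49 would be false precision, whereas 0.5 versus 0.7 is a real
distinction. A minimum of 20 finite ratios is required; a constant
vector is reported as a single point mass rather than fed to the KDE.

**Classification thresholds.** Full compensation is `mX/fXX ≥ 0.9`
rather than `≥ 1.0` so that sampling noise around a truly compensated
gene (true ratio 1.0, SE ≈ 0.05) does not misclassify it; `0.75` marks
the midpoint band between the null (0.5) and full compensation. Both
thresholds are arguments, not constants.

**Statistical tests.** Group comparisons use the Wilcoxon rank-sum test
(exact when the pooled size is ≤ 20 and tie-free, normal approximation
with tie and continuity correction otherwise); ratio–Ks association
uses Spearman's rank correlation. Both are deliberately nonparametric:
calibrated expression ratios are heavy-tailed and the analyses should
not depend on a distributional form. Pairwise strata comparisons are
Holm-adjusted. Global male–female agreement is summarised by Pearson
correlation of `log10(TPM + 0.01)` (the pseudocount keeps zeros finite
while barely moving expressed genes) and by Spearman correlation of the
raw values.

## The synthetic-data generator

`simulate_dataset()` produces a complete study with known truth: focal
TPM and counts for both sexes across tissues, outgroup TPM, X/Y coding
alignments, per-SNP allele depths, a genotype VCF, gene annotation with
strata and Ks, and a truth table with each gene's expected ratios.

The generative model, per gene:

* A baseline per-allele transcription rate is drawn log-normally
  (`meanlog = log(30)`, `sdlog = 1`), shared by all alleles of the gene
  and by the outgroup ortholog — this is what outgroup calibration
  cancels.
* Y alleles express at `y_decay` times the X rate (per stratum;
  1 = intact Y). A fraction `compensation_frac` of pairs up-regulate
  the male X by `compensation_factor`.
* Counts are negative binomial with mean
  `rate × allele_copies × library_size / 1e6` and dispersion 0.1
  (Poisson when 0); females draw two independent X-allele variables.
* Per-SNP allele depths use the same model at `snps_per_gene` sites
  (Poisson mean 10, truncated at ≥ 1).
* X-specific genes (no Y ortholog) are silenced with probability
  `frac_silenced_x_specific`.

A `noiseless = TRUE` switch returns the expected values instead of
random draws, which the test suite uses to verify the ratio arithmetic
exactly before testing stochastic convergence.

**Noise budget.** The default design (2 tissues × 4 replicates per sex,
~10 diagnostic SNPs per gene, median per-SNP depth ~30) gives each gene
roughly 2400 informative reads per sex, hence a per-gene ratio standard
error of about 0.03–0.05 after the median across tissues. That is the
scale needed to resolve density modes 0.2 apart — the generator is
calibrated so the *designed* study can answer the question, not so that
any study can.

**What the generator does not emulate.** It produces summary-level data
(counts and per-site depths), not reads: there is no read mapping, so
no reference/mapping bias toward the X allele, no multi-mapping between
X and Y gametologs, and no isoform structure. Genotypes are error-free,
so `validate_snps()` failures must be injected manually to be tested.
Library sizes are fixed rather than drawn. These simplifications bias
real data toward *underestimating* mY (Y reads lost to mapping bias);
results on real alignments should treat the Y-side estimates as lower
bounds.

## Reproducibility

All stochastic behaviour flows from a single integer seed in
`sim_config()`; the same seed yields byte-identical datasets. The
analysis itself is deterministic. `run_pipeline()` records every stage,
parameter, and output in `run.log` and `summary.json` when given an
output directory.

```{r example, eval = FALSE}
library(dosecomp)
ds  <- simulate_dataset(sim_config(seed = 1))
res <- run_pipeline(dataset = ds, out_dir = "results")
res$peaks$mx_fxx$peaks   # density modes of per-gene mX/fXX
res$reduction            # male expression deficit, % per tissue
table(res$classification$label)
```

## Limitations

* Outgroup calibration assumes the ortholog's expression is the shared
  ancestral state; lineage-specific expression evolution in the
  outgroup propagates directly into the calibrated ratios.
* Diagnostic-SNP validation requires strict X/Y linkage; genes in
  recombining pseudoautosomal regions will fail validation (correctly)
  and drop out of the allele-specific analysis.
* fXX is estimated from female depths at the same diagnostic sites, so
  genes whose X and Y sequences are identical (no SNPs) are invisible
  to the allele-specific stages, biasing the analysed set toward more
  diverged — typically older — gene pairs.
* KDE mode locations are reported on a 0.1 grid; effects smaller than
  the grid require the per-gene ratio tables, which are always
  returned.
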