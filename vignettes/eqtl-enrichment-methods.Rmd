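---
title: "Methods: MAF-matched eQTL enrichment and the eQTL function score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAF-matched eQTL enrichment and the eQTL function score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlenrich)
```

## The problem

SNPs reproducibly associated with complex human traits are, as a set,
peculiar: they are strongly shifted toward common alleles relative to the
genotyping platforms they were discovered on, because GWAS power rises with
minor allele frequency (MAF). eQTL detection power rises with MAF for the
same reason. Any claim that "trait-associated SNPs are enriched for eQTLs"
is therefore confounded by frequency unless the null model is conditioned
on it. This package implements that conditioned test, a per-SNP eQTL
evidence score built on it, and the bin-series displays used to show that
the score prioritizes GWAS signals.

The pipeline consumes finished summary tables — a trait-SNP catalog, a
SNP-by-transcript eQTL p-value extract, gene coordinates, a SNP panel with
MAFs, GWAS summary statistics and a pairwise r² table. It does not map
eQTLs from expression data; the extract it expects is already truncated
(cis rows stored only below 0.01, trans rows only below 10⁻⁴), which is how
such databases are distributed, and the methods are designed around that
truncation rather than pretending the full matrix exists.

## The MAF-matched resampling null

`assign_maf_bins()` partitions [0, 0.5] into bins of width 0.05 — ten
bins, each covering `[k·0.05, (k+1)·0.05)` with the final bin closed at
0.5. Edge handling is a convention the data sources never state; half-open
lower-inclusive bins are the least surprising choice and are pinned by
tests. Bins are built on the pooled platform panel (not per platform);
restricting the pool to one platform is just a different input panel.

`matched_sample()` draws each replicate so that *every* bin contributes
exactly the target's count, uniformly without replacement within the
replicate. Replicates are independent fresh draws: SNPs recur across
replicates. Each replicate runs on its own RNG substream (a seed vector
derived from the user seed), so replicate *i* is reproducible regardless of
how many replicates are requested or in what order they are evaluated.

`enrichment_test()` counts eQTLs — SNPs whose smallest association p-value
is strictly below the threshold — in the target and in each replicate. The
empirical p-value is the proportion of replicates whose count *strictly
exceeds* the observed count, with no +1 smoothing; its granularity is
1/`n_reps`, a value of 0 is printed as "< 1/n_reps", and the tests verify
that on single-bin pools the null counts follow the exact hypergeometric
law this scheme implies. SNPs with undefined MAF are excluded from both
pool and target with a message; a pool bin smaller than its target bin is
an explicit infeasibility error naming the bin.

Founder-only allele frequencies (`founder_allele_freq()`) exist because
panel MAFs are often computed from family data: children's alleles are
copies of their parents', so only pedigree founders enter the count, and
SNPs with no non-missing founder genotype are excluded rather than given a
made-up frequency.

## cis/trans classification and the function score

A SNP is *cis* to a gene when it lies on the same chromosome within 4 Mb of
the gene's boundaries (distance zero inside the gene); the boundary is
inclusive. Everything else is *trans*. The 4 Mb window is deliberately
generous — it is the window within which the cis Bonferroni denominator
N_c counts transcripts.

`summarize_eqtls()` produces, per SNP: p_c (smallest cis p-value, kept only
below the cis truncation), p_o (smallest p-value among truncation-surviving
rows, cis or trans — the overall minimum, not a trans-only minimum), N_c
and N_o. By default N_c counts all annotated genes in the SNP's window,
association or not, because it stands for the number of cis tests
performed; `cis_mode = "observed"` counts only genes with a stored
association row, for extracts where the annotation is unavailable.

The score is

S = max(0, −log₁₀(min(1, p_c·N_c)), −log₁₀(min(1, p_o·N_o)))

with N_o the total transcript count of the underlying study (13,080 for the
LCL exon-array tables this was designed around). This is the one-parameter
family realizing the stated requirements — separate Bonferroni corrections
for the cis and overall signals, truncation at zero, a single ranking
dimension, and the interpretability property that S > 3 if and only if some
corrected p-value is below 10⁻³. A missing signal contributes zero rather
than NA so the score is total over the panel. Monotonicity (better p never
lowers S, more tests never raise it) is property-tested.

Master regulators are SNPs with at least `n_targets` *distinct* target
transcripts at a threshold (counting transcripts, not association rows);
the threshold set must be declared when summaries are built so the counts
are computed once.

## LD pruning and subgroup comparison

`ld_prune()` is greedy: walk the SNPs, keep each unless it has r² >
threshold (default 0.3) with an already-kept SNP; absent pairs count as
unlinked. The result is independent and maximal, both verified exhaustively
on random graphs. Which SNP of a correlated set survives depends on the
walk order, which is exactly why `pruned_enrichment()` randomizes the order
over (by default) 100 prunes and reruns a 100-replicate enrichment test on
each, with MAF bins recomputed from each pruned set — the distribution of
empirical p-values over prunes is the robustness statement.

`subgroup_chisq()` compares eQTL rates between two disjoint SNP subgroups
with a Pearson 1-df chi-square on the 2×2 table, without continuity
correction — the uncorrected form is what reproduces the published worked
example this test is validated against (17/259 vs 29/1339 giving
p ≈ 1.1×10⁻⁴). Degenerate tables (a zero margin) return statistic 0 and
p 1 with a warning instead of NaN.

## GWAS bin series

`qc_filter()` keeps records with missingness strictly below 5%, MAF at or
above 1% (the boundary keeps), and a non-empty rsid. Intensity-based
clustering QC requires raw data and is out of scope.

`score_bin_series()` ranks SNPs by score descending, `assoc_bin_series()`
by association p ascending; both break ties by rsid so the series is a
deterministic function of the data, and permuting input rows changes
nothing. Bins are consecutive groups of `bin_size` (default 10,000); a
partial final bin is kept, flagged, and its expectation scaled to its
actual size. Truncating the display to the first bins is a plotting option
(`autoplot(x, max_bins = )`), not a data decision. The expectation line
uses the sub-threshold proportion over all ranked SNPs by default;
`expectation = "remaining"` recomputes it per bin from the SNPs outside
that bin, for users who prefer the leave-one-bin-out version.

The 95% bands are empirical 2.5/97.5 percentiles of `n_sims` (default 100)
simulated per-bin counts. For the score-ordered series the simulated draws
are MAF-matched to each bin's SNPs, because a high-scoring bin is
frequency-biased and an unmatched band would be too narrow; for the
association-ordered series the draws are unmatched draws from the full
score list. The simulation draws counts, not SNP identities: within each
MAF bin the number of sub-threshold p-values in a without-replacement draw
is hypergeometric, and the bins partition the pool and are drawn
independently, so summing per-bin hypergeometric draws gives exactly the
law of the full matched draw. Empirical-quantile bands from 100 draws of a
discrete count cover the truth slightly off-nominal (≈ 0.94 in the
package's own coverage test, which accepts 0.95 ± 0.03); users wanting
tighter bands can raise `n_sims`.

`cis_trans_split_series()` reruns the score-ordered series ranking on the
cis or trans score component alone, and `exclude_chromosome()` supports the
standard chromosome-6 sensitivity analysis for phenotypes where extended
MHC LD could carry the whole signal.

## The synthetic generator

`generate_world()` builds the full input suite with known truth. What it
emulates, and why:

- **MAF spectrum**: panel MAFs are 0.5·Beta(0.7, 1.3) — a decreasing
  density over [0, 0.5], most SNPs uncommon. With `maf_bias` > 0 the
  catalog is drawn with weight ∝ maf^maf_bias, reproducing the
  common-allele shift of real catalogs that makes MAF matching necessary
  in the first place.
- **Planted eQTLs**: a fraction `f_cis_eqtl` (default 0.2) of SNPs get ≥ 1
  cis association with p ~ Beta(0.1, 1), the standard tractable
  alternative for p-value distributions; a small fraction (`f_master`,
  default 2%) are multi-target hotspots whose target count makes them
  master regulators at the default definition. All other pairs are
  Uniform(0,1) noise, *emitted only below the storage truncations* by
  binomial thinning — the generator never enumerates the full SNP×gene
  matrix, and its output has the same truncated shape as a real extract.
- **Catalog enrichment**: selection weight ∝ (`rho` if true eQTL else 1) ·
  maf^`maf_bias`. `rho = 1` is an exact null; the package's calibration
  test runs 200 such null worlds and checks the empirical p-values against
  Uniform(0,1) by Kolmogorov–Smirnov.
- **GWAS coupling**: `n_true_trait` SNPs get p ~ Beta(0.01, 1), drawn with
  weight `kappa` on true eQTLs; `kappa = 1` decouples score from
  association. A small fraction of records get blanked rsids and
  Beta-distributed missingness so QC has something to do.
- **LD**: block-constant r² (default 0.8 within blocks of 5 consecutive
  SNPs, 0 between). This exercises every pruning contract; it does not
  model r² decay with distance, multi-locus LD, or realistic recombination
  maps, and conclusions about those do not transfer.

What passing on synthetic worlds does *not* show: real catalogs mix study
designs, platforms and ancestries; real eQTL p-values are correlated across
transcripts and SNPs (the generator's are independent given truth); real
LD is not block-constant; and LCL expression is a poor proxy for many
disease tissues. The generator validates the statistics, not the biology.

## Numerical and design choices

- Threshold comparisons: eQTL calls use strict `<`; master-regulator
  target counts use inclusive `≥`; the 4 Mb window and the 1% MAF QC bound
  are inclusive; missingness is strict `<`. Each boundary is pinned by a
  unit test.
- Empirical p-values use strict exceedance with no smoothing; 0 means
  "below 1/n_reps".
- Ties in rankings are broken by rsid; ties in `ld_prune()` by walk order,
  randomized under the outer loop.
- `targets_at` thresholds are keyed by a canonical text rendering of the
  numeric threshold, so lookups cannot silently mismatch on floating-point
  noise; requesting a threshold the summaries were not built with is an
  error, not a recomputation.
- Degenerate inputs: empty catalog files are empty tibbles, not errors;
  empty function classes return NA (0/0 is undefined, not zero); zero
  chi-square margins return statistic 0 with a warning; SNPs with no
  founder genotypes or no MAF are excluded and logged.
- Test problem sizes were chosen to make each statistical check decisive
  at small cost: 200 null worlds of 3,000 SNPs for calibration, 100 worlds
  of 20,000 SNPs (catalog 500, `rho` = 3) for power — the planted effect
  there is large enough that recovery at empirical p < 0.01 in ≥ 95% of
  worlds is expected with margin — 6,000 replicates against the
  closed-form hypergeometric, 500 worlds of 8,000 SNPs for band coverage,
  and 1,000 random graphs for the pruning contracts.

## Limitations

The score's closed form treats p_o with the full N_o correction even when
p_o comes from a cis pair already corrected by N_c; this is conservative
for the trans component and matches the "overall minimum" definition of
p_o. The pipeline deliberately has no analytic approximation to the
resampling null, no LD-aware matching (matching is on MAF only), and no
multiple-testing correction of GWAS p-values — the bin series are displays
of excess, not significance tests per SNP.
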