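---
title: "Methods: chromatin-transcriptome integration in chromexpr"
author: "chromexpr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-transcriptome integration in chromexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromexpr)
```

This vignette explains the models and procedures behind `chromexpr`, the
choices made where the design was genuinely open, and what the synthetic
benchmark does and does not demonstrate about real data.

## Coverage normalization and smoothing

ChIP-seq enters as per-base-pair coverage (bedGraph). Libraries are made
comparable by counts-per-million scaling: every value is multiplied by
10^6^ / total mapped reads. The total is metadata carried with the track
(sequencing-run read counts), never inferred from the coverage integral,
because coverage mass depends on read length and trimming while the CPM
definition does not.

Smoothing averages a 100-bp window slid in 10-bp steps, producing one
value per 10-bp bin in a single pass. Two conventions needed fixing that
the CPM/window definitions leave open:

* **Anchoring.** Bin *i*'s window is `[i*step, i*step + window)` —
  left-anchored at the bin origin, so a bin's coordinate is a genomic
  coordinate. Centered windows would shift all downstream positions by
  half a window; either choice is defensible, but left-anchoring keeps
  the sgr output coordinates interpretable without an offset.
* **Edges.** Windows running past the chromosome end are truncated and
  averaged over covered bases only. Zero-padding instead would bias
  subtelomeric bins downward — exactly where H3K9me3 matters — so
  truncation is the safer default.

Mass is conserved when `step == window` (the bins tile the chromosome),
and smoothing is linear in the track, both of which are enforced by
property tests against a brute-force windowed-mean oracle.

## Gene windows and metagene profiles

Genes are annotated with 0-based half-open coordinates (GFF3 input is
converted on read). Windows are defined in *gene orientation*: the ATG
window covers 500 bp of promoter/5′UTR and 1500 bp of coding region; the
stop-codon window covers 1500 bp of gene body and 500 bp downstream, used
for the 3′-biased H3K36me3. One axis convention is used for both anchors:
negative offsets are 5′ of the anchor, positive offsets 3′ of it, and
minus-strand windows are reflected so position 0 is always the gene's own
anchor base. (Plots of stop-anchored data can simply be read right to
left when the gene body should appear on the right.)

Window bins (10 bp) are averaged from per-bp signal *in the gene frame*,
not sampled from genome-frame bins. This makes the gene-window matrix
exactly invariant under mirroring the whole genome (coordinates and
strands flipped), a property the test suite checks bit-exactly; sampling
genome-frame smoothed bins would break the symmetry by up to one bin.

Bins extending past a contig end are masked, excluded from profile
averages, and genes with more than 50% of their window masked are flagged
and excluded from threshold classification rather than silently scored as
low-signal.

Per-gene mark levels come in two flavors: the window-mean CPM (the
operational "average CPM from −500 to +1500" quantity) and an RPKM-style
measure, reads overlapping the ORF × 10⁹ / (total mapped reads × ORF bp),
with reads reconstructed from raw coverage as coverage/read-length
(fractional reads allowed). The low/high split threshold (log2 level 5
for H3K4me3, 2 for H3K36me3) is applied to the window-mean CPM by
default; the boundary value goes to the low tier (the split is defined as
"≤ threshold"). log2 transforms add a pseudocount of 0.01 × the
genome-wide nonzero median, which preserves ranking while keeping zeros
finite; the constant is configurable and matters only below the 1st
percentile of signal.

## Differential expression

The DE stage is a self-contained, documented equivalent of the standard
voom/limma-style workflow — the package deliberately defines the
algorithm rather than delegating to a library, so its behavior is fully
specified by this section:

1. **TMM factors.** Reference sample = the one whose upper-quartile of
   library-scaled counts is closest to the mean upper-quartile. For each
   sample, per-gene log2 ratios *M* and abundances *A* are computed over
   genes nonzero in both sample and reference; the top/bottom 30% by *M*
   and 5% by *A* are trimmed (rank rule), and the factor is 2 to the
   inverse-variance-weighted mean of the surviving *M* (delta-method
   binomial variances as weights). Factors are rescaled to geometric
   mean 1. The implementation reproduces edgeR's `calcNormFactors`
   to ~1e-9 on random matrices (a Suggests-only cross-check).
2. **log2-CPM.** `log2((count + 0.5) * 1e6 / (TMM-effective library + 1))`;
   the 0.5 prior count keeps zeros finite and shrinks low-count ratios.
3. **Moderated t.** Per-gene pooled two-group variance (df = n₁+n₂−2) is
   shrunk toward an abundance trend: a lowess fit (span 0.5) of the
   bias-corrected log variances against mean log2-CPM gives the prior
   location; the prior degrees of freedom d₀ come from a moments fit
   (excess spread of log-variances over the trigamma(df/2) sampling
   floor, inverted through trigamma). The posterior variance is the
   d₀/df-weighted compromise, and p-values are two-sided t with df + d₀
   degrees of freedom. With fewer than 10 informative genes (degenerate
   inputs) the trend is skipped and raw variances with a small floor are
   used — all-zero or copied samples then yield log2FC 0 and p 1, never
   NaN.
4. **Multiple testing.** BH step-up via `p.adjust`; a test verifies it
   against an independently coded step-up.

Calibration is checked empirically: across ≥20 null simulations of 2000
NB genes the mean fraction of p < 0.05 must land in [0.035, 0.065], and
p-values are near-uniform (KS < 0.05). Planted 4-fold effects at
adequate depth are recovered with median log2FC within ±0.25 of 2.

Three named threshold profiles are shipped, all requiring at least a
4-fold change: `fdr01` (FDR < 0.01), `fdr005` (FDR < 0.005, used for the
mark-by-expression group split) and `fdr05` (FDR < 0.05, used for the
category-deregulation tables). Boundary rules are exact: calls require
|log2FC| ≥ 2 and FDR strictly below the cut.

## Integration

* **Groups.** The low/high H3K4me3 tier crossed with the DE call yields
  G1–G4 (active growth) or G5–G8 (nutrient limitation): odd groups need
  the regulator for expression (up in WT), even groups are repressed by
  it; low-mark groups come first. Group labels exist only for genes with
  both a tier and a significant call, so the four groups partition the
  DE-called, tiered genes — a pipeline-level consistency test.
* **Enrichment.** Category over-representation uses the exact upper-tail
  hypergeometric (one-sided Fisher). One-sided is the standard choice
  for "is the category enriched"; the two-sided Fisher variant and a
  custom universe (all genes vs. categorized genes) are exposed as
  options since different universes change the tail only marginally at
  these sizes.
* **Category summaries.** Medians/quartiles per category, with a
  two-sided Mann–Whitney test between categories — a deliberately
  assumption-light comparison, since mark-level distributions are
  long-tailed mixtures.
* **H3K9me3 domains.** Broad-domain calling is threshold-based: bins at
  or above the threshold (default 4 × the genome-wide nonzero median
  CPM, robust to the euchromatic background level) form runs, runs
  closer than 500 bp merge, and domains shorter than 2 kb are dropped.
  A cluster is "flanked" on a side when the gap between its outermost
  gene coordinate and the nearest domain edge is ≤ 5 kb. All four
  parameters are configurable; the defaults were chosen once to match
  the simulated block geometry (5-kb rectangles) and the visual scale at
  which such flanking is usually judged, and the flanking classification
  is mirror-invariant by construction.

## PTM stoichiometry

Peptide-form tables carry relative abundances per site and strain.
Composite peptides (K9/K14; K27/K36) keep their joint form labels — the
data do not determine per-residue marginals, so no deconvolution is
attempted. Fractions are renormalized to sum to 1 (percent- and
fraction-scale inputs both accepted); total methylation is the me1+me2+me3
share; strain effects are reported both as percentage-point and relative
changes, since both conventions appear in the literature and differ by an
order of magnitude for rare forms.

## The synthetic benchmark

The generator plants, under one master seed (all randomness flows through
per-operation child seeds, so outputs are byte-reproducible and adding a
stage never perturbs another):

* a 2-chromosome × 600-kb genome with 400 non-overlapping genes
  (900–2400 bp) on both strands — large enough for stable category
  statistics, small enough that the full test suite and acceptance run
  finish in minutes on one CPU;
* 4 SM clusters of 8 contiguous genes (32 SM vs. 368 CSF genes, the
  small-category/large-background structure), half of them flanked by
  5-kb H3K9me3 blocks, with additional blocks at every chromosome end;
* per-mark coverage kernels scaled by a 3-level expression tier
  (SM genes are low-tier): H3K4me3 as a Gaussian at +250 bp (σ = 150)
  from the ATG, H3Ac at +75 (σ = 75), H3K36me3 as a linear 5′→3′ ramp,
  on a uniform Poisson background (λ = 1, peak amplitude 20 for a
  mid-tier gene); the mutant loses active-mark signal over its
  down-regulated genes;
* NB counts (dispersion 0.05, log-normal baselines around tier means
  50/400/2000, ~2×10⁶ reads/sample) with planted |log2FC| = 2 effects:
  5% of CSF genes per direction, and 65% down / 15% up among SM genes in
  the nutrient-limited condition;
* Dirichlet-noised peptide-form tables (concentration 200) around fixed
  true stoichiometries in which the mutant gains H3K4me3 at the expense
  of lower methylation states.

What passing on this benchmark shows: the coordinate arithmetic, strand
handling, normalization formulas, test calibration and the integration
logic are correct, and effects of the planted size at the planted depth
are recovered. What it does not show: robustness to mappability gaps,
GC/fragment-length bias, antibody efficiency differences between
samples, overdispersion beyond NB, peptide co-elution — none of which the
generator emulates. Conclusions about real data still require the usual
QC on those axes.

Two statistical design points deserve explicit mention. First, recovery
of planted fold-changes to tight tolerances is tested at 4+ replicates
per group; at 2 vs 2 the sampling spread of a 4-fold effect at depth 500
(sd ≈ 0.33 log2 units) makes per-simulation interval guarantees
unattainable regardless of estimator. Second, stoichiometry recovery to
±1.5 pp estimates fractions as the mean of 40 replicate Dirichlet draws:
a single draw at concentration 200 has a per-form sd of up to ~3.5 pp by
the Dirichlet moments, so replication, not a quieter noise model, is the
honest route to that precision.

## Running end to end

```{r, eval = FALSE}
rep <- run_demo(seed = 2, out_dir = "demo_report")
```

`run_pipeline()` validates its configuration before computing, aborts
with the stage name on any failure, and (given `out_dir`) writes every
result table as TSV plus a parameter log, so any stage can be inspected
or re-run from its plain-text intermediates.
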