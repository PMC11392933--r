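---
title: "Annotating GWAS loci with single-cell multiome data: models and methods"
author: "mgatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating GWAS loci with single-cell multiome data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgatlas)
```

# Overview

`mgatlas` annotates GWAS risk loci with barcode-shared single-nucleus ATAC
and RNA data from a heterogeneous tissue. The pipeline runs in seven
stages, each exposed as exported functions and orchestrated by
`runPipeline()`:

1. **CCV selection** — per-locus candidate causal variants by a
   log-likelihood-ratio band around the lead variant and an LD rule.
2. **cCRE atlas** — per-cell-type peak detection, genomic-context
   annotation, single-cell-type specificity, and a quantile-based
   category assignment.
3. **Colocalization** — CCVs against cCREs under explicit coordinate
   conventions.
4. **Trait relevance** — per-cell enrichment of accessibility at
   CCV-weighted peaks, propagated over a cell-similarity network.
5. **Allelic TF analysis** — position-weight-matrix scoring of both
   alleles, abundant-TF assessment, and Tn5 footprinting.
6. **cCRE-gene linkage** — co-accessibility, modules, background-corrected
   peak-gene links, and a six-level evidence hierarchy.
7. **Variant functional score** — an additive 1-4 score per colocalized
   CCV, plus locus summaries.

A synthetic multiome generator with planted, machine-readable ground truth
(`simConfig()`, `generateDataset()`) makes every stage testable end to end
without external data.

# Statistical models and rules

## CCV selection

For a locus with lead z-score $z_\ell$, a variant with z-score $z_v$ is
kept when the likelihood ratio of the two association models under the
normal approximation stays within $1{:}1000$:
$$\exp\!\big((z_v^2 - z_\ell^2)/2\big) \ge 10^{-3}
  \iff z_\ell^2 - z_v^2 < 2\ln 1000 \approx 13.8155,$$
or when its LD with the lead satisfies $r^2 \ge 0.8$. The lead itself and
declared conditional-signal leads are always kept; each variant is
reported once with the strongest applicable reason
(lead > conditional > llr > ld). The $r^2$ boundary is inclusive by
default and exposed as `r2Inclusive`; an `ld_only` mode reproduces
replication-stage selections that do not use the LLR band. When only
p-values are available the z magnitude is recovered by the inverse normal
transform of the two-sided p-value.

## Category specificity of cCREs

Peaks detected in a single cell type are specific to it; peaks whose
detecting types all fall in one of the four categories (epithelial,
immune, endothelial, stromal) are assigned that category directly. A peak
spanning several categories is attributed to category $g$ (of $n_g$ cell
types) when its detected count $c_g$ strictly exceeds the expected 75th
percentile, $c_g > 0.75\,n_g$ — for the default sizes $(8, 7, 4, 4)$ the
strict thresholds are $(6, 5.25, 3, 3)$, i.e. at least $(7, 6, 4, 4)$
detected types. Several categories may qualify simultaneously; none
qualifying leaves the peak "shared". The 25th percentile plays no role in
assignment: the rule is anchored on its only worked example, and a
depleted-in-category annotation can be derived separately if wanted.

Peak detection on the provided count matrix uses a fraction threshold —
peak $j$ is detected in type $t$ when at least
$\max(\texttt{minCells}, \texttt{minFrac}\cdot n_t)$ of its $n_t$ cells
carry a nonzero count (defaults 10 cells / 2%). De novo peak calling is
out of scope; this rule substitutes for a per-type peak caller on data
that already carry a peak set.

## Genomic context and gene activity

Context labels follow the priority promoter > exonic > intronic >
intergenic, with the promoter window symmetric around the TSS
($\pm 3000$ bp regardless of strand). Gene activity per cell sums
accessibility over the strand-aware window from 2000 bp upstream of the
TSS through the TES, from either the peak-count matrix or a fragment
file.

## Trait relevance score

Each locus carries one unit of probability split evenly across its CCVs;
a peak's trait weight is the sum of the contributions of the CCVs inside
it. A cell's observed score is its depth-normalized weighted
accessibility (depth = number of open peaks). The null uses 50 background
peak sets matched to the trait peaks by nearest neighbours in
standardized (GC content, mean accessibility, peak width) space; the
z-score against that null is the raw trait score. Scores are then
propagated over a mutual kNN graph ($k = 30$) built on a TF-IDF +
truncated-SVD (LSI) embedding with the first, depth-correlated component
dropped: the top 5% of cells by raw score seed a restart random walk
(restart 0.05, iterated to $\|\Delta\|_\infty < 10^{-6}$), and the
stationary distribution is rescaled to mean 1. Propagation runs on the
largest connected component; cells outside it keep their raw-score rank
percentile and are flagged. The propagation hyperparameters are choices
of this package (the seed proportion is the only one fixed by the
upstream method) and all are exposed as arguments.

## Allelic TF binding

A window of motif width scores
$s = \sum_{p} \mathrm{ic}_p \cdot P(\text{base}_p)$, min-max normalized
to $[0,1]$ by the motif's worst/best attainable IC-weighted sums, best
over both strands and all offsets. The motif-match p-value is the
probability that a background window scores at least as high — exact by
enumeration of all $4^w$ windows for widths up to 10, Monte Carlo with
$10^5$ seeded draws otherwise, cached per motif. A variant is allelic for
a TF when $|s_\mathrm{alt} - s_\mathrm{ref}| > 0.7$ and the better
allele's match has $p \le 10^{-4}$ (the stated maximum p-value is read as
$10^{-4}$, since a p-value cannot exceed 1). A TF is *abundant* in a cell
type when it is expressed in more than half of the type's cells and its
log-normalized mean expression exceeds the 75th percentile (type-7,
linear interpolation) over all predicted (TF, cell type) pairs; the mean
is over all cells of the type.

## Footprinting

Fragment cut sites (both fragment ends) are aggregated around motif
centres over $\pm 250$ bp, normalized to mean 1 over the outer flank
($200 \le |d| \le 250$), and corrected by subtracting the expected Tn5
profile — by default the flat outer-flank expectation, optionally a
positional bias vector. Detection replaces the upstream method's visual
judgement with an explicit rule: flank enrichment
($\text{mean corrected}, 20 \le |d| \le 100$) of at least 0.05 *and* a
centre ($|d| \le 10$) at least 20% below the flank. Profiles with fewer
than 20 motif occurrences within the cell type's detected peaks are
returned with an insufficient-data flag and never called.

## cCRE-gene linkage

Cells are aggregated into disjoint metacells of $k = 50$ nearest
neighbours in the LSI embedding (components 2-30). Co-accessibility is
the Pearson correlation of aggregated counts for peak pairs within
500 kb. This is a deliberate, documented divergence from the
distance-penalized graphical-lasso co-accessibility of the original
toolchain: the contract (symmetric, bounded score on distance-limited
pairs) is preserved and the 0.32 module / 0.5 direct cutoffs are applied
to this score as configuration defaults. Modules are Louvain communities
(seeded, ties renumbered by lowest peak coordinate) of size at least two
on the graph of pairs scoring $\ge 0.32$.

Peak-gene links correlate accessibility with expression for peaks within
$\pm 1$ Mb of the TSS ($\pm 2$ and $\pm 5$ Mb variants available), with a
null built from 200 background peaks matched on (GC, mean accessibility,
width) — the three bias covariates named by the upstream method, with
nearest-neighbour matching as this package's mechanism. Links with
one-sided $p < 0.05$ (positive-regulation direction; two-sided by flag)
and $|r| > 0.05$ are retained, subject to a 10-cell minimum for both
features. Six evidence levels connect a CCV-colocalizing cCRE to genes:
(1) a module mate is a promoter cCRE, (2) direct co-accessibility
($\ge 0.5$) with a promoter cCRE, (3) the cCRE itself is a promoter,
(4) a module mate is expression-linked, (5) direct co-accessibility with
an expression-linked cCRE, (6) the cCRE itself is expression-linked.
Every (cCRE, gene) record carries the maximum level and the complete
evidence chain; cCREs linked to several genes are all reported.

## Variant functional score

Only colocalized CCVs are scored. The score adds four indicators:
colocalization (1), any allelic TF (2), an allelic TF abundant in a cell
type detecting an overlapping cCRE (3; the type-matching requirement is
a flag), and an allelic TF with a detected footprint in any cell type
(4; type-agnostic by default, also a flag).

# The synthetic generator

`generateDataset()` plants, on one synthetic chromosome:

* 23 cell types in 4 categories with unbalanced sizes (~4200 cells at
  default scale, epithelial-enriched), per-cell depth factors;
* 5000 peaks with planted detection patterns (40% single-type, a spread
  of 2-10-type and broad patterns, 60% of multi-type patterns drawn
  within one category), Bernoulli presence counts
  ($p_\text{open} = 0.35$ matching / 0.01 non-matching, depth-scaled);
* 1000 genes with negative-binomial expression (log-normal baseline
  means, dispersion 2) and planted peak-to-gene links that multiply the
  mean by 3 in cells where the linked peak is open — the conditioning is
  on per-cell openness, which is exactly the correlation level-6 linkage
  must detect;
* 10 GWAS loci of 50 variants with AR(1) LD ($\rho = 0.9$), causal z
  magnitude 8, and the causal variant placed inside a broad
  trait-category peak that forms a co-accessible trio with two
  same-pattern peaks linked to the locus gene;
* three synthetic motif models planted at footprint sites and at causal
  variants, with allelic variants that disrupt or restore the consensus
  at the maximum-information position;
* Tn5 fragments whose cut sites follow a smooth sinusoidal positional
  bias field, with centre protection (factor 0.2 over $\pm 10$ bp) and a
  flanking occupancy boost (1.5 over $10 < |d| \le 150$ bp) at bound
  sites in bound cell types.

Design notes, in the order the choices arose:

* **Near-binary ATAC.** Accessibility is simulated as Bernoulli presence
  with depth scaling because downstream operations consume detection and
  correlation, not depth.
* **Direct LD.** LD is simulated directly as an AR(1) correlation matrix
  rather than by genotype resampling; downstream only consumes z-scores
  and $r^2$-to-lead.
* **Broad causal-peak patterns.** Causal trio peaks span all but one
  cell type of the trait category, so the strict quantile rule tolerates
  an occasional spurious detection in another category.
* **Motif design.** The synthetic motifs concentrate information content
  at a single core position (the only G of an otherwise A/T consensus),
  and the sequence flanking planted allelic variants is rewritten over
  {A, T}: a single-base substitution then moves the normalized score by
  ~0.9 with an unambiguous best alignment on either strand, while the
  full-width consensus match keeps $p \approx 0.25^w$. This emulates TFs
  whose binding hinges on one core contact; it is the regime in which a
  fixed 0.7 score-difference threshold is meaningful.
* **Footprint occupancy boost.** Beyond centre protection, bound cell
  types receive a flanking accessibility boost; without it, per-type
  flank-enrichment ranking would carry no signal, since profile shape
  would be identical across cell types.
* **TF marker promoters.** Each motif TF gene's TSS sits in a dedicated
  peak accessible in the types where the TF is expressed, so marker
  expression and gene activity co-vary across types.

What the generator does **not** emulate: doublets, batch effects,
ambient RNA, read-level sequences, genotype sampling, overlapping peaks,
trans effects, and realistic motif redundancy. Passing tests therefore
demonstrate that the rules and statistics are implemented correctly and
are calibrated under the stated model — not that the pipeline's defaults
are optimal on real tissue data.

# Numerical choices and degenerate inputs

* Intervals are BED 0-based half-open on disk and `GRanges` 1-based in
  memory; a 1-based variant position $p$ overlaps $[s, e)$ iff
  $s < p \le e$; conversions happen only at parse/serialize boundaries.
* PWM columns are normalized with a pseudocount of 0.8 distributed by
  the background composition; degenerate (non-positive) columns are
  format errors.
* Zero-variance peaks or genes are excluded from correlations and
  recorded as skips; fewer background candidates than requested are used
  in full with a warning.
* Seed-selection ties at the 5% boundary break by cell order; Louvain
  runs under a fixed seed; module ids are renumbered by lowest member
  coordinate; written tables are sorted on stable keys, making pipeline
  output byte-reproducible for a fixed (config, seed).
* The Monte Carlo p-value path derives its RNG stream from the motif
  name and restores the caller's stream, so cached and fresh evaluations
  agree.
* Genes with `tss == tes` are treated as promoter-only windows with a
  warning; fragments with `end <= start` are format errors with line
  numbers; fragments on unknown chromosomes are skipped with a warning.

# Problem sizes used by the test suite

The package's own property suite runs at reduced scale chosen to keep
each check sharp: oracle-equivalence checks use 10,000 random detection
rows, 100 synthetic loci and 200 random linkage instances; link
calibration uses a homogeneous 2,000-cell population over 20 seeds and
recovery an 8,000-cell population (a single cell type makes unlinked
peaks exactly independent of expression, so false-positive accounting is
clean); footprint calibration regenerates fragments 100 times over a
~1,200-cell bundle; trait-relevance recovery runs 100 seeds at 460 cells
with 20 cells per type, where the mutual kNN graph is connected across
types. The full pipeline determinism and recovery checks run a ~1,200
cell, 700-peak configuration (at least 40 cells per type, so every
planted pattern clears the 10-cell detection minimum); `runPipeline(simConfig())` at default
scale (~4,200 cells, 5,000 peaks) takes well under a minute.

# Known limitations

* Co-accessibility is metacell Pearson correlation; on structured data
  the 0.32 cutoff yields large modules, and module-mediated levels (1
  and 4) are correspondingly permissive. The level hierarchy itself is
  unaffected.
* Network propagation is restricted to the largest mutual-kNN component;
  on data with fully separated clusters larger than $k$ this confines
  propagation to one cluster, and cells elsewhere fall back to rank
  scores.
* The abundant-TF percentile depends on the prediction universe supplied
  by the caller; with few predicted pairs the 75th percentile is
  unstable.
* Locus collapsing across studies is deferred to configuration:
  `mergeCcvs()` keeps all locus memberships of a shared variant.
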