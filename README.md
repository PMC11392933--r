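# mgatlas

Cell-type-aware annotation of GWAS risk loci with single-cell multiome
(barcode-shared snATAC + snRNA) data.

Most GWAS risk variants sit in non-coding DNA and act through
cis-regulatory elements whose activity is specific to cell types. Bulk
eQTL and cell-line chromatin data blur those contexts. Given paired
chromatin-accessibility and expression profiles from the same nuclei of a
heterogeneous tissue (the motivating case is normal human lung and lung
cancer risk loci), `mgatlas` answers three questions per locus: *which
variants are plausibly functional*, *in which cell types*, and *through
which target genes*.

The package is written for computational genomicists: it consumes
standard formats (MTX + TSV sidecars, BED, FASTA, JASPAR/MEME motifs,
fragment files, GWAS summary TSVs), keeps data in Bioconductor containers
(`GRanges`, sparse `Matrix`), and ships a synthetic multiome generator
with planted ground truth so the whole pipeline is testable without
controlled-access data.

## The methods in brief

* **CCV selection.** Per locus, candidate causal variants (CCVs) are
  kept when `z_lead² − z_var² < 2·ln(1000)` (a 1:1000 likelihood-ratio
  band under the normal approximation) or `r² ≥ 0.8` to the lead;
  conditional-signal leads are kept as their own class.
* **cCRE atlas.** Peaks (candidate cis-regulatory elements) are detected
  per cell type, labelled promoter/exonic/intronic/intergenic, and
  assigned to cell-type categories by a strict quantile rule: category
  `g` with `n_g` cell types claims a multi-category peak when its
  detected count exceeds `0.75·n_g` (e.g. more than 6 of 8 epithelial
  types).
* **Trait relevance score (TRS).** CCV-weighted accessibility per cell,
  z-scored against covariate-matched background peak sets and propagated
  by a restart random walk (5% seed cells) over a mutual kNN graph of
  the LSI embedding.
* **Allelic TFs and footprints.** Both alleles of each CCV are scored
  against PWMs with an information-content-weighted score normalized to
  [0,1]; a variant is allelic when the score difference exceeds 0.7 with
  a motif-match p ≤ 1e-4. Abundant TFs (expressed in >50% of a type's
  cells, mean expression above the 75th percentile of predicted
  TF-cell-type pairs) and bias-corrected Tn5 footprint profiles add
  cell-type evidence.
* **Six-level cCRE-gene linkage.** Metacell co-accessibility (module
  cutoff 0.32, direct cutoff 0.5, Louvain modules) and
  background-corrected peak-gene correlation (±1/2/5 Mb windows,
  p < 0.05, |r| > 0.05) combine into an evidence hierarchy from
  module-to-promoter (level 1) up to direct expression linkage
  (level 6).
* **Functional score 1-4.** Per colocalized CCV: colocalization + any
  allelic TF + type-matched abundant TF + detected footprint.

See the methods vignette (`vignettes/methods.Rmd`) for formulas,
defaults, design decisions and limitations.

## Worked example

Generate a reduced synthetic study (≈1,000 cells, 1,200 peaks, 4 GWAS
loci) and run the variant-annotation stages:

```r
library(mgatlas)
cfg <- simConfig(cellScale = 0.25, nPeaks = 1200, nGenes = 250,
                 nLoci = 4, variantsPerLocus = 30)
ds  <- generateDataset(cfg, seed = 11)
ds$bundle
#> MultiomeBundle: 1039 cells | 1200 peaks | 250 genes
#>   categories: endothelial=176, epithelial=395, immune=384, stromal=84
#>   cell types: 23

ccvs <- selectCcvsAll(ds$gwas)
table(ccvs$inclusion_reason)
#>   ld lead  llr
#>    6    4    3

atlas <- buildPeakAtlas(ds$bundle)
atlas
#> PeakAtlas: 1001 peaks x 23 cell types
#>   context: exonic=61, intergenic=610, intronic=50, promoter=280
#>   single-cell-type peaks: 439

coloc <- colocalizeCcvs(ccvs, atlas)
nrow(coloc)
#> [1] 12
table(coloc$single_category)
#> epithelial
#>         12

preds <- allelicEffectsAll(ds$pwms,
           ds$variants[ds$variants$variant_id %in% coloc$variant_id, ],
           ds$genome)
subset(preds, allelic,
       select = c(variant_id, tf, ref_score, alt_score, delta, match_p))
#>    variant_id    tf  ref_score  alt_score      delta      match_p
#> 4    rsS01016  IRF8 1.00000000 0.06883264 -0.9311674 9.536743e-07
#> 14   rsS02012 CEBPB 0.05436812 1.00000000  0.9456319 1.525879e-05
#> 24   rsS03016  SPI1 1.00000000 0.06883264 -0.9311674 9.536743e-07
#> 31   rsS04015  IRF8 0.06883264 1.00000000  0.9311674 9.536743e-07
```

Reading the output: of the 13 selected CCVs, 12 fall inside cCREs that
are detected only in epithelial cell types (the planted trait-relevant
category), and one CCV per locus carries a large allelic
TF-binding-score difference (|delta| ≈ 0.93) with a significant motif
match — exactly the variants the generator planted at motif core
positions. `runPipeline(simConfig(), seed = 1, outDir = "out/")` runs
every stage at the default scale (~4,200 cells) and writes all result
tables plus a manifest; with a fixed config and seed the outputs are
byte-identical across runs.

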