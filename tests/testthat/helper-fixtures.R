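## Shared fixtures, generated once per session and memoized.

.fixtureCache <- new.env(parent = emptyenv())

uniformCellsPerType <- function(n = 20L) {
    types <- schemeCellTypes(defaultCategoryScheme())
    stats::setNames(rep(as.integer(n), length(types)), types)
}

## A mid-sized heterogeneous dataset exercising every stage.
baseConfig <- function() {
    simConfig(cellScale = 0.25, nPeaks = 1200, nGenes = 250,
              nLoci = 4, variantsPerLocus = 30, nFootprintSites = 25)
}

## Homogeneous single-population config: peaks are independent Bernoulli
## across cells, so only planted links produce peak-gene correlation.
homogConfig <- function(nCells = 8000L, linkEffect = 3, nLinks = 60L,
                        depthLogSD = 0) {
    simConfig(cellsPerType = c(AT2 = as.integer(nCells)), nPeaks = 250,
              nGenes = 70, nLoci = 2, variantsPerLocus = 20,
              nFootprintSites = 5, nLinks = nLinks,
              linkEffect = linkEffect, depthLogSD = depthLogSD)
}

## Footprint-oriented config: enough cells of the bound immune types.
footprintConfig <- function(protectionFactor = 0.2, fpFlankBoost = 1.5) {
    cpt <- uniformCellsPerType(30L)
    cpt[c("Dendritic", "Macrophage", "Bcell")] <- 150L
    simConfig(cellsPerType = cpt, nPeaks = 600, nGenes = 120,
              nLoci = 3, variantsPerLocus = 20, nFootprintSites = 30,
              protectionFactor = protectionFactor,
              fpFlankBoost = fpFlankBoost)
}

## Small connected-graph config for trait-relevance recovery: cluster
## sizes below k force the mutual kNN graph to connect across types.
trsConfig <- function() {
    simConfig(cellsPerType = uniformCellsPerType(20L), nPeaks = 500,
              nGenes = 120, nLoci = 4, variantsPerLocus = 25,
              nFootprintSites = 20)
}

pipelineConfig <- function() {
    ## >= 40 cells per type keeps every planted pattern above the
    ## 10-cell detection minimum
    cpt <- uniformCellsPerType(40L)
    cpt[c("Dendritic", "Macrophage", "Bcell")] <- 100L
    simConfig(cellsPerType = cpt, nPeaks = 700, nGenes = 150,
              nLoci = 3, variantsPerLocus = 25, nFootprintSites = 25)
}

getPipelineRun <- function() {
    if (is.null(.fixtureCache$pipelineRun)) {
        dir <- file.path(tempdir(), "mgatlas-pipeline-run")
        .fixtureCache$pipelineRun <- runPipeline(pipelineConfig(),
                                                 seed = 42, outDir = dir,
                                                 metacellK = 20)
        .fixtureCache$pipelineDir <- dir
    }
    .fixtureCache$pipelineRun
}

getFixture <- function(name) {
    if (!is.null(.fixtureCache[[name]])) return(.fixtureCache[[name]])
    ds <- switch(name,
        base = generateDataset(baseConfig(), seed = 11),
        baseNoSeq = generateDataset(baseConfig(), seed = 11,
                                    withFragments = FALSE,
                                    withSequences = FALSE),
        homog = generateDataset(homogConfig(), seed = 11,
                                withFragments = FALSE,
                                withSequences = FALSE),
        footprint = generateDataset(footprintConfig(), seed = 5,
                                    withSequences = FALSE),
        stop("unknown fixture ", name))
    .fixtureCache[[name]] <- ds
    ds
}

## Tiny hand-built bundle: 3 cells, 2 peaks, 2 genes.
tinyBundle <- function() {
    atac <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 3),
                                 x = c(1, 1, 2), dims = c(2, 3))
    rna <- Matrix::sparseMatrix(i = c(1, 2, 2), j = c(1, 2, 3),
                                x = c(3, 1, 4), dims = c(2, 3))
    peaks <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(101, 501), c(300, 700)))
    peaks$gc <- c(0.4, 0.6)
    gdf <- data.frame(gene_id = c("G1", "G2"), gene_name = c("A", "B"),
                      chrom = "chr1", strand = c("+", "-"),
                      tss = c(1000L, 5000L), tes = c(3000L, 4000L),
                      exons = c("1000-1500;2500-3000", "4000-4400"))
    genes <- mgatlas:::.geneModelGRanges(gdf)
    meta <- S4Vectors::DataFrame(
        sample_id = c("S1", "S1", "S2"),
        cell_type = c("AT2", "AT2", "Tcell"),
        category = c("epithelial", "epithelial", "immune"),
        smoking_status = c("ever", "never", "ever"),
        row.names = c("bc1", "bc2", "bc3"))
    new("MultiomeBundle", atac = as(atac, "CsparseMatrix"),
        rna = as(rna, "CsparseMatrix"), peaks = peaks, genes = genes,
        cellMeta = meta,
        scheme = CategoryScheme(c(AT2 = "epithelial", Tcell = "immune")))
}

## Independent re-evaluation of the category rule, used as oracle.
oracleCategoryAssignment <- function(row, scheme) {
    map <- scheme@map
    det <- names(row)[row]
    cats <- unname(map[det])
    if (length(unique(cats)) == 1L) return(unique(cats))
    out <- character(0)
    for (g in c("epithelial", "immune", "endothelial", "stromal")) {
        ng <- sum(map == g)
        cg <- sum(cats == g)
        if (cg > 0.75 * ng) out <- c(out, g)
    }
    out
}
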