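#' @include synthetic.R ccv.R atlas.R tf.R linkage.R trs.R scoring.R
NULL

#' Run the full annotation pipeline on a synthetic dataset
#'
#' Generates a dataset, selects CCVs, builds the cCRE atlas, colocalizes
#' CCVs with cCREs, computes trait relevance scores, scores allelic TF
#' binding / abundance / footprints, assigns six-level cCRE-gene
#' linkage, and derives the additive functional scores and locus
#' summaries. All stages consume the one seed; with a fixed (config,
#' seed) the written tables are byte-identical across runs.
#'
#' @param config a [simConfig()].
#' @param seed integer seed for every source of randomness.
#' @param outDir optional directory; when given, every result table is
#'   written as TSV plus a `manifest.json`.
#' @param linkWindow peak-gene window in bp (default 1e6).
#' @param metacellK cells per metacell (default 50).
#' @param skip character vector of stages to skip among `"trs"`,
#'   `"tf"`, `"linkage"` (skipped stages leave their outputs absent;
#'   downstream scoring then sees empty evidence).
#' @return list with all intermediate and final objects: `dataset`,
#'   `ccvs`, `atlas`, `coloc`, `trs`, `trsSummary`, `allelic`,
#'   `abundance`, `footprints`, `metacells`, `coaccess`, `modules`,
#'   `links`, `linkage`, `scores`, `locusSummary`.
#' @export
runPipeline <- function(config = simConfig(), seed = 1L, outDir = NULL,
                        linkWindow = 1e6, metacellK = 50,
                        skip = character()) {
    set.seed(seed)
    dataset <- generateDataset(config, seed)
    bundle <- dataset$bundle
    genes <- geneModels(bundle)
    res <- list(dataset = dataset)

    res$ccvs <- selectCcvsAll(dataset$gwas)
    res$atlas <- buildPeakAtlas(bundle)
    res$coloc <- colocalizeCcvs(res$ccvs, res$atlas)

    if (!"trs" %in% skip) {
        w <- traitWeights(res$ccvs, peakRanges(bundle))
        rawZ <- rawTraitScore(atacCounts(bundle), w, peakRanges(bundle))
        emb <- .lsiEmbedding(atacCounts(bundle))
        res$trs <- propagateTrs(rawZ, emb)
        res$trsSummary <- trsSummary(res$trs, cellMeta(bundle))
    }

    if (!"tf" %in% skip) {
        colocVariants <- dataset$variants[
            dataset$variants$variant_id %in% res$coloc$variant_id, ,
            drop = FALSE]
        res$allelic <- allelicEffectsAll(dataset$pwms, colocVariants,
                                         dataset$genome)
        predTfs <- unique(res$allelic$tf[res$allelic$allelic])
        if (!length(predTfs)) predTfs <- names(dataset$pwms)
        types <- colnames(detectionMatrix(res$atlas))
        universe <- expand.grid(tf = predTfs, cell_type = types,
                                stringsAsFactors = FALSE)
        rna <- rnaCounts(bundle)
        rownames(rna) <- genes$gene_name
        res$abundance <- tfAbundance(
            rna, as.character(cellMeta(bundle)$cell_type), universe)
        occ <- dataset$truth$motifOccurrences
        occ$chrom <- config$chrom
        res$footprints <- do.call(rbind, lapply(predTfs, function(tf)
            tfFootprints(dataset$fragments, occ, res$atlas, bundle,
                         tf)$summary))
    }

    if (!"linkage" %in% skip) {
        res$metacells <- makeMetacells(bundle, k = metacellK)
        res$coaccess <- coaccessibility(res$metacells$atac,
                                        peakRanges(bundle))
        res$modules <- detectModules(res$coaccess)
        res$links <- linkPeaksToGenes(
            res$metacells$atac, res$metacells$rna, peakRanges(bundle),
            genes, window = linkWindow,
            cellAtac = atacCounts(bundle), cellRna = rnaCounts(bundle))
        promMap <- promoterGeneMap(peakRanges(bundle), genes)
        ccres <- sort(unique(as.integer(unlist(
            strsplit(res$coloc$peaks, ";")))))
        res$linkage <- assignLinkageLevel(ccres, res$modules,
                                          res$coaccess, promMap,
                                          res$links, genes)
    }

    res$scores <- functionalScoresAll(
        res$coloc,
        if (is.null(res$allelic)) data.frame(variant_id = character(),
                                             tf = character(),
                                             allelic = logical())
        else res$allelic,
        if (is.null(res$abundance)) data.frame(tf = character(),
                                               cell_type = character(),
                                               abundant = logical())
        else res$abundance,
        if (is.null(res$footprints)) data.frame(tf = character(),
                                                cell_type = character(),
                                                detected = logical())
        else res$footprints)
    res$locusSummary <- locusSummary(
        res$ccvs, res$coloc, res$scores,
        if (is.null(res$linkage)) data.frame(ccre = integer(),
                                             gene_id = character(),
                                             level = integer())
        else res$linkage)

    if (!is.null(outDir)) .writePipelineTables(res, config, seed, outDir)
    res
}

.writePipelineTables <- function(res, config, seed, outDir) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    wt <- function(obj, name) if (!is.null(obj))
        writeResultTable(obj, file.path(outDir, paste0(name, ".tsv")))
    wt(res$ccvs, "ccvs")
    wt(atlasTable(res$atlas), "atlas")
    wt(res$coloc, "colocalization")
    wt(res$trs, "trs")
    wt(res$trsSummary, "trs_summary")
    wt(res$allelic, "allelic_predictions")
    wt(res$abundance, "tf_abundance")
    wt(res$footprints, "footprints")
    wt(res$coaccess, "coaccess_pairs")
    wt(res$modules, "modules")
    wt(res$links, "peak_gene_links")
    wt(res$linkage, "linkage_records")
    wt(res$scores, "variant_scores")
    wt(res$locusSummary$perLocus, "locus_summary")
    cfg <- config
    cfg$cellsPerType <- as.list(cfg$cellsPerType)
    manifest <- list(
        package = "mgatlas",
        version = as.character(utils::packageVersion("mgatlas")),
        seed = seed, config = unclass(cfg),
        global = res$locusSummary$global,
        tables = sort(list.files(outDir, pattern = "\\.tsv$")))
    json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    con <- file(file.path(outDir, "manifest.json"), "wb")
    writeLines(json, con)
    close(con)
    invisible(outDir)
}
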