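#' @include AllClasses.R utils.R io.R
NULL

#' Per-cell-type peak detection from the count matrix
#'
#' A peak is detected in a cell type when at least
#' `max(minCells, minFrac * n_t)` of that type's `n_t` cells carry a
#' nonzero count. This is the detection rule applied to an existing
#' peak-by-cell matrix (peak calling itself happens upstream of this
#' package).
#'
#' @param bundle a [MultiomeBundle-class].
#' @param minFrac minimal fraction of the type's cells (default 0.02).
#' @param minCells minimal absolute cell count (default 10).
#' @return logical peaks x cell-types matrix.
#' @export
detectPeaksPerType <- function(bundle, minFrac = 0.02, minCells = 10) {
    ct <- as.character(cellMeta(bundle)$cell_type)
    types <- schemeCellTypes(categoryScheme(bundle))
    types <- types[types %in% ct]
    empty <- setdiff(schemeCellTypes(categoryScheme(bundle)), types)
    if (length(empty))
        warning("cell type(s) with 0 cells excluded: ",
                paste(empty, collapse = ", "))
    atac <- atacCounts(bundle)
    ind <- Matrix::sparseMatrix(i = seq_along(ct), j = match(ct, types),
                                x = 1, dims = c(length(ct), length(types)))
    counts <- as.matrix((atac > 0) %*% ind)
    nPerType <- table(factor(ct, levels = types))
    thr <- pmax(minCells, minFrac * as.numeric(nPerType))
    det <- sweep(counts, 2L, thr, `>=`)
    dimnames(det) <- list(NULL, types)
    det
}

#' Genomic context of peaks
#'
#' Labels each peak `promoter`, `exonic`, `intronic` or `intergenic` with
#' that priority. A peak is a promoter when it overlaps the symmetric
#' window around any TSS (default +/-3000 bp); exonic/intronic require
#' overlap with an exon / the gene span.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes gene-model `GRanges` (with `tss`, `tes` and optionally
#'   `exons` metadata, as built by [.geneModelGRanges()]).
#' @param tssWindow two integers, offsets around the TSS (default
#'   `c(-3000, 3000)`).
#' @return character vector of context labels per peak.
#' @export
annotateGenomicContext <- function(peaks, genes,
                                   tssWindow = c(-3000, 3000)) {
    chr <- as.character(GenomicRanges::seqnames(genes))
    prom <- GenomicRanges::GRanges(chr,
        IRanges::IRanges(pmax(1L, genes$tss + tssWindow[1]),
                         genes$tss + tssWindow[2]))
    isProm <- IRanges::overlapsAny(peaks, prom)
    if (!is.null(genes$exons)) {
        exGR <- GenomicRanges::GRanges(
            rep(chr, lengths(genes$exons)), unlist(genes$exons))
        isEx <- IRanges::overlapsAny(peaks, exGR)
    } else isEx <- IRanges::overlapsAny(peaks, genes)
    isBody <- IRanges::overlapsAny(peaks, genes)
    out <- rep("intergenic", length(peaks))
    out[isBody] <- "intronic"
    out[isEx] <- "exonic"
    out[isProm] <- "promoter"
    out
}

#' Cell-type specificity of one detection row
#'
#' @param detectionRow named logical vector over cell types (>= 1 TRUE).
#' @return the single detecting cell type, or `NA` when more than one
#'   type detects the peak.
#' @export
cellTypeSpecificity <- function(detectionRow) {
    if (!any(detectionRow))
        .validationError("detection row with no detected cell type")
    hit <- names(detectionRow)[detectionRow]
    if (length(hit) == 1L) hit else NA_character_
}

#' Strict 75th-percentile category threshold
#'
#' The detected cell-type count a category of `n` cell types must
#' strictly exceed to claim a multi-category peak: `0.75 * n` (e.g. 6
#' for an 8-type category, so 7 or more detected types are required).
#'
#' @param n number of cell types in the category.
#' @return the strict threshold `0.75 * n`.
#' @examples
#' categoryThreshold(8)  # 6
#' @export
categoryThreshold <- function(n) 0.75 * n

#' Category assignment of one detection row
#'
#' If every detected cell type belongs to one category, the peak is
#' assigned to it. Otherwise a category `g` of `n_g` cell types claims
#' the peak when the detected count `c_g` strictly exceeds
#' `categoryThreshold(n_g) = 0.75 * n_g`; several categories may
#' qualify, and none qualifying leaves the peak "shared" (empty set).
#'
#' @inheritParams cellTypeSpecificity
#' @param scheme a [CategoryScheme-class].
#' @return character vector of assigned categories (possibly empty).
#' @examples
#' sch <- defaultCategoryScheme()
#' row <- setNames(rep(FALSE, 23), schemeCellTypes(sch))
#' row[c("AT2","AT1","Club","Ciliated","Goblet","Basal","AT1_AT2",
#'       "Macrophage","Tcell","Capillary","Fibroblast")] <- TRUE
#' categoryAssignment(row, sch)  # 7 of 8 epithelial > 6 -> "epithelial"
#' @export
categoryAssignment <- function(detectionRow, scheme) {
    if (!any(detectionRow))
        .validationError("detection row with no detected cell type")
    unknown <- setdiff(names(detectionRow), schemeCellTypes(scheme))
    if (length(unknown))
        .validationError(paste0("unknown cell type(s): ",
                                paste(unknown, collapse = ", ")))
    det <- names(detectionRow)[detectionRow]
    cats <- unname(scheme@map[det])
    if (length(unique(cats)) == 1L) return(unique(cats))
    sizes <- categorySizes(scheme)
    counts <- vapply(names(sizes), function(g) sum(cats == g), numeric(1))
    names(sizes)[counts > categoryThreshold(sizes)]
}

#' Gene activity scores from chromatin accessibility
#'
#' Sums accessibility signal per cell over each gene's activity window:
#' the promoter (2000 bp upstream of the TSS, strand-aware) through the
#' gene body to the TES. Accepts either a bundle (peak counts overlapping
#' the window are summed) or a fragment data.frame (fragments overlapping
#' the window are counted).
#'
#' @param x a [MultiomeBundle-class], or a fragment data.frame from
#'   [loadFragments()].
#' @param genes gene-model `GRanges`; defaults to the bundle's.
#' @param barcodes cell barcodes defining the column order (required for
#'   fragments).
#' @param upstream promoter extent upstream of the TSS (default 2000 bp).
#' @return genes x cells activity matrix (sparse).
#' @export
geneActivity <- function(x, genes = NULL, barcodes = NULL,
                         upstream = 2000) {
    if (is(x, "MultiomeBundle")) {
        if (is.null(genes)) genes <- geneModels(x)
        win <- .activityWindows(genes, upstream)
        ov <- GenomicRanges::findOverlaps(win, peakRanges(x))
        ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                                    j = S4Vectors::subjectHits(ov), x = 1,
                                    dims = c(length(genes),
                                             length(peakRanges(x))))
        act <- ind %*% atacCounts(x)
        rownames(act) <- genes$gene_id
        colnames(act) <- rownames(cellMeta(x))
        return(as(act, "CsparseMatrix"))
    }
    stopifnot(is.data.frame(x), !is.null(genes), !is.null(barcodes))
    win <- .activityWindows(genes, upstream)
    fr <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(x$start + 1L, x$end))
    ov <- GenomicRanges::findOverlaps(win, fr)
    cellIdx <- match(x$barcode[S4Vectors::subjectHits(ov)], barcodes)
    keep <- !is.na(cellIdx)
    act <- Matrix::sparseMatrix(i = S4Vectors::queryHits(ov)[keep],
                                j = cellIdx[keep],
                                x = x$count[S4Vectors::subjectHits(ov)[keep]],
                                dims = c(length(genes), length(barcodes)))
    rownames(act) <- genes$gene_id
    colnames(act) <- barcodes
    as(act, "CsparseMatrix")
}

.activityWindows <- function(genes, upstream) {
    zero <- genes$tss == genes$tes
    if (any(zero))
        warning(sum(zero), " gene(s) with tss == tes treated as promoter-only")
    plus <- as.character(GenomicRanges::strand(genes)) != "-"
    lo <- ifelse(plus, genes$tss - upstream, pmin(genes$tes, genes$tss))
    hi <- ifelse(plus, pmax(genes$tes, genes$tss), genes$tss + upstream)
    GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(genes)),
                           IRanges::IRanges(pmax(1, lo), hi))
}

#' Build the cell-type cCRE atlas
#'
#' Runs per-type detection, genomic-context annotation, single-cell-type
#' specificity and the quantile category rule over every detected peak.
#' Peaks detected in no cell type are dropped (with a message); the
#' returned atlas records their original indices in
#' `peakRanges(atlas)$peak_index`.
#'
#' @inheritParams detectPeaksPerType
#' @param tssWindow promoter window for context annotation.
#' @return a [PeakAtlas-class].
#' @export
buildPeakAtlas <- function(bundle, minFrac = 0.02, minCells = 10,
                           tssWindow = c(-3000, 3000)) {
    det <- detectPeaksPerType(bundle, minFrac, minCells)
    keep <- rowSums(det) > 0
    if (any(!keep))
        message(sum(!keep), " peak(s) detected in no cell type dropped")
    det <- det[keep, , drop = FALSE]
    pk <- peakRanges(bundle)[keep]
    pk$peak_index <- which(keep)
    scheme <- categoryScheme(bundle)
    ctx <- annotateGenomicContext(pk, geneModels(bundle), tssWindow)
    sp <- apply(det, 1L, cellTypeSpecificity)
    cats <- lapply(seq_len(nrow(det)), function(i)
        categoryAssignment(det[i, ], scheme))
    new("PeakAtlas", peaks = pk, detection = det, context = ctx,
        specificType = unname(sp), categories = cats, scheme = scheme)
}

#' Summarize a peak atlas as a table
#'
#' @param atlas a [PeakAtlas-class].
#' @return data.frame with chrom, start (0-based), end, context,
#'   detected_types, specific_cell_type, categories.
#' @export
atlasTable <- function(atlas) {
    pk <- peakRanges(atlas)
    data.frame(chrom = as.character(GenomicRanges::seqnames(pk)),
               start = GenomicRanges::start(pk) - 1L,
               end = GenomicRanges::end(pk),
               peak_index = pk$peak_index,
               context = peakContext(atlas),
               detected_types = vapply(seq_len(nrow(detectionMatrix(atlas))),
                   function(i) paste(colnames(detectionMatrix(atlas))[
                       detectionMatrix(atlas)[i, ]], collapse = ";"),
                   character(1)),
               specific_cell_type = specificCellType(atlas),
               categories = vapply(peakCategories(atlas), paste,
                                   character(1), collapse = ";"))
}
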