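#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Matrix dgCMatrix
NULL

## The four lung cell categories used throughout. Order is fixed so that
## tables and matrices are reproducible byte-for-byte.
.CATEGORIES <- c("epithelial", "immune", "endothelial", "stromal")

#' Cell-type to category scheme
#'
#' Maps every cell type to one of the four lung cell categories
#' (epithelial, immune, endothelial, stromal). The per-category sizes
#' (number of cell types, not number of cells) drive the 75th-percentile
#' category-specificity rule.
#'
#' @slot map named character vector: names are cell types, values are
#'   category labels.
#' @export
setClass("CategoryScheme", representation(map = "character"))

setValidity("CategoryScheme", function(object) {
    if (is.null(names(object@map)) || any(!nzchar(names(object@map))))
        return("every cell type must be named")
    if (anyDuplicated(names(object@map)))
        return("duplicated cell type in scheme")
    bad <- setdiff(unique(object@map), .CATEGORIES)
    if (length(bad))
        return(paste0("unknown category label(s): ",
                      paste(bad, collapse = ", ")))
    TRUE
})

#' Construct a CategoryScheme
#'
#' @param map named character vector mapping cell type to category; values
#'   must be among `epithelial`, `immune`, `endothelial`, `stromal`.
#' @return a [CategoryScheme-class] object.
#' @examples
#' CategoryScheme(c(AT2 = "epithelial", Tcell = "immune"))
#' @export
CategoryScheme <- function(map) new("CategoryScheme", map = map)

#' Barcode-shared single-nucleus multiome container
#'
#' Holds the paired snATAC and snRNA count matrices over one shared set of
#' cell barcodes, together with peak intervals, gene models and per-cell
#' metadata. Matrices are stored features-by-cells (Bioconductor
#' convention) as sparse `dgCMatrix`.
#'
#' @slot atac sparse peaks x cells non-negative count matrix.
#' @slot rna sparse genes x cells non-negative count matrix.
#' @slot peaks `GRanges` of peak intervals (0-based half-open on disk,
#'   1-based closed as `GRanges` in memory), in matrix row order.
#' @slot genes `GRanges` spanning each gene, with metadata columns
#'   `gene_id`, `gene_name`, `tss`, `tes` (1-based), in `rna` row order.
#' @slot cellMeta `DataFrame` with columns `sample_id`, `cell_type`,
#'   `category`, `smoking_status`, rownames = barcodes.
#' @slot scheme the [CategoryScheme-class] declaring type-to-category
#'   consistency.
#' @export
setClass("MultiomeBundle",
    representation(atac = "dgCMatrix", rna = "dgCMatrix",
                   peaks = "GRanges", genes = "GRanges",
                   cellMeta = "DataFrame", scheme = "CategoryScheme"))

setValidity("MultiomeBundle", function(object) {
    msg <- character()
    if (ncol(object@atac) != nrow(object@cellMeta))
        msg <- c(msg, "atac columns do not match cell metadata rows")
    if (ncol(object@rna) != nrow(object@cellMeta))
        msg <- c(msg, "rna columns do not match cell metadata rows")
    if (nrow(object@atac) != length(object@peaks))
        msg <- c(msg, "atac rows do not match peaks")
    if (nrow(object@rna) != length(object@genes))
        msg <- c(msg, "rna rows do not match genes")
    need <- c("sample_id", "cell_type", "category", "smoking_status")
    miss <- setdiff(need, colnames(object@cellMeta))
    if (length(miss))
        msg <- c(msg, paste0("cell metadata lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        bad <- setdiff(unique(object@cellMeta$category), .CATEGORIES)
        if (length(bad))
            msg <- c(msg, paste0("unknown category label(s): ",
                                 paste(bad, collapse = ", ")))
        map <- object@scheme@map
        ct <- as.character(object@cellMeta$cell_type)
        unknown <- setdiff(unique(ct), names(map))
        if (length(unknown))
            msg <- c(msg, paste0("cell type(s) not in scheme: ",
                                 paste(unknown, collapse = ", ")))
        else if (any(map[ct] != as.character(object@cellMeta$category)))
            msg <- c(msg, "cell categories inconsistent with the scheme")
        if (any(object@atac@x < 0) || any(object@rna@x < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Per-cell-type cCRE atlas
#'
#' Peaks with a boolean per-cell-type detection matrix, a genomic context
#' label, the single detecting cell type where applicable, and the
#' category assignment from the quantile rule.
#'
#' @slot peaks `GRanges` of the peaks.
#' @slot detection logical peaks x cell-types matrix.
#' @slot context character: `promoter`, `exonic`, `intronic` or
#'   `intergenic` per peak.
#' @slot specificType character per peak; `NA` unless detected in exactly
#'   one cell type.
#' @slot categories list of character vectors per peak (possibly empty =
#'   shared across categories).
#' @slot scheme the [CategoryScheme-class] used for assignment.
#' @export
setClass("PeakAtlas",
    representation(peaks = "GRanges", detection = "matrix",
                   context = "character", specificType = "character",
                   categories = "list", scheme = "CategoryScheme"))

setValidity("PeakAtlas", function(object) {
    msg <- character()
    n <- length(object@peaks)
    if (nrow(object@detection) != n)
        msg <- c(msg, "detection rows do not match peaks")
    if (!is.logical(object@detection))
        msg <- c(msg, "detection must be a logical matrix")
    if (length(object@context) != n || length(object@specificType) != n ||
        length(object@categories) != n)
        msg <- c(msg, "per-peak annotations must match peak count")
    if (!length(msg) && n > 0) {
        if (any(rowSums(object@detection) == 0))
            msg <- c(msg, "every peak must be detected in >= 1 cell type")
        one <- rowSums(object@detection) == 1L
        hasSp <- !is.na(object@specificType)
        if (any(one != hasSp))
            msg <- c(msg, "specificType must be set iff exactly one type detects the peak")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MultiomeBundle", function(object) {
    cat("MultiomeBundle:", ncol(object@atac), "cells |",
        nrow(object@atac), "peaks |", nrow(object@rna), "genes\n")
    tab <- table(object@cellMeta$category)
    cat("  categories:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    cat("  cell types:", length(unique(object@cellMeta$cell_type)), "\n")
})

setMethod("show", "PeakAtlas", function(object) {
    cat("PeakAtlas:", length(object@peaks), "peaks x",
        ncol(object@detection), "cell types\n")
    cat("  context:",
        paste(names(table(object@context)),
              as.integer(table(object@context)),
              sep = "=", collapse = ", "), "\n")
    cat("  single-cell-type peaks:", sum(!is.na(object@specificType)), "\n")
})
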