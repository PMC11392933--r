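#' @include AllClasses.R
NULL

#' Accessors for MultiomeBundle and PeakAtlas
#'
#' Accessor generics for the central containers: counts, ranges, metadata
#' and atlas annotations.
#'
#' @param x a [MultiomeBundle-class] or [PeakAtlas-class] object.
#' @return the requested component; see each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atacCounts", function(x) standardGeneric("atacCounts"))
#' @rdname accessors
#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))
#' @rdname accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @rdname accessors
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname accessors
#' @export
setGeneric("cellMeta", function(x) standardGeneric("cellMeta"))
#' @rdname accessors
#' @export
setGeneric("categoryScheme", function(x) standardGeneric("categoryScheme"))
#' @rdname accessors
#' @export
setGeneric("detectionMatrix", function(x) standardGeneric("detectionMatrix"))
#' @rdname accessors
#' @export
setGeneric("peakContext", function(x) standardGeneric("peakContext"))
#' @rdname accessors
#' @export
setGeneric("specificCellType", function(x) standardGeneric("specificCellType"))
#' @rdname accessors
#' @export
setGeneric("peakCategories", function(x) standardGeneric("peakCategories"))

#' @rdname accessors
#' @export
setMethod("atacCounts", "MultiomeBundle", function(x) x@atac)
#' @rdname accessors
#' @export
setMethod("rnaCounts", "MultiomeBundle", function(x) x@rna)
#' @rdname accessors
#' @export
setMethod("peakRanges", "MultiomeBundle", function(x) x@peaks)
#' @rdname accessors
#' @export
setMethod("geneModels", "MultiomeBundle", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("cellMeta", "MultiomeBundle", function(x) x@cellMeta)
#' @rdname accessors
#' @export
setMethod("categoryScheme", "MultiomeBundle", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("peakRanges", "PeakAtlas", function(x) x@peaks)
#' @rdname accessors
#' @export
setMethod("detectionMatrix", "PeakAtlas", function(x) x@detection)
#' @rdname accessors
#' @export
setMethod("peakContext", "PeakAtlas", function(x) x@context)
#' @rdname accessors
#' @export
setMethod("specificCellType", "PeakAtlas", function(x) x@specificType)
#' @rdname accessors
#' @export
setMethod("peakCategories", "PeakAtlas", function(x) x@categories)
#' @rdname accessors
#' @export
setMethod("categoryScheme", "PeakAtlas", function(x) x@scheme)

#' Cell types and category sizes of a scheme
#'
#' @param scheme a [CategoryScheme-class].
#' @return `schemeCellTypes`: the cell-type names; `categorySizes`: named
#'   integer vector of cell-type counts per category (all four categories,
#'   in fixed order).
#' @examples
#' categorySizes(defaultCategoryScheme())
#' @export
categorySizes <- function(scheme) {
    stopifnot(is(scheme, "CategoryScheme"))
    out <- vapply(.CATEGORIES, function(g) sum(scheme@map == g), integer(1))
    out
}

#' @rdname categorySizes
#' @export
schemeCellTypes <- function(scheme) {
    stopifnot(is(scheme, "CategoryScheme"))
    names(scheme@map)
}
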