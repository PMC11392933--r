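#' @include AllClasses.R utils.R atlas.R
NULL

#' Colocalize CCVs with atlas cCREs
#'
#' A 1-based variant position `p` overlaps a 0-based half-open peak
#' `[s, e)` iff `s < p <= e`. Each colocalized CCV carries the union of
#' detecting cell types and category assignments over its overlapping
#' peaks; `single_category` is the intersection when it resolves to one
#' category.
#'
#' @param ccvs CCV data.frame (locus_id, variant_id, chrom, pos, ...).
#' @param atlas a [PeakAtlas-class].
#' @return data.frame with one row per colocalized CCV: CCV keys,
#'   `peaks` (semicolon-joined original peak indices), `cell_types`,
#'   `categories` (unions), `single_category` (or NA).
#' @export
colocalizeCcvs <- function(ccvs, atlas) {
    pk <- peakRanges(atlas)
    known <- unique(as.character(GenomicRanges::seqnames(pk)))
    off <- !(ccvs$chrom %in% known)
    if (any(off)) {
        warning(sum(off), " CCV(s) on chromosomes absent from the atlas skipped")
        ccvs <- ccvs[!off, , drop = FALSE]
    }
    if (!nrow(ccvs))
        return(data.frame(locus_id = character(), variant_id = character(),
                          chrom = character(), pos = integer(),
                          peaks = character(), cell_types = character(),
                          categories = character(),
                          single_category = character()))
    vGR <- GenomicRanges::GRanges(ccvs$chrom,
                                  IRanges::IRanges(ccvs$pos, ccvs$pos))
    ov <- GenomicRanges::findOverlaps(vGR, pk)
    det <- detectionMatrix(atlas)
    cats <- peakCategories(atlas)
    hitRows <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    out <- lapply(names(hitRows), function(q) {
        i <- as.integer(q)
        hits <- hitRows[[q]]
        types <- sort(unique(unlist(lapply(hits, function(h)
            colnames(det)[det[h, ]]))))
        catList <- lapply(hits, function(h) cats[[h]])
        un <- sort(unique(unlist(catList)))
        inter <- Reduce(intersect, catList)
        data.frame(locus_id = ccvs$locus_id[i],
                   variant_id = ccvs$variant_id[i],
                   chrom = ccvs$chrom[i], pos = ccvs$pos[i],
                   peaks = paste(pk$peak_index[hits], collapse = ";"),
                   cell_types = paste(types, collapse = ";"),
                   categories = paste(un, collapse = ";"),
                   single_category = if (length(inter) == 1L) inter
                                     else NA_character_)
    })
    res <- do.call(rbind, out)
    res <- res[order(res$locus_id, res$pos, res$variant_id), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Additive 1-4 functional score of a colocalized CCV
#'
#' The score counts four evidence indicators: cCRE colocalization (the
#' entry ticket: only colocalized CCVs are scored), at least one
#' predicted allelic TF, a cell-type-matching abundant allelic TF, and
#' a detected footprint for an allelic TF.
#'
#' @param record one row of [colocalizeCcvs()] output.
#' @param allelic allelic predictions ([allelicEffectsAll()] output).
#' @param abundance [tfAbundance()] output.
#' @param footprints footprint summary rows (from [tfFootprints()]
#'   `$summary`, possibly row-bound over TFs).
#' @param abundanceTypeMatch require the abundant cell type to be among
#'   the CCV's detecting cell types (default TRUE).
#' @param footprintTypeMatch require the footprint cell type to be among
#'   the detecting types (default FALSE: any cell type counts).
#' @return one-row data.frame: locus_id, variant_id, colocalized,
#'   allelic_tfs, abundance_match, footprint_match, functional_score.
#' @export
functionalScore <- function(record, allelic, abundance, footprints,
                            abundanceTypeMatch = TRUE,
                            footprintTypeMatch = FALSE) {
    .assert(nzchar(record$peaks), "cannot score a non-colocalized CCV",
            "mgatlas_contract_error")
    types <- strsplit(record$cell_types, ";")[[1]]
    av <- allelic[allelic$variant_id == record$variant_id &
                  allelic$allelic, , drop = FALSE]
    tfs <- unique(av$tf)
    abMatch <- FALSE
    fpMatch <- FALSE
    if (length(tfs)) {
        ab <- abundance[abundance$tf %in% tfs & abundance$abundant, ,
                        drop = FALSE]
        abMatch <- if (abundanceTypeMatch) any(ab$cell_type %in% types)
                   else nrow(ab) > 0
        fp <- footprints[footprints$tf %in% tfs & footprints$detected, ,
                         drop = FALSE]
        fpMatch <- if (footprintTypeMatch) any(fp$cell_type %in% types)
                   else nrow(fp) > 0
    }
    data.frame(locus_id = record$locus_id,
               variant_id = record$variant_id,
               colocalized = TRUE,
               allelic_tfs = paste(tfs, collapse = ";"),
               abundance_match = abMatch, footprint_match = fpMatch,
               functional_score = 1L + as.integer(length(tfs) > 0) +
                   as.integer(abMatch) + as.integer(fpMatch))
}

#' @rdname functionalScore
#' @param coloc full [colocalizeCcvs()] output.
#' @return `functionalScoresAll`: row-bound scores over all colocalized
#'   CCVs.
#' @export
functionalScoresAll <- function(coloc, allelic, abundance, footprints,
                                abundanceTypeMatch = TRUE,
                                footprintTypeMatch = FALSE) {
    out <- lapply(seq_len(nrow(coloc)), function(i)
        functionalScore(coloc[i, , drop = FALSE], allelic, abundance,
                        footprints, abundanceTypeMatch,
                        footprintTypeMatch))
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(locus_id = character(), variant_id = character(),
                          colocalized = logical(), allelic_tfs = character(),
                          abundance_match = logical(),
                          footprint_match = logical(),
                          functional_score = integer())
    rownames(res) <- NULL
    res
}

#' Per-locus summary and global fractions
#'
#' @param ccvs CCV table ([selectCcvsAll()] output).
#' @param coloc [colocalizeCcvs()] output.
#' @param scores [functionalScoresAll()] output.
#' @param linkage [assignLinkageLevel()] output; `coloc` ties cCREs to
#'   loci through their overlapping peak indices.
#' @return list with `perLocus` (locus_id, n_ccvs, n_colocalized,
#'   categories, max_functional_score, genes_by_level) and `global`
#'   (n_loci, n_unique_ccvs, frac_loci_colocalized,
#'   frac_loci_level6).
#' @export
locusSummary <- function(ccvs, coloc, scores, linkage) {
    loci <- sort(unique(ccvs$locus_id))
    ccrePerLocus <- lapply(stats::setNames(loci, loci), function(l) {
        pk <- unlist(strsplit(coloc$peaks[coloc$locus_id == l], ";"))
        unique(as.integer(pk))
    })
    rows <- lapply(loci, function(l) {
        cc <- ccvs[ccvs$locus_id == l, , drop = FALSE]
        co <- coloc[coloc$locus_id == l, , drop = FALSE]
        sc <- scores[scores$locus_id == l, , drop = FALSE]
        lk <- linkage[linkage$ccre %in% ccrePerLocus[[l]], , drop = FALSE]
        genes <- if (nrow(lk)) {
            mx <- tapply(lk$level, lk$gene_id, max)
            paste(sprintf("%s:%d", names(mx), as.integer(mx)),
                  collapse = ";")
        } else ""
        cats <- sort(unique(unlist(strsplit(co$categories, ";"))))
        data.frame(locus_id = l, n_ccvs = nrow(cc),
                   n_colocalized = nrow(co),
                   categories = paste(cats, collapse = ";"),
                   max_functional_score = if (nrow(sc))
                       max(sc$functional_score) else 0L,
                   genes_by_level = genes,
                   n_level6_genes = if (nrow(lk))
                       length(unique(lk$gene_id[lk$level == 6L])) else 0L)
    })
    perLocus <- do.call(rbind, rows)
    rownames(perLocus) <- NULL
    key <- paste(ccvs$chrom, ccvs$pos, ccvs$ref, ccvs$alt)
    global <- list(
        n_loci = length(loci),
        n_unique_ccvs = length(unique(key)),
        frac_loci_colocalized = mean(perLocus$n_colocalized > 0),
        frac_loci_level6 = mean(perLocus$n_level6_genes > 0))
    list(perLocus = perLocus, global = global)
}
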