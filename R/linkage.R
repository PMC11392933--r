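#' @include AllClasses.R utils.R atlas.R
#' @importFrom igraph graph_from_data_frame cluster_louvain membership components
NULL

#' Aggregate cells into metacells
#'
#' Cells are embedded by TF-IDF + truncated SVD of the ATAC matrix
#' (components 2..nComponents; the first component tracks depth and is
#' dropped) and grouped greedily into disjoint sets of `k` nearest
#' neighbours; counts are summed within groups. Exactly
#' `floor(n_cells / k)` metacells are produced.
#'
#' @param bundle a [MultiomeBundle-class].
#' @param k cells per metacell (default 50).
#' @param nComponents SVD components before dropping the first.
#' @return list with `atac` (peaks x metacells), `rna`
#'   (genes x metacells), `assign` (metacell index per cell, NA for
#'   leftovers), `cellType` (dominant type per metacell), `k`.
#' @export
makeMetacells <- function(bundle, k = 50, nComponents = 30) {
    atac <- atacCounts(bundle)
    n <- ncol(atac)
    .assert(n >= k, "fewer cells than k", "mgatlas_parameter_error")
    if (n < 2 * k)
        warning("fewer than 2k cells: a single metacell split is returned")
    m <- n %/% k
    emb <- .lsiEmbedding(atac, nComponents)
    assign <- rep(NA_integer_, n)
    remaining <- seq_len(n)
    for (g in seq_len(m)) {
        seedCell <- remaining[1L]
        d2 <- rowSums((emb[remaining, , drop = FALSE] -
                       matrix(emb[seedCell, ], length(remaining),
                              ncol(emb), byrow = TRUE))^2)
        pick <- remaining[order(d2)[seq_len(k)]]
        assign[pick] <- g
        remaining <- setdiff(remaining, pick)
    }
    ok <- !is.na(assign)
    ind <- Matrix::sparseMatrix(i = which(ok), j = assign[ok], x = 1,
                                dims = c(n, m))
    ct <- as.character(cellMeta(bundle)$cell_type)
    dominant <- vapply(seq_len(m), function(g)
        names(sort(table(ct[which(assign == g)]), decreasing = TRUE))[1],
        character(1))
    list(atac = as.matrix(atac %*% ind),
         rna = as.matrix(rnaCounts(bundle) %*% ind),
         assign = assign, cellType = dominant, k = k)
}

## Row-standardize a dense unit matrix; zero-variance rows flagged NA.
.rowStd <- function(m) {
    m <- as.matrix(m)
    mu <- rowMeans(m)
    s <- sqrt(pmax(rowSums((m - mu)^2), 0) / (ncol(m) - 1L))
    bad <- !is.finite(s) | s == 0
    s[bad] <- 1
    out <- (m - mu) / s
    out[bad, ] <- NA_real_
    out
}

#' Pairwise co-accessibility scores
#'
#' Pearson correlation of aggregated (metacell) accessibility for every
#' peak pair within `maxDist` bp (midpoint distance) on the same
#' chromosome. Pairs with undefined correlation (a zero-variance peak)
#' are omitted.
#'
#' @param metaAtac peaks x metacells matrix (from [makeMetacells()]).
#' @param peaks `GRanges` of the peaks (same order).
#' @param maxDist maximal midpoint distance in bp (default 500 kb).
#' @param minMetacells minimal number of aggregation units (default 10).
#' @return data.frame peak_i, peak_j (i < j by coordinate), score,
#'   distance.
#' @export
coaccessibility <- function(metaAtac, peaks, maxDist = 5e5,
                            minMetacells = 10) {
    .assert(ncol(metaAtac) >= minMetacells,
            "need >= minMetacells aggregation units",
            "mgatlas_parameter_error")
    M <- ncol(metaAtac)
    xs <- .rowStd(metaAtac)
    mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2
    chr <- as.character(GenomicRanges::seqnames(peaks))
    out <- list()
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        idx <- idx[order(mid[idx])]
        mids <- mid[idx]
        hiBound <- findInterval(mids + maxDist, mids)
        rows <- list()
        for (a in seq_along(idx)) {
            if (hiBound[a] <= a) next
            js <- (a + 1L):hiBound[a]
            i <- idx[a]
            if (all(is.na(xs[i, ]))) next
            r <- as.numeric(xs[idx[js], , drop = FALSE] %*% xs[i, ]) /
                (M - 1L)
            ok <- is.finite(r)
            if (!any(ok)) next
            pi <- pmin(i, idx[js][ok]); pj <- pmax(i, idx[js][ok])
            rows[[length(rows) + 1L]] <-
                data.frame(peak_i = pi, peak_j = pj, score = r[ok],
                           distance = abs(mids[js][ok] - mids[a]))
        }
        if (length(rows)) out[[ch]] <- do.call(rbind, rows)
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(peak_i = integer(), peak_j = integer(),
                           score = numeric(), distance = numeric())
    res <- res[order(res$peak_i, res$peak_j), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Detect co-accessible cCRE modules
#'
#' Louvain community detection on the graph of peak pairs with
#' co-accessibility at or above the module cutoff; communities of two or
#' more peaks are modules. Module ids are renumbered by each module's
#' lowest peak index for determinism.
#'
#' @param pairs data.frame from [coaccessibility()].
#' @param moduleCutoff minimal score for a module edge (default 0.32).
#' @param communitySeed RNG seed for the Louvain pass (default 1).
#' @return data.frame module_id, peak.
#' @export
detectModules <- function(pairs, moduleCutoff = 0.32, communitySeed = 1L) {
    ed <- pairs[pairs$score >= moduleCutoff, c("peak_i", "peak_j"),
                drop = FALSE]
    if (!nrow(ed))
        return(data.frame(module_id = integer(), peak = integer()))
    g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(ed$peak_i),
                   to = as.character(ed$peak_j)), directed = FALSE)
    set.seed(communitySeed)
    comm <- igraph::cluster_louvain(g)
    mem <- igraph::membership(comm)
    peak <- as.integer(names(mem))
    keepMods <- names(which(table(mem) >= 2))
    keep <- as.character(mem) %in% keepMods
    df <- data.frame(comm = as.integer(mem[keep]), peak = peak[keep])
    ## renumber by lowest member coordinate (peak index order)
    lo <- tapply(df$peak, df$comm, min)
    newId <- stats::setNames(rank(lo, ties.method = "first"), names(lo))
    df$module_id <- as.integer(newId[as.character(df$comm)])
    df <- df[order(df$module_id, df$peak), c("module_id", "peak")]
    rownames(df) <- NULL
    df
}

#' Background-corrected peak-gene links
#'
#' For each gene, peaks whose midpoint lies within `window` of the TSS
#' are correlated with its expression across aggregation units. The raw
#' Pearson r is compared against the correlations of `nBackground`
#' peaks matched to the focal peak by nearest neighbours in standardized
#' (GC fraction, mean accessibility, width) space; the z-score against
#' that matched null gives a one-sided (default) p-value. Links with
#' `p < pCutoff` and `|r| > rCutoff` are flagged retained.
#'
#' @param unitAtac,unitRna peaks x units and genes x units matrices
#'   (cells or metacells; `cellAtac`/`cellRna` supply the per-cell
#'   matrices for the min.cells filter when units are metacells).
#' @param peaks `GRanges` with optional `gc` metadata.
#' @param genes gene-model `GRanges`.
#' @param window max |midpoint - TSS| in bp (1e6; use 2e6/5e6 for the
#'   wide-window variants).
#' @param minCells minimal cells with signal for a peak/gene to be
#'   tested (default 10).
#' @param nBackground matched background peaks per focal peak (200).
#' @param pCutoff,rCutoff retention thresholds (0.05 / 0.05).
#' @param twoSided use a two-sided p-value (default FALSE: one-sided in
#'   the direction of positive regulation).
#' @param cellAtac,cellRna optional per-cell matrices for the filter.
#' @return data.frame peak, gene_id, gene_index, r, z, p, tss_distance,
#'   retained; attribute `skipped` counts zero-variance pairs.
#' @export
linkPeaksToGenes <- function(unitAtac, unitRna, peaks, genes,
                             window = 1e6, minCells = 10,
                             nBackground = 200, pCutoff = 0.05,
                             rCutoff = 0.05, twoSided = FALSE,
                             cellAtac = NULL, cellRna = NULL) {
    M <- ncol(unitAtac)
    peakSignal <- if (is.null(cellAtac)) unitAtac else cellAtac
    geneSignal <- if (is.null(cellRna)) unitRna else cellRna
    peaksOK <- Matrix::rowSums(peakSignal > 0) >= minCells
    genesOK <- Matrix::rowSums(geneSignal > 0) >= minCells
    xs <- .rowStd(unitAtac)
    ys <- .rowStd(unitRna)
    ## covariate space for background matching
    gc <- if (!is.null(peaks$gc)) peaks$gc else rep(0.5, length(peaks))
    cov <- .zscale(cbind(gc = gc,
                         acc = Matrix::rowMeans(unitAtac),
                         width = GenomicRanges::width(peaks)))
    pool <- which(peaksOK & !is.na(xs[, 1]))
    nb <- min(nBackground, length(pool) - 1L)
    if (nb < nBackground)
        warning("only ", nb, " background candidate peaks available")
    nn <- RANN::nn2(cov[pool, , drop = FALSE], cov, k = min(nb + 1L,
                                                            length(pool)))
    ## background selector: row pk averages its nb matched peaks
    ## (self-matches dropped)
    bgI <- rep(seq_len(length(peaks)), each = ncol(nn$nn.idx))
    bgJ <- pool[as.vector(t(nn$nn.idx))]
    keepBG <- bgI != bgJ
    bgI <- bgI[keepBG]; bgJ <- bgJ[keepBG]
    ord <- order(bgI)
    bgI <- bgI[ord]; bgJ <- bgJ[ord]
    rankInPeak <- stats::ave(bgJ, bgI, FUN = seq_along)
    keepBG <- rankInPeak <= nb
    bgI <- bgI[keepBG]; bgJ <- bgJ[keepBG]
    nbPer <- tabulate(bgI, nbins = length(peaks))
    nbPer[nbPer == 0] <- 1L
    B <- Matrix::sparseMatrix(i = bgI, j = bgJ,
                              x = 1 / nbPer[bgI],
                              dims = c(length(peaks), length(peaks)))
    ## all correlations and matched-null moments in three matmuls
    geneSel <- which(genesOK & !is.na(ys[, 1]))
    skipped <- sum(genesOK) - length(geneSel)
    rAll <- (xs %*% t(ys[geneSel, , drop = FALSE])) / (M - 1L)
    muN <- as.matrix(B %*% rAll)
    sdN <- sqrt(pmax(as.matrix(B %*% rAll^2) - muN^2, 0) *
                (nbPer / pmax(nbPer - 1L, 1L)))
    mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2
    chrP <- as.character(GenomicRanges::seqnames(peaks))
    chrG <- as.character(GenomicRanges::seqnames(genes))
    rows <- list()
    for (col in seq_along(geneSel)) {
        g <- geneSel[col]
        cand <- which(chrP == chrG[g] & abs(mid - genes$tss[g]) <= window &
                      peaksOK & !is.na(xs[, 1]) & sdN[, col] > 0)
        if (!length(cand)) next
        z <- (rAll[cand, col] - muN[cand, col]) / sdN[cand, col]
        p <- if (twoSided) 2 * stats::pnorm(-abs(z))
             else stats::pnorm(z, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            peak = cand, gene_id = genes$gene_id[g], gene_index = g,
            r = rAll[cand, col], z = z, p = p,
            tss_distance = mid[cand] - genes$tss[g],
            retained = p < pCutoff & abs(rAll[cand, col]) > rCutoff)
    }
    res <- if (length(rows)) do.call(rbind, rows)
           else data.frame(peak = integer(), gene_id = character(),
                           gene_index = integer(), r = numeric(),
                           z = numeric(), p = numeric(),
                           tss_distance = numeric(), retained = logical())
    res <- res[order(res$peak, res$gene_index), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "skipped") <- skipped
    res
}

#' Six-level cCRE-to-gene linkage assignment
#'
#' Evaluates, for each query cCRE, the six evidence predicates of the
#' linkage hierarchy -- (1) a module mate is a promoter cCRE, (2)
#' directly co-accessible with a promoter cCRE, (3) itself a promoter,
#' (4) a module mate carries a retained expression link, (5) directly
#' co-accessible with an expression-linked cCRE, (6) itself
#' expression-linked -- and emits one record per (cCRE, gene) with the
#' maximum attained level and the full evidence chain.
#'
#' @param ccres integer peak indices to query (CCV-colocalizing cCREs).
#' @param modules data.frame from [detectModules()].
#' @param pairs data.frame from [coaccessibility()]; pairs with
#'   `score >= directCutoff` (default 0.5) count as directly
#'   co-accessible.
#' @param promoterMap data.frame peak, gene_index: peaks overlapping a
#'   gene's promoter window (see [promoterGeneMap()]).
#' @param links data.frame from [linkPeaksToGenes()]; only retained rows
#'   are used.
#' @param genes gene-model `GRanges` (for gene ids).
#' @param directCutoff direct co-accessibility threshold.
#' @return data.frame ccre, gene_index, gene_id, level, evidence
#'   (semicolon-joined chain like `"L4:via=123"`).
#' @export
assignLinkageLevel <- function(ccres, modules, pairs, promoterMap, links,
                               genes, directCutoff = 0.5) {
    retained <- links[links$retained, , drop = FALSE]
    direct <- pairs[pairs$score >= directCutoff, , drop = FALSE]
    promByPeak <- split(promoterMap$gene_index, promoterMap$peak)
    linkByPeak <- split(retained$gene_index, retained$peak)
    modByPeak <- stats::setNames(modules$module_id,
                                 as.character(modules$peak))
    modMembers <- split(modules$peak, modules$module_id)
    out <- list()
    for (cc in ccres) {
        ev <- list()   # gene_index -> list(level, via)
        addEv <- function(gidx, level, via) {
            for (g in gidx) {
                key <- as.character(g)
                ev[[key]] <<- c(ev[[key]],
                                sprintf("L%d:%s", level, via))
            }
        }
        mates <- integer(0)
        mid <- modByPeak[as.character(cc)]
        if (!is.na(mid) && length(mid))
            mates <- setdiff(modMembers[[as.character(mid)]], cc)
        partners <- c(direct$peak_j[direct$peak_i == cc],
                      direct$peak_i[direct$peak_j == cc])
        for (m in mates) {
            pg <- promByPeak[[as.character(m)]]
            if (!is.null(pg)) addEv(pg, 1L, paste0("module_mate=", m))
            lg <- linkByPeak[[as.character(m)]]
            if (!is.null(lg)) addEv(lg, 4L, paste0("module_mate=", m))
        }
        for (pt in partners) {
            pg <- promByPeak[[as.character(pt)]]
            if (!is.null(pg)) addEv(pg, 2L, paste0("coaccessible=", pt))
            lg <- linkByPeak[[as.character(pt)]]
            if (!is.null(lg)) addEv(lg, 5L, paste0("coaccessible=", pt))
        }
        selfProm <- promByPeak[[as.character(cc)]]
        if (!is.null(selfProm)) addEv(selfProm, 3L, "self_promoter")
        selfLink <- linkByPeak[[as.character(cc)]]
        if (!is.null(selfLink)) addEv(selfLink, 6L, "self_link")
        if (!length(ev)) next
        for (key in names(ev)) {
            lv <- as.integer(sub("^L(\\d).*", "\\1", ev[[key]]))
            out[[length(out) + 1L]] <- data.frame(
                ccre = cc, gene_index = as.integer(key),
                gene_id = genes$gene_id[as.integer(key)],
                level = max(lv),
                evidence = paste(sort(unique(ev[[key]])), collapse = ";"))
        }
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(ccre = integer(), gene_index = integer(),
                           gene_id = character(), level = integer(),
                           evidence = character())
    res <- res[order(res$ccre, res$gene_index), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Promoter window to gene map
#'
#' @param peaks `GRanges` of peaks.
#' @param genes gene-model `GRanges`.
#' @param tssWindow symmetric promoter window (default +/-3000 bp).
#' @return data.frame peak, gene_index for every peak overlapping a
#'   gene's promoter window.
#' @export
promoterGeneMap <- function(peaks, genes, tssWindow = c(-3000, 3000)) {
    prom <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(genes)),
        IRanges::IRanges(pmax(1L, genes$tss + tssWindow[1]),
                         genes$tss + tssWindow[2]))
    ov <- GenomicRanges::findOverlaps(peaks, prom)
    data.frame(peak = S4Vectors::queryHits(ov),
               gene_index = S4Vectors::subjectHits(ov))
}
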