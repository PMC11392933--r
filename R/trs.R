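#' @include AllClasses.R utils.R
NULL

#' Per-peak trait weights from CCVs
#'
#' Each locus carries one unit of probability split evenly across its
#' CCVs; a peak's trait weight is the sum over CCVs falling inside it of
#' `1 / n_CCVs(locus)`.
#'
#' @param ccvs CCV data.frame with locus_id, chrom, pos.
#' @param peaks `GRanges` of the peaks.
#' @return numeric weight per peak.
#' @export
traitWeights <- function(ccvs, peaks) {
    w <- numeric(length(peaks))
    if (!nrow(ccvs)) return(w)
    perLocus <- table(ccvs$locus_id)
    vGR <- GenomicRanges::GRanges(ccvs$chrom,
                                  IRanges::IRanges(ccvs$pos, ccvs$pos))
    ov <- GenomicRanges::findOverlaps(vGR, peaks)
    contrib <- 1 / as.numeric(perLocus[ccvs$locus_id[
        S4Vectors::queryHits(ov)]])
    agg <- tapply(contrib, S4Vectors::subjectHits(ov), sum)
    w[as.integer(names(agg))] <- agg
    w
}

#' Bias-corrected per-cell raw trait score
#'
#' The observed score of a cell is its depth-normalized weighted
#' accessibility over trait peaks. The null distribution comes from
#' `nBackgroundSets` peak sets in which every trait peak is replaced by
#' a random peak among its nearest neighbours in standardized (GC, mean
#' accessibility, width) space, keeping the weights.
#'
#' @param atac peaks x cells count matrix.
#' @param weights per-peak trait weights (see [traitWeights()]).
#' @param peaks `GRanges` with optional `gc` metadata.
#' @param nBackgroundSets number of matched null sets (default 50).
#' @param nNeighbors matched-candidate pool per trait peak (default 50).
#' @return numeric raw z-score per cell.
#' @export
rawTraitScore <- function(atac, weights, peaks, nBackgroundSets = 50,
                          nNeighbors = 50) {
    trait <- which(weights > 0)
    if (!length(trait))
        .validationError("no CCV overlaps any peak: all trait weights zero")
    depth <- Matrix::colSums(atac > 0)
    depth[depth == 0] <- 1
    gc <- if (!is.null(peaks$gc)) peaks$gc else rep(0.5, length(peaks))
    cov <- .zscale(cbind(gc = gc, acc = Matrix::rowMeans(atac),
                         width = GenomicRanges::width(peaks)))
    pool <- setdiff(seq_len(length(peaks)), trait)
    k <- min(nNeighbors, length(pool))
    nn <- RANN::nn2(cov[pool, , drop = FALSE],
                    cov[trait, , drop = FALSE], k = k)
    obs <- as.numeric(Matrix::crossprod(atac[trait, , drop = FALSE],
                                        weights[trait])) / depth
    nullScores <- matrix(0, nBackgroundSets, ncol(atac))
    for (s in seq_len(nBackgroundSets)) {
        picks <- pool[nn$nn.idx[cbind(seq_along(trait),
                                      sample.int(k, length(trait),
                                                 replace = TRUE))]]
        nullScores[s, ] <- as.numeric(
            Matrix::crossprod(atac[picks, , drop = FALSE],
                              weights[trait])) / depth
    }
    mu <- colMeans(nullScores)
    sdv <- apply(nullScores, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    (obs - mu) / sdv
}

#' Network-propagated trait relevance score
#'
#' Builds a mutual kNN graph on the embedding, seeds the top
#' `seedFrac` cells by raw score (ties broken by cell order), and runs
#' a restart random walk from the uniform-over-seeds restart vector to
#' convergence. Scores are scaled to mean 1 over the propagated cells.
#' Cells outside the largest connected component are not propagated:
#' they receive their raw-score rank percentile (flagged
#' `propagated = FALSE`).
#'
#' @param rawZ per-cell raw scores.
#' @param embedding cells x d matrix (e.g. the LSI embedding).
#' @param k mutual kNN neighbours (default 30).
#' @param seedFrac fraction of cells used as seeds (default 0.05).
#' @param restart restart probability (default 0.05); `restart = 1`
#'   returns the (scaled) seed indicator.
#' @param tol sup-norm convergence tolerance (default 1e-6).
#' @param maxIter iteration cap.
#' @return data.frame cell, raw_z, seed, trs, propagated.
#' @export
propagateTrs <- function(rawZ, embedding, k = 30, seedFrac = 0.05,
                         restart = 0.05, tol = 1e-6, maxIter = 10000) {
    n <- length(rawZ)
    .assert(k < n, "k must be smaller than the number of cells",
            "mgatlas_parameter_error")
    .assert(restart > 0 && restart <= 1, "restart must lie in (0, 1]",
            "mgatlas_parameter_error")
    nn <- RANN::nn2(embedding, embedding, k = k + 1L)
    src <- rep(seq_len(n), k)
    dst <- as.vector(nn$nn.idx[, -1L])
    A <- Matrix::sparseMatrix(i = src, j = dst, x = 1, dims = c(n, n))
    A <- A * Matrix::t(A)          # mutual edges only
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        A > 0, mode = "undirected"))
    inLC <- comp$membership == which.max(comp$csize)
    nSeeds <- max(1L, ceiling(seedFrac * n))
    seedOrder <- order(-rawZ, seq_len(n))
    seeds <- rep(FALSE, n)
    seeds[utils::head(seedOrder[inLC[seedOrder]], nSeeds)] <- TRUE
    idx <- which(inLC)
    Asub <- A[idx, idx, drop = FALSE]
    deg <- Matrix::rowSums(Asub)
    deg[deg == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / deg) %*% Asub
    s <- as.numeric(seeds[idx]); s <- s / sum(s)
    p <- s
    for (it in seq_len(maxIter)) {
        pNew <- (1 - restart) * as.numeric(Matrix::crossprod(W, p)) +
            restart * s
        if (max(abs(pNew - p)) < tol) { p <- pNew; break }
        p <- pNew
    }
    trs <- rep(NA_real_, n)
    trs[idx] <- p / mean(p)
    out <- data.frame(cell = seq_len(n), raw_z = rawZ, seed = seeds,
                      trs = trs, propagated = inLC)
    if (any(!inLC))
        out$trs[!inLC] <- rank(rawZ[!inLC]) / sum(!inLC)
    out
}

#' Summarize TRS by cell type and category
#'
#' @param trs data.frame from [propagateTrs()].
#' @param meta cell metadata (`DataFrame`/data.frame with cell_type and
#'   category), same cell order.
#' @param nBoot bootstrap resamples for the CI (default 1000).
#' @param conf confidence level (default 0.95).
#' @return data.frame grouping, group, mean_trs, ci_lo, ci_hi, n_cells.
#' @export
trsSummary <- function(trs, meta, nBoot = 1000, conf = 0.95) {
    a <- (1 - conf) / 2
    one <- function(values) {
        bm <- vapply(seq_len(nBoot), function(b)
            mean(values[sample.int(length(values), replace = TRUE)]),
            numeric(1))
        c(mean(values), stats::quantile(bm, c(a, 1 - a), names = FALSE))
    }
    blocks <- list(cell_type = as.character(meta$cell_type),
                   category = as.character(meta$category))
    out <- list()
    for (gr in names(blocks)) {
        for (g in sort(unique(blocks[[gr]]))) {
            v <- trs$trs[blocks[[gr]] == g]
            st <- one(v)
            out[[length(out) + 1L]] <- data.frame(
                grouping = gr, group = g, mean_trs = st[1],
                ci_lo = st[2], ci_hi = st[3], n_cells = length(v))
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
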