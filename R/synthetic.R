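#' @include AllClasses.R utils.R io.R
#' @importFrom Biostrings DNAStringSet
NULL

## Default lung cell-type inventory: 23 types in 4 categories with
## deliberately unbalanced sizes (epithelial-enriched, rare types present).
.defaultCellTypes <- function() {
    list(
        epithelial = c(AT2 = 560, AT1 = 280, Club = 210, Ciliated = 170,
                       Goblet = 110, Basal = 130, AT1_AT2 = 85,
                       AT2_prolif = 40),
        immune = c(Macrophage = 490, Tcell = 420, NK = 210, Monocyte = 170,
                   Bcell = 110, Dendritic = 55, NK_T = 85),
        endothelial = c(Capillary = 350, Vein = 170, Artery = 110,
                        Lymphatic = 70),
        stromal = c(Fibroblast = 170, SmoothMuscle = 85, Mesothelial = 35,
                    Myofibroblast = 50))
}

#' Default cell-type to category scheme
#'
#' Eight epithelial, seven immune, four endothelial and four stromal lung
#' cell types.
#'
#' @return a [CategoryScheme-class].
#' @export
defaultCategoryScheme <- function() {
    ct <- .defaultCellTypes()
    map <- unlist(lapply(names(ct), function(g)
        stats::setNames(rep(g, length(ct[[g]])), names(ct[[g]]))))
    CategoryScheme(map)
}

## Built-in synthetic motif models (plain count matrices; synthetic, not
## any database's measured motifs). Information content is concentrated
## at one core position (position 5, the only G of each consensus; all
## other positions are weak A/T preferences) so that substituting the
## core base moves the min-max-normalized IC-weighted score by ~0.9
## while a full-width consensus match stays highly significant
## (p ~ 0.25^width).
.builtinMotifConsensus <- c(IRF8 = "ATTAGTTAAT", CEBPB = "TTAAGATT",
                            SPI1 = "TATTGAATTA")
.builtinCorePos <- 5L

.builtinMotifs <- function(background = rep(0.25, 4)) {
    bases <- c("A", "C", "G", "T")
    out <- lapply(names(.builtinMotifConsensus), function(nm) {
        cons <- strsplit(.builtinMotifConsensus[[nm]], "")[[1]]
        counts <- matrix(20, 4, length(cons), dimnames = list(bases, NULL))
        counts[cbind(match(cons, bases), seq_along(cons))] <- 40
        counts[, .builtinCorePos] <- 1
        counts[match(cons[.builtinCorePos], bases), .builtinCorePos] <- 297
        newPWM(nm, counts, pseudocount = 0.8, background = background)
    })
    names(out) <- names(.builtinMotifConsensus)
    out
}

#' Synthetic multiome study configuration
#'
#' Bundles every knob of the synthetic data generator: cell-type
#' inventory, peak layout and accessibility probabilities, expression
#' model, planted peak-to-gene links, GWAS locus structure, motif set and
#' Tn5 fragment model. Defaults emulate the structure of a lung multiome
#' study at desk scale (~4200 cells, 5000 peaks, 1000 genes, 10 loci of
#' 50 variants).
#'
#' @param cellsPerType named integer vector of cells per cell type; the
#'   default is the 23-type lung inventory.
#' @param cellScale global multiplier on `cellsPerType` (minimum 2 cells
#'   per type survive scaling).
#' @param nPeaks number of peaks; `peakSpacing` bp between peak slots.
#' @param peakWidthMean,peakWidthSD,peakWidthRange peak width model (bp);
#'   structural peaks (GWAS/footprint sites) are fixed at 500 bp.
#' @param pOpenHigh,pOpenLow Bernoulli open probabilities for cells whose
#'   type is / is not in a peak's planted pattern.
#' @param depthLogSD log-normal sd of the per-cell depth factor.
#' @param nGenes number of genes (includes the motif TF genes).
#' @param geneMeanLog,geneMeanLogSD log-normal model of baseline gene
#'   means; `nbDispersion` is the NB size parameter.
#' @param linkEffect multiplicative expression effect when a planted
#'   linked peak is open in the same cell; `nLinks` extra random planted
#'   links besides the per-locus ones; `linkMinDist`/`linkMaxDist` bound
#'   the planted peak-TSS distance (bp).
#' @param nLoci,variantsPerLocus GWAS structure; `ldRho` AR(1) LD decay;
#'   `causalZ` planted causal z magnitude; `variantSpacing` bp between
#'   consecutive variants.
#' @param traitCategory the planted trait-relevant cell category.
#' @param nFootprintSites motif occurrences planted per TF;
#'   `protectionFactor` multiplies insertion probability at the motif
#'   centre (+/- 10 bp) in bound cell types; `fpFlankBoost` multiplies it
#'   over the bound-type flanking region (TF occupancy keeps the
#'   surrounding chromatin accessible).
#' @param biasAmplitude,biasPeriod smooth positional Tn5 bias field
#'   (log-amplitude and period in bp).
#' @param fragMeanPerOpen mean fragments per open cell-peak pair;
#'   `fragmentPeaks` either `"sites"` (motif-carrying peaks only) or
#'   `"all"`.
#' @param background genome base composition (A, C, G, T).
#' @return a validated `SimConfig` (list).
#' @export
simConfig <- function(cellsPerType = NULL, cellScale = 1,
                      nPeaks = 5000L, peakSpacing = 4000L,
                      peakWidthMean = 450, peakWidthSD = 50,
                      peakWidthRange = c(300, 600),
                      pOpenHigh = 0.35, pOpenLow = 0.01, depthLogSD = 0.2,
                      nGenes = 1000L, geneMeanLog = log(0.5),
                      geneMeanLogSD = 1, nbDispersion = 2,
                      linkEffect = 3, nLinks = 40L, linkMinDist = 0,
                      linkMaxDist = 5e5,
                      nLoci = 10L, variantsPerLocus = 50L, ldRho = 0.9,
                      causalZ = 8, variantSpacing = 400L,
                      traitCategory = "epithelial",
                      nFootprintSites = 30L, protectionFactor = 0.2,
                      fpFlankBoost = 1.5, biasAmplitude = 0.3,
                      biasPeriod = 147, fragMeanPerOpen = 4,
                      fragmentPeaks = c("sites", "all"),
                      background = rep(0.25, 4)) {
    types <- .defaultCellTypes()
    if (is.null(cellsPerType))
        cellsPerType <- unlist(unname(lapply(types, identity)))
    cellsPerType <- stats::setNames(
        pmax(2L, as.integer(round(cellsPerType * cellScale))),
        names(cellsPerType))
    .assert(!is.null(names(cellsPerType)),
            "cellsPerType must be named by cell type", "mgatlas_config_error")
    .assert(pOpenHigh >= 0 && pOpenHigh <= 1 && pOpenLow >= 0 &&
            pOpenLow <= 1, "open probabilities must lie in [0,1]",
            "mgatlas_config_error")
    .assert(ldRho >= 0 && ldRho < 1, "ldRho must lie in [0,1)",
            "mgatlas_config_error")
    .assert(causalZ > 0, "causalZ must be positive", "mgatlas_config_error")
    .assert(protectionFactor >= 0 && protectionFactor <= 1,
            "protectionFactor must lie in [0,1]", "mgatlas_config_error")
    .assert(traitCategory %in% .CATEGORIES, "unknown traitCategory",
            "mgatlas_config_error")
    nTF <- length(.builtinMotifConsensus)
    .assert(nLoci * 3L + nTF * nFootprintSites <= nPeaks,
            "config requests more structural (category-specific) peaks than nPeaks",
            "mgatlas_config_error")
    .assert(nGenes > nTF + nLoci, "nGenes too small for planted genes",
            "mgatlas_config_error")
    structure(list(
        cellsPerType = cellsPerType, nPeaks = as.integer(nPeaks),
        peakSpacing = as.integer(peakSpacing),
        peakWidthMean = peakWidthMean, peakWidthSD = peakWidthSD,
        peakWidthRange = peakWidthRange, pOpenHigh = pOpenHigh,
        pOpenLow = pOpenLow, depthLogSD = depthLogSD,
        nGenes = as.integer(nGenes), geneMeanLog = geneMeanLog,
        geneMeanLogSD = geneMeanLogSD, nbDispersion = nbDispersion,
        linkEffect = linkEffect, nLinks = as.integer(nLinks),
        linkMinDist = linkMinDist, linkMaxDist = linkMaxDist, nLoci = as.integer(nLoci),
        variantsPerLocus = as.integer(variantsPerLocus), ldRho = ldRho,
        causalZ = causalZ, variantSpacing = as.integer(variantSpacing),
        traitCategory = traitCategory,
        nFootprintSites = as.integer(nFootprintSites),
        protectionFactor = protectionFactor, fpFlankBoost = fpFlankBoost,
        biasAmplitude = biasAmplitude, biasPeriod = biasPeriod,
        fragMeanPerOpen = fragMeanPerOpen,
        fragmentPeaks = match.arg(fragmentPeaks),
        background = background / sum(background),
        chrom = "chrS",
        genomeLength = as.integer(nPeaks) * as.integer(peakSpacing) + 60000L
    ), class = "SimConfig")
}

## TF planting map: each built-in motif TF gets a bound immune-side cell
## type (footprint + abundance) and an epithelial anchor type that seeds
## the trait-relevant causal-peak patterns.
.tfBoundTypes <- c(IRF8 = "Dendritic", CEBPB = "Macrophage", SPI1 = "Bcell")
.tfEpiAnchors <- c(IRF8 = "AT2", CEBPB = "Club", SPI1 = "Basal")

#' Generate a synthetic multiome bundle with planted truth
#'
#' Lays out peaks and genes on one synthetic chromosome, plants per-peak
#' cell-type detection patterns (including per-locus trios of
#' co-accessible trait-category peaks and TF footprint site peaks),
#' plants peak-to-gene links, and draws the sparse ATAC (Bernoulli
#' presence with per-cell depth) and RNA (negative binomial with
#' multiplicative link effects) matrices.
#'
#' @param config a [simConfig()] object.
#' @param seed integer RNG seed; the same (config, seed) pair always
#'   returns identical output.
#' @return list with elements `bundle` ([MultiomeBundle-class]) and
#'   `truth` (`SyntheticTruth` list: peak patterns, planted links, locus
#'   table, variant table, footprint sites, motif occurrences, bias field
#'   parameters, trait category, per-cell depths, seed).
#' @export
generateMultiome <- function(config, seed) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(seed)
    scheme <- defaultCategoryScheme()
    keep <- names(config$cellsPerType)
    .assert(all(keep %in% schemeCellTypes(scheme)),
            "cellsPerType names must be known cell types",
            "mgatlas_config_error")
    types <- keep
    typeCat <- scheme@map[types]
    nTF <- length(.builtinMotifConsensus)
    tfNames <- names(.builtinMotifConsensus)

    ## ---- cells ----
    cellType <- rep(types, config$cellsPerType[types])
    n <- length(cellType)
    barcodes <- sprintf("cell_%05d", seq_len(n))
    sampleId <- sprintf("S%02d", 1L + (seq_len(n) %% 16L))
    smoking <- ifelse(seq_len(n) %% 2L == 0L, "ever", "never")
    depth <- pmin(2, pmax(0.5, exp(stats::rnorm(n, 0, config$depthLogSD))))

    ## ---- peak layout ----
    P <- config$nPeaks
    sp <- config$peakSpacing
    width <- round(pmin(config$peakWidthRange[2],
                        pmax(config$peakWidthRange[1],
                             stats::rnorm(P, config$peakWidthMean,
                                          config$peakWidthSD))))
    slotStart <- (seq_len(P) - 1L) * sp + 500L +
        sample.int(200L, P, replace = TRUE)

    ## structural peak slots: per-locus trios + TF footprint sites
    lociSlots <- as.integer(round(seq_len(config$nLoci) * P /
                                  (config$nLoci + 1)))
    trioIdx <- lapply(lociSlots, function(s) c(s, s - 10L, s + 10L))
    structural <- unlist(trioIdx)
    freeSlots <- setdiff(seq_len(P), unlist(lapply(structural, function(s)
        (s - 2L):(s + 2L))))
    fpIdx <- lapply(seq_len(nTF), function(k) {
        pick <- sort(sample(freeSlots, config$nFootprintSites))
        freeSlots <<- setdiff(freeSlots, pick)
        pick
    })
    names(fpIdx) <- tfNames
    ## one promoter peak per TF gene, accessible where the TF is
    ## expressed, so marker expression and gene activity co-vary
    tfPromIdx <- sample(freeSlots, nTF)
    freeSlots <- setdiff(freeSlots, tfPromIdx)
    width[c(structural, unlist(fpIdx), tfPromIdx)] <- 500L
    peakStart0 <- slotStart
    peakEnd0 <- slotStart + width
    gc <- stats::runif(P, 0.35, 0.65)

    ## ---- planted detection patterns ----
    byCat <- split(types, typeCat)
    pattern <- vector("list", P)
    u <- stats::runif(P)
    for (j in seq_len(P)) {
        if (u[j] < 0.40) k <- 1L
        else if (u[j] < 0.75) k <- sample(2:4, 1L)
        else if (u[j] < 0.90) k <- sample(5:10, 1L)
        else k <- length(types)
        k <- min(k, length(types))
        if (k == length(types)) pattern[[j]] <- types
        else if (stats::runif(1) < 0.6) {
            g <- sample(names(byCat), 1L,
                        prob = lengths(byCat) / length(types))
            pool <- byCat[[g]]
            pattern[[j]] <- sample(pool, min(k, length(pool)))
        } else pattern[[j]] <- sample(types, k)
    }
    ## per-locus trait-category trios: anchor epithelial type of the
    ## locus TF plus two other types of the trait category
    traitTypes <- byCat[[config$traitCategory]]
    if (is.null(traitTypes)) traitTypes <- types
    locusTF <- tfNames[1L + (seq_len(config$nLoci) - 1L) %% nTF]
    for (i in seq_len(config$nLoci)) {
        anchor <- .tfEpiAnchors[[locusTF[i]]]
        if (!anchor %in% traitTypes) anchor <- traitTypes[1]
        others <- setdiff(traitTypes, anchor)
        ## broad trait-category pattern (all but one type of the
        ## category): the quantile rule then tolerates a spurious
        ## detection in another category
        pat <- c(anchor, sample(others, min(length(others),
                                            max(2L, length(traitTypes) - 2L))))
        for (s in trioIdx[[i]]) pattern[[s]] <- pat
    }
    ## footprint site peaks: bound type + two other random types
    for (t in tfNames) {
        bound <- .tfBoundTypes[[t]]
        if (!bound %in% types) bound <- types[length(types)]
        extra <- setdiff(types, bound)
        for (s in fpIdx[[t]])
            pattern[[s]] <- c(bound, sample(extra, min(2L, length(extra))))
    }
    for (k in seq_len(nTF)) {
        t <- tfNames[k]
        pat <- unique(c(.tfBoundTypes[[t]], .tfEpiAnchors[[t]]))
        pat <- pat[pat %in% types]
        if (!length(pat)) pat <- types[1]
        pattern[[tfPromIdx[k]]] <- pat
    }

    ## ---- ATAC matrix ----
    typeIdx <- match(cellType, types)
    ii <- vector("list", P)
    for (j in seq_len(P)) {
        inPat <- types %in% pattern[[j]]
        p <- ifelse(inPat[typeIdx], config$pOpenHigh, config$pOpenLow)
        open <- stats::runif(n) < pmin(1, p * depth)
        ii[[j]] <- which(open)
    }
    lens <- lengths(ii)
    atac <- Matrix::sparseMatrix(i = rep.int(seq_len(P), lens),
                                 j = unlist(ii), x = 1,
                                 dims = c(P, n))
    atac <- as(atac, "CsparseMatrix")

    ## ---- genes ----
    G <- config$nGenes
    geneNames <- c(tfNames, sprintf("gene_%04d", seq_len(G - nTF)))
    tssPos <- sample.int(config$genomeLength - 20000L, G) + 10000L
    strandG <- sample(c("+", "-"), G, replace = TRUE)
    glen <- round(stats::runif(G, 2000, 10000))
    ## locus genes: reposition one gene near each causal peak
    locusGene <- nTF + seq_len(config$nLoci)
    causalPeak <- vapply(trioIdx, `[`, integer(1), 1L)
    causalMid <- as.integer((peakStart0[causalPeak] +
                             peakEnd0[causalPeak]) / 2)
    tssPos[locusGene] <- causalMid +
        sample(c(-1L, 1L), config$nLoci, replace = TRUE) *
        round(stats::runif(config$nLoci, 5e4, 3e5))
    ## TF marker genes start at their planted promoter peak
    tssPos[seq_len(nTF)] <- as.integer((peakStart0[tfPromIdx] +
                                        peakEnd0[tfPromIdx]) / 2)
    strandG[seq_len(nTF)] <- "+"
    tssPos <- pmax(11000L, pmin(config$genomeLength - 11000L, tssPos))
    tesPos <- ifelse(strandG == "+", tssPos + glen, tssPos - glen)
    gdf <- data.frame(gene_id = sprintf("G%04d", seq_len(G)),
                      gene_name = geneNames, chrom = config$chrom,
                      strand = strandG, tss = tssPos, tes = tesPos)
    ## 2-4 exons per gene, laid left-to-right inside the span
    gdf$exons <- vapply(seq_len(G), function(g) {
        lo <- min(tssPos[g], tesPos[g]); hi <- max(tssPos[g], tesPos[g])
        nEx <- sample(2:4, 1L)
        bounds <- sort(sample(seq(lo, hi), 2L * nEx))
        paste(sprintf("%d-%d", bounds[seq(1, 2 * nEx, 2)],
                      bounds[seq(2, 2 * nEx, 2)]), collapse = ";")
    }, character(1))
    genes <- .geneModelGRanges(gdf)

    ## ---- planted links ----
    linkPeak <- integer(0); linkGene <- integer(0); linkKind <- character(0)
    for (i in seq_len(config$nLoci)) {
        linkPeak <- c(linkPeak, trioIdx[[i]])
        linkGene <- c(linkGene, rep(locusGene[i], 3L))
        linkKind <- c(linkKind, rep("locus", 3L))
    }
    if (config$nLinks > 0) {
        midAll <- (peakStart0 + peakEnd0) / 2
        pool <- setdiff(seq_len(P), c(unlist(trioIdx), unlist(fpIdx)))
        rp <- sample(pool, config$nLinks)
        for (j in rp) {
            d <- abs(tssPos - midAll[j])
            d[seq_len(nTF)] <- Inf          # keep TF genes unlinked
            d[locusGene] <- Inf
            gsel <- which(d <= config$linkMaxDist & d >= config$linkMinDist)
            if (!length(gsel)) next
            gpick <- gsel[which.min(d[gsel])]
            linkPeak <- c(linkPeak, j)
            linkGene <- c(linkGene, gpick)
            linkKind <- c(linkKind, "random")
        }
    }
    links <- data.frame(peak = linkPeak, gene_id = gdf$gene_id[linkGene],
                        gene_index = linkGene, effect = config$linkEffect,
                        kind = linkKind)

    ## ---- RNA matrix ----
    baseMean <- pmin(10, pmax(0.05,
        exp(stats::rnorm(G, config$geneMeanLog, config$geneMeanLogSD))))
    ## TF genes: planted abundance in the bound type and the epithelial
    ## anchor, low baseline elsewhere
    tfMeanByType <- matrix(0.05, nTF, length(types),
                           dimnames = list(tfNames, types))
    for (t in tfNames) {
        if (.tfBoundTypes[[t]] %in% types)
            tfMeanByType[t, .tfBoundTypes[[t]]] <- 3
        if (.tfEpiAnchors[[t]] %in% types)
            tfMeanByType[t, .tfEpiAnchors[[t]]] <- 1.5
    }
    linkByGene <- split(links$peak, links$gene_index)
    gi <- vector("list", G)
    gx <- vector("list", G)
    for (g in seq_len(G)) {
        mu <- if (g <= nTF) tfMeanByType[g, typeIdx] else rep(baseMean[g], n)
        mu <- mu * depth
        lp <- linkByGene[[as.character(g)]]
        if (!is.null(lp)) {
            openAny <- if (length(lp) == 1L) atac[lp, ] > 0
                       else Matrix::colSums(atac[lp, , drop = FALSE]) > 0
            mu[as.logical(openAny)] <- mu[as.logical(openAny)] *
                config$linkEffect
        }
        x <- stats::rnbinom(n, mu = mu, size = config$nbDispersion)
        nz <- which(x > 0)
        gi[[g]] <- nz
        gx[[g]] <- x[nz]
    }
    lens <- lengths(gi)
    rna <- Matrix::sparseMatrix(i = rep.int(seq_len(G), lens),
                                j = unlist(gi), x = unlist(gx),
                                dims = c(G, n))
    rna <- as(rna, "CsparseMatrix")

    ## ---- variants (positions only; alleles filled with sequences) ----
    v <- config$variantsPerLocus
    varRows <- vector("list", config$nLoci)
    for (i in seq_len(config$nLoci)) {
        ci <- sample(10:(v - 10), 1L)
        offs <- (seq_len(v) - ci) * config$variantSpacing
        offs[ci - 1L] <- -160L
        offs[ci + 1L] <- 160L
        pos <- causalMid[i] + offs
        varRows[[i]] <- data.frame(
            locus_id = sprintf("%d_%s", i, config$chrom),
            variant_id = sprintf("rsS%02d%03d", i, seq_len(v)),
            chrom = config$chrom, pos = as.integer(pos),
            ref = "N", alt = "N",
            causal = seq_len(v) == ci, causal_index = ci,
            tf = locusTF[i])
    }
    variants <- do.call(rbind, varRows)
    pkGR <- GenomicRanges::GRanges(config$chrom,
        IRanges::IRanges(peakStart0 + 1L, peakEnd0))
    pkGR$gc <- gc
    vGR <- GenomicRanges::GRanges(variants$chrom,
        IRanges::IRanges(variants$pos, variants$pos))
    ov <- GenomicRanges::findOverlaps(vGR, pkGR)
    variants$peak <- NA_integer_
    variants$peak[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
    variants$in_peak <- !is.na(variants$peak)

    ## ---- motif occurrences ----
    occ <- rbind(
        do.call(rbind, lapply(tfNames, function(t)
            data.frame(tf = t, peak = fpIdx[[t]],
                       center = as.integer((peakStart0[fpIdx[[t]]] +
                                            peakEnd0[fpIdx[[t]]]) / 2),
                       bound_types = I(lapply(fpIdx[[t]], function(.)
                           .tfBoundTypes[[t]])),
                       site_type = "footprint"))),
        data.frame(tf = locusTF, peak = causalPeak,
                   center = causalMid,
                   bound_types = I(replicate(config$nLoci, character(0),
                                             simplify = FALSE)),
                   site_type = "causal"))

    meta <- S4Vectors::DataFrame(sample_id = sampleId, cell_type = cellType,
                                 category = unname(typeCat[cellType]),
                                 smoking_status = smoking,
                                 row.names = barcodes)
    bundle <- new("MultiomeBundle", atac = atac, rna = rna, peaks = pkGR,
                  genes = genes, cellMeta = meta,
                  scheme = CategoryScheme(typeCat))

    catTruth <- vapply(pattern, function(p) {
        cats <- unique(unname(typeCat[p]))
        if (length(cats) == 1L) cats else NA_character_
    }, character(1))

    truth <- structure(list(
        seed = seed, config = config,
        peakPattern = pattern, peakCategory = catTruth,
        links = links,
        loci = data.frame(locus_id = sprintf("%d_%s", seq_len(config$nLoci),
                                             config$chrom),
                          causal_peak = causalPeak,
                          gene_id = gdf$gene_id[locusGene],
                          gene_index = locusGene, tf = locusTF),
        trioPeaks = trioIdx,
        variants = variants,
        footprintSites = fpIdx,
        tfPromoterPeaks = stats::setNames(tfPromIdx, tfNames),
        motifOccurrences = occ,
        bias = list(amplitude = config$biasAmplitude,
                    period = config$biasPeriod,
                    phase = stats::runif(1, 0, 2 * pi)),
        traitCategory = config$traitCategory,
        depth = depth,
        cellsPerCategory = table(unname(typeCat[cellType]))
    ), class = "SyntheticTruth")
    list(bundle = bundle, truth = truth)
}

#' Generate LD-structured GWAS summary statistics
#'
#' Per locus, the variant correlation matrix is AR(1)
#' (`R[i,j] = rho^|i-j|`), z-scores are drawn from
#' `MVN(lambda * R * e_causal, R)`, the lead is the largest `|z|`, and
#' `r2_to_lead` is the squared correlation with the lead. With a
#' `SyntheticTruth` the variants reuse the planted genomic positions and
#' locus structure; standalone, loci are laid out abstractly.
#'
#' @inheritParams generateMultiome
#' @param truth optional `SyntheticTruth` from [generateMultiome()].
#' @return list with `gwas` (merged stats + LD data.frame as from
#'   [loadGwasBundle()]) and `truth` (updated with per-locus lead and
#'   causal bookkeeping).
#' @export
generateGwas <- function(config, seed, truth = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(seed + 1000L)
    v <- config$variantsPerLocus
    rho <- config$ldRho
    R <- rho ^ abs(outer(seq_len(v), seq_len(v), `-`))
    CH <- chol(R)
    rows <- vector("list", config$nLoci)
    leadIdx <- integer(config$nLoci)
    for (i in seq_len(config$nLoci)) {
        if (!is.null(truth)) {
            vt <- truth$variants[truth$variants$locus_id ==
                                 truth$loci$locus_id[i], , drop = FALSE]
            ci <- vt$causal_index[1]
        } else {
            ci <- sample(seq_len(v), 1L)
            vt <- data.frame(locus_id = sprintf("locus_%02d", i),
                             variant_id = sprintf("rsA%02d%03d", i,
                                                  seq_len(v)),
                             chrom = "chrA", pos = i * 10L + seq_len(v),
                             ref = "A", alt = "G")
        }
        z <- config$causalZ * R[, ci] + drop(crossprod(CH, stats::rnorm(v)))
        lead <- which.max(abs(z))
        leadIdx[i] <- lead
        rows[[i]] <- data.frame(
            locus_id = vt$locus_id, variant_id = vt$variant_id,
            chrom = vt$chrom, pos = vt$pos, ref = vt$ref, alt = vt$alt,
            p = 2 * stats::pnorm(-abs(z)), z = z,
            is_lead = seq_len(v) == lead,
            r2_to_lead = R[, lead]^2, population = "SYN")
    }
    gwas <- do.call(rbind, rows)
    rownames(gwas) <- NULL
    if (!is.null(truth)) {
        truth$loci$lead_index <- leadIdx
        truth$gwas <- gwas
    }
    list(gwas = gwas, truth = truth)
}

## Evaluate the smooth positional Tn5 bias multiplier at 1-based positions.
.biasAt <- function(pos, bias) {
    exp(bias$amplitude * sin(2 * pi * pos / bias$period + bias$phase))
}

#' Generate the synthetic genome and allelic variants
#'
#' Draws a random background chromosome, writes each planted motif
#' occurrence's consensus into it, and converts each locus's causal
#' variant into an allelic variant at the motif's maximum-information
#' position: `disrupt` loci carry the consensus base as reference and the
#' worst base as alternative; `create` loci the reverse. Non-causal
#' variants get the genome base as reference and a random different
#' alternative.
#'
#' @inheritParams generateGwas
#' @param truth `SyntheticTruth` from [generateMultiome()] (required: the
#'   motif occurrences and variant positions live there).
#' @param pwms motif set (default: the built-in synthetic motifs).
#' @return list with `genome` (`DNAStringSet`), `variants` (completed
#'   allele table) and updated `truth` (allelic plant records under
#'   `$allelic`).
#' @export
generateSequencesAndVariants <- function(config, seed, truth,
                                         pwms = .builtinMotifs(config$background)) {
    stopifnot(inherits(config, "SimConfig"), inherits(truth, "SyntheticTruth"))
    set.seed(seed + 2000L)
    bases <- c("A", "C", "G", "T")
    L <- config$genomeLength
    seqChar <- sample(bases, L, replace = TRUE, prob = config$background)

    occ <- truth$motifOccurrences
    widths <- vapply(pwms, function(p) ncol(p$probs), integer(1))
    .assert(all(widths <= 500), "motif wider than structural peak width",
            "mgatlas_config_error")
    maxIC <- vapply(pwms, function(p) which.max(p$ic), integer(1))
    ## write consensus at every occurrence; motif placed so its
    ## max-IC position sits on the occurrence centre. Around causal
    ## (allelic) sites the flanking sequence is rewritten over {A, T}
    ## first: neither strand can then present a spurious core-position
    ## match, so the planted allele has an unambiguous best alignment.
    occ$motif_start <- NA_integer_
    for (r in seq_len(nrow(occ))) {
        pw <- pwms[[occ$tf[r]]]
        w <- ncol(pw$probs)
        cons <- bases[apply(pw$probs, 2L, which.max)]
        if (occ$site_type[r] == "causal") {
            lo <- occ$center[r] - (w + 35L)
            hi <- occ$center[r] + (w + 35L)
            seqChar[lo:hi] <- sample(c("A", "T"), hi - lo + 1L,
                                     replace = TRUE)
        }
        startPos <- occ$center[r] - (maxIC[occ$tf[r]] - 1L)
        seqChar[startPos:(startPos + w - 1L)] <- cons
        occ$motif_start[r] <- startPos
    }
    truth$motifOccurrences <- occ

    ## allelic variants at causal positions
    variants <- truth$variants
    direction <- ifelse(seq_len(config$nLoci) %% 2L == 1L,
                        "disrupt", "create")
    allelic <- data.frame(variant_id = character(0), tf = character(0),
                          direction = character(0))
    for (i in seq_len(config$nLoci)) {
        lid <- truth$loci$locus_id[i]
        tf <- truth$loci$tf[i]
        pw <- pwms[[tf]]
        pos <- variants$pos[variants$locus_id == lid & variants$causal]
        col <- pw$probs[, maxIC[tf]]
        consBase <- bases[which.max(col)]
        ## among the (tied) minimal-probability bases pick one whose
        ## complement is not the core base, so the minus strand cannot
        ## recover the match
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        cand <- bases[col <= min(col) + 1e-12]
        cand <- cand[cand != consBase & comp[cand] != consBase]
        worstBase <- cand[1]
        if (direction[i] == "disrupt") {
            seqChar[pos] <- consBase; refB <- consBase; altB <- worstBase
        } else {
            seqChar[pos] <- worstBase; refB <- worstBase; altB <- consBase
        }
        variants$ref[variants$locus_id == lid & variants$causal] <- refB
        variants$alt[variants$locus_id == lid & variants$causal] <- altB
        allelic <- rbind(allelic,
                         data.frame(variant_id = variants$variant_id[
                             variants$locus_id == lid & variants$causal],
                             tf = tf, direction = direction[i]))
    }
    plain <- !variants$causal
    variants$ref[plain] <- seqChar[variants$pos[plain]]
    variants$alt[plain] <- vapply(variants$ref[plain], function(b)
        sample(setdiff(bases, b), 1L), character(1))

    genome <- Biostrings::DNAStringSet(
        stats::setNames(paste(seqChar, collapse = ""), config$chrom))
    truth$variants <- variants
    truth$allelic <- allelic
    list(genome = genome, variants = variants, truth = truth)
}

#' Generate Tn5 fragments with planted footprints
#'
#' For each motif-carrying peak (or every peak with
#' `fragmentPeaks = "all"`) and each cell in which it is open, fragment
#' cut sites are sampled proportionally to the smooth positional Tn5 bias
#' field; in bound cell types the planted footprint multiplies the
#' centre (+/-10 bp) insertion probability by the protection factor and
#' the flanking region by the occupancy boost.
#'
#' @inheritParams generateSequencesAndVariants
#' @param bundle the [MultiomeBundle-class] from the same generation.
#' @return list with `fragments` (data.frame chrom/start/end/barcode/count,
#'   sorted by start, 0-based half-open) and updated `truth` (fragment
#'   tally under `$emittedFragments`).
#' @export
generateFragments <- function(config, bundle, truth, seed) {
    stopifnot(inherits(config, "SimConfig"), inherits(truth, "SyntheticTruth"))
    set.seed(seed + 3000L)
    atac <- atacCounts(bundle)
    pk <- peakRanges(bundle)
    bcs <- rownames(cellMeta(bundle))
    ctype <- as.character(cellMeta(bundle)$cell_type)
    occ <- truth$motifOccurrences
    sitePeaks <- unique(occ$peak)
    peaksToDo <- if (config$fragmentPeaks == "all") seq_along(pk)
                 else sitePeaks
    out <- vector("list", length(peaksToDo))
    for (k in seq_along(peaksToDo)) {
        j <- peaksToDo[k]
        cells <- which(atac[j, ] > 0)
        if (!length(cells)) next
        s1 <- GenomicRanges::start(pk)[j]      # 1-based
        e1 <- GenomicRanges::end(pk)[j]
        posRange <- s1:e1
        w <- .biasAt(posRange, truth$bias)
        rows <- occ[occ$peak == j, , drop = FALSE]
        boundTypes <- unique(unlist(rows$bound_types))
        wBound <- w
        if (length(boundTypes) && nrow(rows)) {
            for (r in seq_len(nrow(rows))) {
                if (!length(rows$bound_types[[r]])) next
                d <- abs(posRange - rows$center[r])
                wBound[d <= 10] <- wBound[d <= 10] * config$protectionFactor
                fl <- d > 10 & d <= 150
                wBound[fl] <- wBound[fl] * config$fpFlankBoost
            }
        }
        isBound <- ctype[cells] %in% boundTypes
        nf <- stats::rpois(length(cells), config$fragMeanPerOpen)
        emit <- function(cellIdx, weights) {
            tot <- sum(nf[cellIdx])
            if (!tot) return(NULL)
            cuts1 <- sample(posRange, tot, replace = TRUE, prob = weights)
            cuts2 <- sample(posRange, tot, replace = TRUE, prob = weights)
            data.frame(chrom = as.character(GenomicRanges::seqnames(pk)[j]),
                       start = pmin(cuts1, cuts2) - 1L,       # to 0-based
                       end = pmax(cuts1, cuts2),              # half-open
                       barcode = rep(bcs[cells[cellIdx]], nf[cellIdx]),
                       count = 1L)
        }
        out[[k]] <- rbind(emit(which(isBound), wBound),
                          emit(which(!isBound), w))
    }
    frags <- do.call(rbind, out)
    if (is.null(frags))
        frags <- data.frame(chrom = character(), start = integer(),
                            end = integer(), barcode = character(),
                            count = integer())
    frags$end[frags$end <= frags$start] <-
        frags$start[frags$end <= frags$start] + 1L
    frags <- frags[order(frags$chrom, frags$start, frags$end,
                         frags$barcode), , drop = FALSE]
    rownames(frags) <- NULL
    truth$emittedFragments <- nrow(frags)
    list(fragments = frags, truth = truth)
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper running [generateMultiome()],
#' [generateSequencesAndVariants()], [generateGwas()] and
#' [generateFragments()] with one seed.
#'
#' @inheritParams generateMultiome
#' @param withFragments,withSequences disable the heavier stages if the
#'   caller only needs matrices.
#' @return list with `bundle`, `truth`, `gwas`, `genome`, `variants`,
#'   `fragments`, `pwms`.
#' @export
generateDataset <- function(config, seed, withFragments = TRUE,
                            withSequences = TRUE) {
    gm <- generateMultiome(config, seed)
    pwms <- .builtinMotifs(config$background)
    genome <- NULL; variants <- gm$truth$variants
    if (withSequences) {
        sq <- generateSequencesAndVariants(config, seed, gm$truth, pwms)
        gm$truth <- sq$truth; genome <- sq$genome; variants <- sq$variants
    }
    gw <- generateGwas(config, seed, gm$truth)
    gm$truth <- gw$truth
    frags <- NULL
    if (withFragments) {
        fr <- generateFragments(config, gm$bundle, gm$truth, seed)
        gm$truth <- fr$truth; frags <- fr$fragments
    }
    list(bundle = gm$bundle, truth = gm$truth, gwas = gw$gwas,
         genome = genome, variants = variants, fragments = frags,
         pwms = pwms)
}
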