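test_that("metacell count and grouping follow the contract", {
    ds <- getFixture("baseNoSeq")
    n <- ncol(atacCounts(ds$bundle))
    mc <- makeMetacells(ds$bundle, k = 25)
    expect_identical(ncol(mc$atac), n %/% 25L)
    sizes <- table(mc$assign)
    expect_true(all(sizes == 25))
    ## groups are disjoint and counts are sums of members
    g1 <- which(mc$assign == 1)
    expect_equal(mc$atac[, 1],
                 as.numeric(Matrix::rowSums(
                     atacCounts(ds$bundle)[, g1, drop = FALSE])))
})

test_that("metacells do not mix planted cell-type clusters", {
    ds <- getFixture("baseNoSeq")
    mc <- makeMetacells(ds$bundle, k = 25)
    ct <- as.character(cellMeta(ds$bundle)$category)
    purity <- vapply(seq_len(ncol(mc$atac)), function(g) {
        max(table(ct[which(mc$assign == g)])) / 25
    }, numeric(1))
    expect_gt(mean(purity), 0.9)
})

test_that("co-accessibility is a bounded symmetric correlation", {
    ds <- getFixture("baseNoSeq")
    mc <- makeMetacells(ds$bundle, k = 25)
    coa <- coaccessibility(mc$atac, peakRanges(ds$bundle))
    expect_true(all(coa$score >= -1 - 1e-12 & coa$score <= 1 + 1e-12))
    expect_true(all(coa$peak_i < coa$peak_j))
    expect_true(all(coa$distance <= 5e5))
    ## a duplicated peak is perfectly co-open with itself
    dup <- rbind(mc$atac[1:50, ], mc$atac[1, , drop = FALSE])
    pk <- c(peakRanges(ds$bundle)[1:50],
            GenomicRanges::shift(peakRanges(ds$bundle)[1], 10))
    coaD <- coaccessibility(dup, pk)
    pair <- coaD[coaD$peak_i == 1 & coaD$peak_j == 51, ]
    expect_equal(pair$score, 1, tolerance = 1e-12)
})

test_that("planted co-regulated peak trios are strongly co-accessible", {
    ds <- getFixture("baseNoSeq")
    mc <- makeMetacells(ds$bundle, k = 25)
    coa <- coaccessibility(mc$atac, peakRanges(ds$bundle))
    trio <- ds$truth$trioPeaks[[1]]
    cmb <- utils::combn(sort(trio), 2)
    for (i in seq_len(ncol(cmb))) {
        sc <- coa$score[coa$peak_i == cmb[1, i] & coa$peak_j == cmb[2, i]]
        expect_gt(sc, 0.5)
    }
    ## and they land in one module
    mods <- detectModules(coa)
    expect_identical(length(unique(mods$module_id[
        match(trio, mods$peak)])), 1L)
})

test_that("module detection handles disjoint pairs and singletons", {
    pairs <- data.frame(peak_i = c(1L, 3L, 1L), peak_j = c(2L, 4L, 5L),
                        score = c(0.9, 0.8, 0.1),
                        distance = c(100, 100, 100))
    mods <- detectModules(pairs)
    expect_identical(length(unique(mods$module_id)), 2L)
    expect_false(5L %in% mods$peak)       # edge below cutoff
    expect_setequal(mods$peak[mods$module_id == 1], c(1L, 2L))
    expect_setequal(mods$peak[mods$module_id == 2], c(3L, 4L))
    empty <- detectModules(pairs[pairs$score > 1, ])
    expect_identical(nrow(empty), 0L)
})

test_that("null co-accessibility stays below the module cutoff", {
    ## independent Bernoulli peaks aggregated into 200 units
    set.seed(10)
    fails <- 0L
    for (s in 1:10) {
        m <- matrix(rbinom(40 * 200, 25, 0.3), nrow = 40)
        pk <- GenomicRanges::GRanges("chrS",
            IRanges::IRanges(seq_len(40) * 2000, width = 400))
        coa <- coaccessibility(m, pk)
        if (any(abs(coa$score) >= 0.32)) fails <- fails + 1L
    }
    expect_lte(fails, 2L)
})

test_that("peak-gene links recover planted effects without false positives", {
    ds <- getFixture("homog")
    links <- linkPeaksToGenes(atacCounts(ds$bundle), rnaCounts(ds$bundle),
                              peakRanges(ds$bundle), geneModels(ds$bundle))
    truthKey <- unique(paste(ds$truth$links$peak,
                             ds$truth$links$gene_index))
    retKey <- paste(links$peak[links$retained],
                    links$gene_index[links$retained])
    expect_gte(mean(truthKey %in% retKey), 0.8)
    expect_lte(mean(!(retKey %in% truthKey)), 0.10)
    expect_true(all(links$p[links$retained] < 0.05))
    expect_true(all(abs(links$r[links$retained]) > 0.05))
})

test_that("zero-variance genes are skipped with an explicit record", {
    ds <- getFixture("homog")
    rna <- rnaCounts(ds$bundle)
    g <- ds$truth$links$gene_index[1]
    rna[g, ] <- 5   # nonzero everywhere but constant
    links <- linkPeaksToGenes(atacCounts(ds$bundle), rna,
                              peakRanges(ds$bundle), geneModels(ds$bundle))
    expect_false(g %in% links$gene_index)
    expect_gte(attr(links, "skipped"), 1L)
})

test_that("the distance window bounds which pairs are tested", {
    ds <- getFixture("homog")
    links <- linkPeaksToGenes(atacCounts(ds$bundle), rnaCounts(ds$bundle),
                              peakRanges(ds$bundle), geneModels(ds$bundle),
                              window = 2e5)
    expect_true(all(abs(links$tss_distance) <= 2e5))
    ## nesting: tested pairs and retained links grow with the window
    wide <- linkPeaksToGenes(atacCounts(ds$bundle), rnaCounts(ds$bundle),
                             peakRanges(ds$bundle), geneModels(ds$bundle),
                             window = 6e5)
    key <- function(l, retained = FALSE) {
        l <- if (retained) l[l$retained, ] else l
        paste(l$peak, l$gene_index)
    }
    expect_true(all(key(links) %in% key(wide)))
    expect_true(all(key(links, TRUE) %in% key(wide, TRUE)))
})

test_that("a planted 3 Mb link is recovered only at the 5 Mb window", {
    cfg <- simConfig(cellsPerType = c(AT2 = 4000L), nPeaks = 250,
                     nGenes = 70, nLoci = 2, variantsPerLocus = 20,
                     nFootprintSites = 5, nLinks = 20L, depthLogSD = 0,
                     peakSpacing = 20000L,
                     linkMinDist = 2.6e6, linkMaxDist = 3.4e6)
    ds <- generateDataset(cfg, seed = 21, withFragments = FALSE,
                          withSequences = FALSE)
    far <- ds$truth$links[ds$truth$links$kind == "random", ]
    expect_true(all(abs(
        (GenomicRanges::start(peakRanges(ds$bundle))[far$peak] +
         GenomicRanges::end(peakRanges(ds$bundle))[far$peak]) / 2 -
        geneModels(ds$bundle)$tss[far$gene_index]) > 2e6))
    runWin <- function(w)
        linkPeaksToGenes(atacCounts(ds$bundle), rnaCounts(ds$bundle),
                         peakRanges(ds$bundle), geneModels(ds$bundle),
                         window = w)
    k <- function(l) paste(l$peak[l$retained], l$gene_index[l$retained])
    farKey <- paste(far$peak, far$gene_index)
    expect_false(any(farKey %in% k(runWin(1e6))))
    expect_false(any(farKey %in% k(runWin(2e6))))
    expect_gte(mean(farKey %in% k(runWin(5e6))), 0.8)
})

test_that("level assignment covers the six predicates on a hand-built case", {
    genes <- mgatlas:::.geneModelGRanges(data.frame(
        gene_id = c("G1", "G2"), gene_name = c("g1", "g2"),
        chrom = "chrS", strand = "+", tss = c(10000L, 50000L),
        tes = c(15000L, 56000L)))
    ## peaks: 1 promoter of G1; 2 module-mate of 3; 3 query; 4 linked
    modules <- data.frame(module_id = 1L, peak = c(1L, 3L))
    pairs <- data.frame(peak_i = c(3L, 3L), peak_j = c(1L, 4L),
                        score = c(0.6, 0.55), distance = 1)
    promMap <- data.frame(peak = 1L, gene_index = 1L)
    links <- data.frame(peak = c(4L, 3L), gene_id = c("G2", "G2"),
                        gene_index = 2L, r = 0.4, z = 4, p = 1e-4,
                        tss_distance = 100, retained = c(TRUE, TRUE))
    rec <- assignLinkageLevel(3L, modules, pairs, promMap, links, genes)
    ## G1: module mate promoter (L1) + direct promoter pair (L2) -> max 2
    expect_identical(rec$level[rec$gene_id == "G1"], 2L)
    ## G2: direct pair with linked peak (L5) + self link (L6) -> max 6
    expect_identical(rec$level[rec$gene_id == "G2"], 6L)
    expect_match(rec$evidence[rec$gene_id == "G2"], "L6:self_link")

    ## a promoter query with no other evidence is level 3
    rec3 <- assignLinkageLevel(1L, modules[0, ], pairs[0, ], promMap,
                               links[0, ], genes)
    expect_identical(rec3$level, 3L)
    ## no evidence at all -> no records
    rec0 <- assignLinkageLevel(9L, modules, pairs, promMap, links, genes)
    expect_identical(nrow(rec0), 0L)
})
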