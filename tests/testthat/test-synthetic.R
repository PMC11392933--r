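test_that("generation is fully deterministic given (config, seed)", {
    cfg <- simConfig(cellsPerType = uniformCellsPerType(10L), nPeaks = 300,
                     nGenes = 60, nLoci = 2, variantsPerLocus = 15,
                     nFootprintSites = 10)
    a <- generateDataset(cfg, seed = 3)
    b <- generateDataset(cfg, seed = 3)
    expect_identical(as.matrix(atacCounts(a$bundle)),
                     as.matrix(atacCounts(b$bundle)))
    expect_identical(as.matrix(rnaCounts(a$bundle)),
                     as.matrix(rnaCounts(b$bundle)))
    expect_identical(a$truth$gwas$z, b$truth$gwas$z)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$fragments, b$fragments)
})

test_that("zero leak probability confines accessibility to pattern types", {
    cfg <- simConfig(cellsPerType = uniformCellsPerType(10L), nPeaks = 300,
                     nGenes = 60, nLoci = 2, variantsPerLocus = 15,
                     nFootprintSites = 10, pOpenLow = 0, pOpenHigh = 1,
                     depthLogSD = 0)
    ds <- generateDataset(cfg, seed = 4, withFragments = FALSE,
                          withSequences = FALSE)
    atac <- atacCounts(ds$bundle)
    ct <- as.character(cellMeta(ds$bundle)$cell_type)
    for (j in sample(nrow(atac), 40)) {
        open <- ct[which(atac[j, ] > 0)]
        expect_true(all(open %in% ds$truth$peakPattern[[j]]))
        ## pOpenHigh = 1, unit depth: every pattern-type cell is open
        expect_identical(sort(unique(open)),
                         sort(ds$truth$peakPattern[[j]]))
    }
})

test_that("empirical open rate matches the depth-adjusted parameters", {
    ds <- getFixture("baseNoSeq")
    cfg <- ds$truth$config
    atac <- atacCounts(ds$bundle)
    ct <- as.character(cellMeta(ds$bundle)$cell_type)
    depth <- ds$truth$depth
    ## pool matching (cell, peak) entries over a sample of peaks
    set.seed(1)
    js <- sample(nrow(atac), 100)
    nOpen <- 0; expOpen <- 0; varOpen <- 0
    for (j in js) {
        match <- ct %in% ds$truth$peakPattern[[j]]
        p <- pmin(1, cfg$pOpenHigh * depth[match])
        nOpen <- nOpen + sum(atac[j, match] > 0)
        expOpen <- expOpen + sum(p)
        varOpen <- varOpen + sum(p * (1 - p))
    }
    expect_lt(abs(nOpen - expOpen), 3 * sqrt(varOpen))
})

test_that("AR(1) GWAS z-scores have the stated LD structure", {
    ## rho = 0: non-lead variants have r2_to_lead = 0
    cfg0 <- simConfig(cellsPerType = uniformCellsPerType(5L), nPeaks = 200,
                      nGenes = 40, nLoci = 3, variantsPerLocus = 20,
                      nFootprintSites = 5, ldRho = 0)
    g0 <- generateGwas(cfg0, seed = 9)$gwas
    expect_true(all(g0$r2_to_lead[!g0$is_lead] == 0))
    expect_true(all(g0$r2_to_lead[g0$is_lead] == 1))

    ## rho = 0.95, strong causal z: the lead is the causal variant and
    ## the adjacent variant has r2 = 0.95^2 = 0.9025 (closed form)
    cfg1 <- simConfig(cellsPerType = uniformCellsPerType(5L), nPeaks = 200,
                      nGenes = 40, nLoci = 5, variantsPerLocus = 20,
                      nFootprintSites = 5, ldRho = 0.95, causalZ = 50)
    ds1 <- generateMultiome(cfg1, seed = 9)
    g1 <- generateGwas(cfg1, seed = 9, ds1$truth)
    for (l in unique(g1$gwas$locus_id)) {
        sub <- g1$gwas[g1$gwas$locus_id == l, ]
        ci <- ds1$truth$variants$causal_index[
            ds1$truth$variants$locus_id == l][1]
        expect_identical(which(sub$is_lead), as.integer(ci))
        expect_equal(sub$r2_to_lead[ci + 1L], 0.9025, tolerance = 1e-12)
    }
})

test_that("lead z stays at null scale when no causal signal is planted", {
    cfg <- simConfig(cellsPerType = uniformCellsPerType(5L), nPeaks = 300,
                     nGenes = 80, nLoci = 50, variantsPerLocus = 20,
                     nFootprintSites = 5, ldRho = 0, causalZ = 1e-9)
    g <- generateGwas(cfg, seed = 2)$gwas
    zl <- abs(g$z[g$is_lead])
    expect_true(all(is.finite(zl)))
    ## max of 20 iid N(0,1): mean ~ 1.87; far below genome-wide scale
    expect_lt(mean(zl), 3)
    expect_gt(mean(zl), 1.2)
})

test_that("planted allelic variants disrupt or restore the motif consensus", {
    ds <- getFixture("base")
    al <- ds$truth$allelic
    expect_true(nrow(al) >= 2)
    for (i in seq_len(nrow(al))) {
        v <- ds$truth$variants[ds$truth$variants$variant_id ==
                               al$variant_id[i], ]
        pred <- allelicEffect(ds$pwms[[al$tf[i]]], v, ds$genome)
        if (al$direction[i] == "disrupt") expect_lt(pred$delta, 0)
        else expect_gt(pred$delta, 0)
        expect_true(pred$allelic)
    }
})

test_that("variants outside motifs are not allelic for planted TFs", {
    ds <- getFixture("base")
    plain <- ds$truth$variants[!ds$truth$variants$causal, ]
    set.seed(2)
    plain <- plain[sample(nrow(plain), 12), ]
    preds <- allelicEffectsAll(ds$pwms, plain, ds$genome)
    expect_true(mean(preds$allelic) < 0.05)
})

test_that("fragment protection suppresses centre insertions by the stated factor", {
    cfg <- footprintConfig(protectionFactor = 0.2, fpFlankBoost = 1)
    ds <- generateDataset(cfg, seed = 6, withSequences = FALSE)
    occ <- ds$truth$motifOccurrences
    occ <- occ[occ$site_type == "footprint" & occ$tf == "IRF8", ]
    bound <- "Dendritic"
    bcs <- rownames(cellMeta(ds$bundle))[
        cellMeta(ds$bundle)$cell_type == bound]
    fr <- ds$fragments[ds$fragments$barcode %in% bcs, ]
    cuts <- c(fr$start + 1L, fr$end)
    centerN <- 0; flankN <- 0
    for (m in occ$center) {
        d <- abs(cuts - m)
        centerN <- centerN + sum(d <= 10)
        flankN <- flankN + sum(d > 10 & d <= 100)
    }
    expect_gt(centerN + flankN, 2000)
    ratio <- (centerN / 21) / (flankN / 180)
    expect_gt(ratio, 0.1)
    expect_lt(ratio, 0.32)

    ## protection factor 1: centre and flank rates agree
    cfg1 <- footprintConfig(protectionFactor = 1, fpFlankBoost = 1)
    ds1 <- generateDataset(cfg1, seed = 6, withSequences = FALSE)
    fr1 <- ds1$fragments[ds1$fragments$barcode %in% bcs, ]
    cuts1 <- c(fr1$start + 1L, fr1$end)
    centerN1 <- 0; flankN1 <- 0
    for (m in occ$center) {
        d <- abs(cuts1 - m)
        centerN1 <- centerN1 + sum(d <= 10)
        flankN1 <- flankN1 + sum(d > 10 & d <= 100)
    }
    ratio1 <- (centerN1 / 21) / (flankN1 / 180)
    expect_gt(ratio1, 0.8)
    expect_lt(ratio1, 1.25)
})

test_that("every emitted fragment overlaps a peak", {
    ds <- getFixture("footprint")
    fr <- GenomicRanges::GRanges(ds$fragments$chrom,
        IRanges::IRanges(ds$fragments$start + 1L, ds$fragments$end))
    expect_true(all(IRanges::overlapsAny(fr, peakRanges(ds$bundle))))
})

test_that("configs violating structural constraints are rejected", {
    expect_error(simConfig(nPeaks = 50L, nLoci = 10L,
                           nFootprintSites = 30L),
                 class = "mgatlas_config_error")
    expect_error(simConfig(ldRho = 1), class = "mgatlas_config_error")
    expect_error(simConfig(protectionFactor = 2),
                 class = "mgatlas_config_error")
})
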