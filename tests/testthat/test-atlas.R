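sch <- defaultCategoryScheme()

detRow <- function(types) {
    row <- stats::setNames(rep(FALSE, length(schemeCellTypes(sch))),
                           schemeCellTypes(sch))
    row[types] <- TRUE
    row
}

test_that("category sizes and strict thresholds follow the scheme", {
    expect_identical(unname(categorySizes(sch)), c(8L, 7L, 4L, 4L))
    expect_equal(categoryThreshold(categorySizes(sch)),
                 c(epithelial = 6, immune = 5.25, endothelial = 3,
                   stromal = 3))
})

test_that("the worked multi-category example assigns epithelial only", {
    row <- detRow(c("AT2", "AT1", "Club", "Ciliated", "Goblet", "Basal",
                    "AT1_AT2",          # 7 epithelial
                    "Macrophage", "Tcell",   # 2 immune
                    "Capillary",             # 1 endothelial
                    "Fibroblast"))           # 1 stromal
    expect_identical(categoryAssignment(row, sch), "epithelial")
})

test_that("single-category detections assign that category directly", {
    expect_identical(categoryAssignment(detRow(c("Tcell", "NK")), sch),
                     "immune")
    expect_identical(categoryAssignment(detRow("Mesothelial"), sch),
                     "stromal")
})

test_that("no category above threshold leaves the peak shared", {
    row <- detRow(c("AT2", "AT1", "Tcell", "NK", "Capillary",
                    "Fibroblast"))
    expect_identical(categoryAssignment(row, sch), character(0))
})

test_that("several categories can pass their thresholds together", {
    row <- detRow(c("AT2", "AT1", "Club", "Ciliated", "Goblet", "Basal",
                    "AT1_AT2",                               # 7 of 8 epi
                    "Capillary", "Vein", "Artery", "Lymphatic"))  # 4 of 4
    expect_setequal(categoryAssignment(row, sch),
                    c("epithelial", "endothelial"))
})

test_that("assignment depends only on per-category counts (monotone)", {
    set.seed(7)
    for (i in 1:50) {
        types <- sample(schemeCellTypes(sch), sample(2:23, 1))
        row <- detRow(types)
        got <- categoryAssignment(row, sch)
        ## adding one more detection never removes its own category
        extra <- setdiff(schemeCellTypes(sch), types)
        if (length(extra)) {
            t2 <- extra[1]
            got2 <- categoryAssignment(detRow(c(types, t2)), sch)
            g <- unname(sch@map[t2])
            expect_true(all(setdiff(got, g) %in% c(got2, g)) ||
                        length(unique(sch@map[types])) == 1L)
        }
    }
})

test_that("degenerate detection rows are rejected", {
    expect_error(categoryAssignment(detRow(character(0)), sch),
                 class = "mgatlas_validation_error")
    row <- c(detRow("AT2"), Unknown = TRUE)
    expect_error(categoryAssignment(row, sch),
                 class = "mgatlas_validation_error")
    expect_error(cellTypeSpecificity(detRow(character(0))),
                 class = "mgatlas_validation_error")
})

test_that("cell-type specificity requires a single detecting type", {
    expect_identical(cellTypeSpecificity(detRow("AT2")), "AT2")
    expect_true(is.na(cellTypeSpecificity(detRow(c("AT2", "AT1")))))
})

test_that("genomic context labels follow the stated priority", {
    gdf <- data.frame(gene_id = c("GA", "GB"), gene_name = c("A", "B"),
                      chrom = "chr1", strand = c("+", "+"),
                      tss = c(50000L, 9000L), tes = c(70000L, 12000L),
                      exons = c("50000-51000;60000-61000", "9000-9500"))
    genes <- mgatlas:::.geneModelGRanges(gdf)
    peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(49900, 55000, 60100, 100000, 11000),
        c(50100, 55400, 60400, 100400, 11400)))
    ctx <- annotateGenomicContext(peaks, genes)
    ## TSS-centred peak; intron; exon; 30 kb beyond any span; gene-B body
    ## that also lies in gene-B's promoter window -> promoter wins
    expect_identical(ctx, c("promoter", "intronic", "exonic",
                            "intergenic", "promoter"))
})

test_that("a peak overlapping an exon of A and the promoter of B is a promoter", {
    gdf <- data.frame(gene_id = c("GA", "GB"), gene_name = c("A", "B"),
                      chrom = "chr1", strand = "+",
                      tss = c(1000L, 22000L), tes = c(21000L, 30000L),
                      exons = c("1000-2000;19500-20500", "22000-23000"))
    genes <- mgatlas:::.geneModelGRanges(gdf)
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(19900, 20200))
    expect_identical(annotateGenomicContext(pk, genes), "promoter")
})

test_that("planted patterns are recovered exactly without leak accessibility", {
    cfg <- simConfig(cellsPerType = uniformCellsPerType(15L), nPeaks = 300,
                     nGenes = 60, nLoci = 2, variantsPerLocus = 15,
                     nFootprintSites = 10, pOpenLow = 0, pOpenHigh = 1,
                     depthLogSD = 0)
    ds <- generateDataset(cfg, seed = 8, withFragments = FALSE,
                          withSequences = FALSE)
    det <- detectPeaksPerType(ds$bundle, minFrac = 0, minCells = 1)
    truthDet <- t(vapply(ds$truth$peakPattern,
                         function(p) colnames(det) %in% p,
                         logical(ncol(det))))
    expect_identical(unname(det), unname(truthDet))
})

test_that("gene activity sums accessibility over promoter and gene body", {
    b <- tinyBundle()
    ## windows: G1 (+): [tss-2000, tes] = [-1000 -> 1, 3000]
    ##          G2 (-): [tes, tss+2000] = [4000, 7000]
    act <- geneActivity(b)
    ## both peaks fall inside G1's [tss - 2000, tes] window
    expect_equal(as.numeric(act["G1", ]), c(1, 1, 2))
    ## G2 (- strand): window [tes, tss + 2000] = [4000, 7000]: no peaks
    expect_equal(as.numeric(act["G2", ]), c(0, 0, 0))

    ## fragment route: one fragment fully inside the G1 body -> 1,
    ## one inside the G2 promoter-side window, one outside everything
    fr <- data.frame(chrom = "chr1", start = c(1499L, 4049L, 9000L),
                     end = c(1600L, 4150L, 9100L),
                     barcode = c("bc1", "bc2", "bc1"), count = 1L)
    actF <- geneActivity(fr, genes = geneModels(b),
                         barcodes = rownames(cellMeta(b)))
    expect_equal(as.numeric(actF["G1", ]), c(1, 0, 0))
    expect_equal(as.numeric(actF["G2", ]), c(0, 1, 0))
})

test_that("marker gene expression and gene activity agree across types", {
    ds <- getFixture("baseNoSeq")
    b <- ds$bundle
    act <- geneActivity(b)
    rna <- rnaCounts(b)
    ct <- as.character(cellMeta(b)$cell_type)
    types <- unique(ct)
    ## TF marker genes: expression and promoter-peak accessibility are
    ## both planted in the same cell types
    gset <- which(geneModels(b)$gene_name %in%
                  names(ds$truth$tfPromoterPeaks))
    cors <- vapply(gset, function(g) {
        pe <- vapply(types, function(t) mean(rna[g, ct == t] > 0),
                     numeric(1))
        pa <- vapply(types, function(t) mean(act[g, ct == t] > 0),
                     numeric(1))
        suppressWarnings(cor(pe, pa))
    }, numeric(1))
    expect_gt(mean(cors > 0.5, na.rm = TRUE), 0.5)
})

test_that("the atlas container validates and summarizes consistently", {
    ds <- getFixture("baseNoSeq")
    atlas <- buildPeakAtlas(ds$bundle)
    expect_s4_class(atlas, "PeakAtlas")
    det <- detectionMatrix(atlas)
    expect_true(all(rowSums(det) >= 1))
    one <- rowSums(det) == 1
    expect_identical(unname(one), !is.na(specificCellType(atlas)))
    tab <- atlasTable(atlas)
    expect_identical(nrow(tab), length(peakRanges(atlas)))
    expect_true(all(tab$context %in% c("promoter", "exonic", "intronic",
                                       "intergenic")))
})
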