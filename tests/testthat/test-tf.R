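simplePWM <- function(width = 4, name = "T1") {
    counts <- matrix(2, 4, width, dimnames = list(c("A", "C", "G", "T"),
                                                  NULL))
    cons <- rep_len(c(1L, 3L, 4L, 2L), width)   # A G T C ...
    counts[cbind(cons, seq_len(width))] <- 30
    newPWM(name, counts)
}

consensusOf <- function(pwm)
    paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)],
          collapse = "")

antiConsensusOf <- function(pwm)
    paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.min)],
          collapse = "")

test_that("consensus scores 1 and the anti-consensus scores 0", {
    pwm <- simplePWM(6)
    expect_equal(relativeScore(pwm, consensusOf(pwm))$score, 1,
                 tolerance = 1e-12)
    expect_equal(relativeScore(pwm, antiConsensusOf(pwm),
                               strand = "+")$score, 0, tolerance = 1e-12)
})

test_that("scoring is strand-symmetric", {
    pwm <- simplePWM(7)
    set.seed(3)
    for (i in 1:10) {
        seq <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                     collapse = "")
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
        a <- relativeScore(pwm, seq)
        b <- relativeScore(pwm, rc)
        expect_equal(a$score, b$score, tolerance = 1e-12)
        expect_equal(a$match_p, b$match_p, tolerance = 1e-12)
    }
})

test_that("match p-values equal the exhaustive window enumeration", {
    pwm <- simplePWM(4)
    weight <- sweep(pwm$probs, 2, pwm$ic, `*`)
    bases <- c("A", "C", "G", "T")
    grid <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    raws <- apply(grid, 1, function(b) sum(weight[cbind(b, 1:4)]))
    set.seed(4)
    for (i in 1:10) {
        seq <- paste(sample(bases, 4), collapse = "")
        got <- relativeScore(pwm, seq, strand = "+")
        rawBest <- sum(weight[cbind(match(strsplit(seq, "")[[1]], bases),
                                    1:4)])
        expect_equal(got$match_p, mean(raws >= rawBest - 1e-12),
                     tolerance = 1e-12)
    }
})

test_that("windows containing N are skipped and bad characters rejected", {
    pwm <- simplePWM(4)
    expect_error(relativeScore(pwm, "ACGTXACGT"),
                 class = "mgatlas_format_error")
    out <- relativeScore(pwm, paste0("NN", consensusOf(pwm), "NN"))
    expect_equal(out$score, 1, tolerance = 1e-12)
    allN <- relativeScore(pwm, "NNNN")
    expect_true(is.na(allN$score))
})

test_that("allelic deltas are antisymmetric under swapping ref and alt", {
    ds <- getFixture("base")
    v <- ds$truth$variants[ds$truth$variants$causal, ][1, ]
    pwm <- ds$pwms[[ds$truth$allelic$tf[
        ds$truth$allelic$variant_id == v$variant_id]]]
    fwd <- allelicEffect(pwm, v, ds$genome)
    ## swap: mutate the genome to the alt allele, then score alt->ref
    g2 <- ds$genome
    Biostrings::subseq(g2[[v$chrom]], v$pos, v$pos) <-
        Biostrings::DNAString(v$alt)
    v2 <- v; v2$ref <- v$alt; v2$alt <- v$ref
    rev <- allelicEffect(pwm, v2, g2)
    expect_equal(fwd$delta, -rev$delta, tolerance = 1e-12)
})

test_that("degenerate identical alleles give delta 0 and no allelic flag", {
    ds <- getFixture("base")
    v <- ds$truth$variants[1, ]
    v$alt <- v$ref
    pred <- allelicEffect(ds$pwms[[1]], v, ds$genome)
    expect_equal(pred$delta, 0, tolerance = 1e-12)
    expect_false(pred$allelic)
})

test_that("a reference allele mismatch is reported with its position", {
    ds <- getFixture("base")
    v <- ds$truth$variants[1, ]
    v$ref <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
    expect_error(allelicEffect(ds$pwms[[1]], v, ds$genome),
                 as.character(v$pos), class = "mgatlas_validation_error")
})

test_that("abundance requires both the expression fraction and the quantile", {
    ## universe of 4 pairs with means ~ (1,2,3,4): only the pair above
    ## the 75th percentile (3.25) and expressed in > 50% can be abundant
    n <- 200
    counts <- rbind(TF1 = rep(c(0L, 2L), each = n / 2),
                    TF2 = rep(c(0L, 8L), c(n * 0.4, n * 0.6)),
                    TF3 = rep(c(0L, 30L), c(n * 0.4, n * 0.6)),
                    TF4 = rep(c(0L, 150L), c(n * 0.4, n * 0.6)))
    rna <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    universe <- data.frame(tf = paste0("TF", 1:4), cell_type = "X")
    ab <- tfAbundance(rna, rep("X", n), universe)
    q75 <- quantile(ab$mean_expr, 0.75, type = 7, names = FALSE)
    expect_identical(ab$abundant,
                     ab$frac_expressing > 0.5 & ab$mean_expr > q75)
    expect_identical(sum(ab$abundant), 1L)
    expect_identical(ab$tf[ab$abundant], "TF4")

    ## TF absent from the matrix: frac 0, not abundant, with a warning
    u2 <- rbind(universe, data.frame(tf = "TF9", cell_type = "X"))
    expect_warning(ab2 <- tfAbundance(rna, rep("X", n), u2), "TF9")
    expect_false(ab2$abundant[ab2$tf == "TF9"])
})

test_that("abundance flags are invariant to cell order and count scaling", {
    ds <- getFixture("baseNoSeq")
    rna <- rnaCounts(ds$bundle)
    rownames(rna) <- geneModels(ds$bundle)$gene_name
    ct <- as.character(cellMeta(ds$bundle)$cell_type)
    universe <- expand.grid(tf = names(ds$truth$tfPromoterPeaks),
                            cell_type = unique(ct),
                            stringsAsFactors = FALSE)
    a <- tfAbundance(rna, ct, universe)
    set.seed(5)
    perm <- sample(ncol(rna))
    b <- tfAbundance(rna[, perm], ct[perm], universe)
    expect_identical(a$abundant, b$abundant)
    ## doubling all counts rescales library sizes too: flags unchanged
    c <- tfAbundance(rna * 2, ct, universe)
    expect_identical(a$abundant, c$abundant)
})

test_that("the planted abundant TF is flagged in its bound cell type", {
    ds <- getFixture("baseNoSeq")
    rna <- rnaCounts(ds$bundle)
    rownames(rna) <- geneModels(ds$bundle)$gene_name
    ct <- as.character(cellMeta(ds$bundle)$cell_type)
    universe <- expand.grid(tf = c("IRF8", "CEBPB", "SPI1"),
                            cell_type = unique(ct),
                            stringsAsFactors = FALSE)
    ab <- tfAbundance(rna, ct, universe)
    expect_true(ab$abundant[ab$tf == "IRF8" & ab$cell_type == "Dendritic"])
    expect_true(ab$abundant[ab$tf == "CEBPB" &
                            ab$cell_type == "Macrophage"])
})

test_that("insufficient motif occurrences yield an unflagged profile", {
    ds <- getFixture("footprint")
    occ <- ds$truth$motifOccurrences
    occ$chrom <- ds$truth$config$chrom
    few <- occ[occ$tf == "IRF8", ][1:3, ]
    prof <- footprintProfile(ds$fragments, few[, c("chrom", "center")],
                             rownames(cellMeta(ds$bundle)))
    expect_true(prof$insufficient)
    expect_false(prof$detected)
})

test_that("planted footprints are detected in the bound cell type only", {
    ds <- getFixture("footprint")
    occ <- ds$truth$motifOccurrences
    occ$chrom <- ds$truth$config$chrom
    atlas <- buildPeakAtlas(ds$bundle)
    fp <- tfFootprints(ds$fragments, occ, atlas, ds$bundle, "IRF8")
    s <- fp$summary
    expect_true(s$detected[s$cell_type == "Dendritic"])
    expect_identical(s$cell_type[s$rank == 1], "Dendritic")
    prof <- fp$profiles$Dendritic
    expect_identical(length(prof$observed), 501L)
    expect_gt(prof$flank_enrichment, 0)
    expect_lt(prof$center_depletion, prof$flank_enrichment)
})
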