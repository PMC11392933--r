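#' @include AllClasses.R utils.R io.R
#' @importFrom Biostrings reverseComplement DNAString subseq
NULL

.BASES <- c("A", "C", "G", "T")

## Run code with a locally-derived RNG state; the caller's stream is
## untouched, so cached Monte Carlo p-value grids stay deterministic
## regardless of call order.
.withLocalSeed <- function(seed, expr) {
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

## Null distribution of raw IC-weighted window scores under the
## background composition. Exact by enumeration for width <= 10, Monte
## Carlo (1e5 draws, deterministically seeded from the motif) otherwise.
## Cached per motif; returns function(rawScore) -> P(S >= rawScore).
.pwmNullCache <- new.env(parent = emptyenv())

.pwmNullTail <- function(pwm, nDraws = 1e5) {
    key <- paste0(pwm$name, "_", ncol(pwm$probs), "_",
                  signif(sum(pwm$probs * pwm$ic), 10))
    if (!is.null(.pwmNullCache[[key]])) return(.pwmNullCache[[key]])
    w <- ncol(pwm$probs)
    weight <- sweep(pwm$probs, 2L, pwm$ic, `*`)
    bg <- pwm$background
    if (w <= 10) {
        nWin <- 4L^w
        scores <- numeric(nWin)
        logp <- numeric(nWin)
        idx0 <- seq_len(nWin) - 1L
        for (pos in seq_len(w)) {
            b <- (idx0 %/% 4L^(pos - 1L)) %% 4L + 1L
            scores <- scores + weight[b, pos]
            logp <- logp + log(bg[b])
        }
        o <- order(scores)
        scores <- scores[o]
        prob <- exp(logp[o])
    } else {
        draws <- .withLocalSeed(
            sum(utf8ToInt(pwm$name)) + w,
            matrix(sample.int(4L, nDraws * w, replace = TRUE, prob = bg),
                   nDraws, w))
        scores <- numeric(nDraws)
        for (pos in seq_len(w))
            scores <- scores + weight[draws[, pos], pos]
        o <- order(scores)
        scores <- scores[o]
        prob <- rep(1 / nDraws, nDraws)
    }
    ## survival function P(S >= s); findInterval on the sorted grid
    cumRight <- rev(cumsum(rev(prob)))
    fn <- function(s) {
        i <- findInterval(s - 1e-12, scores) + 1L
        ifelse(i > length(scores), 0, cumRight[pmin(i, length(scores))])
    }
    .pwmNullCache[[key]] <- fn
    fn
}

.revComp <- function(seq)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

#' Relative IC-weighted motif match score of a sequence
#'
#' Every window of motif width on both strands is scored as the sum over
#' positions of `ic_pos * probs[base, pos]`, min-max normalized to [0,1]
#' by the motif's worst/best attainable IC-weighted sums. The best
#' window is reported together with a motif-match p-value: the
#' probability that a random background window scores at least as high
#' (exact enumeration for widths up to 10, Monte Carlo otherwise).
#' Windows containing N are skipped.
#'
#' @param pwm an `mgaPWM` from [newPWM()]/[loadPWMs()].
#' @param sequence DNA string, length >= motif width.
#' @param strand `"both"` (default) or `"+"` to restrict to the given
#'   orientation.
#' @return list with `score` (in [0,1]), `match_p`, `strand`, `offset`
#'   (1-based offset of the best window on the given sequence).
#' @export
relativeScore <- function(pwm, sequence, strand = c("both", "+")) {
    strand <- match.arg(strand)
    sequence <- toupper(sequence)
    .assert(!grepl("[^ACGTN]", sequence),
            "sequence contains non-IUPAC characters",
            "mgatlas_format_error")
    w <- ncol(pwm$probs)
    .assert(nchar(sequence) >= w, "sequence shorter than motif width",
            "mgatlas_parameter_error")
    weight <- sweep(pwm$probs, 2L, pwm$ic, `*`)
    sMin <- sum(apply(weight, 2L, min))
    sMax <- sum(apply(weight, 2L, max))
    scoreStrand <- function(seq) {
        ch <- strsplit(seq, "")[[1]]
        b <- match(ch, .BASES)
        nOff <- length(b) - w + 1L
        raw <- rep(NA_real_, nOff)
        for (o in seq_len(nOff)) {
            win <- b[o:(o + w - 1L)]
            if (anyNA(win)) next
            raw[o] <- sum(weight[cbind(win, seq_len(w))])
        }
        raw
    }
    fwd <- scoreStrand(sequence)
    if (strand == "both") rev <- scoreStrand(.revComp(sequence))
    else rev <- rep(NA_real_, length(fwd))
    if (all(is.na(c(fwd, rev))))
        return(list(score = NA_real_, match_p = NA_real_,
                    strand = NA_character_, offset = NA_integer_))
    bestF <- if (all(is.na(fwd))) -Inf else max(fwd, na.rm = TRUE)
    bestR <- if (all(is.na(rev))) -Inf else max(rev, na.rm = TRUE)
    if (bestF >= bestR) {
        raw <- bestF; st <- "+"; off <- which.max(fwd)
    } else {
        raw <- bestR; st <- "-"
        off <- nchar(sequence) - w + 2L - which.max(rev)
    }
    list(score = (raw - sMin) / (sMax - sMin),
         match_p = .pwmNullTail(pwm)(raw),
         strand = st, offset = as.integer(off))
}

#' Allelic TF-binding effect of a variant
#'
#' Scores the reference and alternative sequences (variant +/- `flank`)
#' with [relativeScore()] and flags the variant allelic when the score
#' difference exceeds `allelicThreshold` and the better allele's motif
#' match is significant (`match_p <= pThreshold`).
#'
#' @param pwm an `mgaPWM`.
#' @param variant one-row data.frame (or list) with chrom, pos (1-based),
#'   ref, alt, and optionally variant_id.
#' @param genome a `DNAStringSet` keyed by chromosome.
#' @param flank bp of context on each side (default 30).
#' @param allelicThreshold minimal |alt - ref| relative-score difference
#'   (default 0.7).
#' @param pThreshold maximal motif-match p-value (default 1e-4).
#' @return one-row data.frame: variant_id, tf, ref_score, alt_score,
#'   delta, match_p, strand, offset, allelic.
#' @export
allelicEffect <- function(pwm, variant, genome, flank = 30,
                          allelicThreshold = 0.7, pThreshold = 1e-4) {
    chrom <- as.character(variant$chrom)
    .assert(chrom %in% names(genome), paste0("chromosome ", chrom,
            " absent from genome"), "mgatlas_validation_error")
    pos <- as.integer(variant$pos)
    ref <- toupper(as.character(variant$ref))
    alt <- toupper(as.character(variant$alt))
    chromSeq <- genome[[chrom]]
    .assert(pos >= 1 && pos + nchar(ref) - 1 <= length(chromSeq),
            "variant outside genome bounds", "mgatlas_validation_error")
    genomeRef <- as.character(Biostrings::subseq(chromSeq, pos,
                                                 pos + nchar(ref) - 1L))
    if (genomeRef != ref)
        .validationError(sprintf(
            "reference allele mismatch at %s:%d (genome %s, given %s)",
            chrom, pos, genomeRef, ref))
    lo <- max(1L, pos - as.integer(flank))
    hi <- min(length(chromSeq), pos + nchar(ref) - 1L + as.integer(flank))
    ctx <- as.character(Biostrings::subseq(chromSeq, lo, hi))
    relPos <- pos - lo + 1L
    refSeq <- ctx
    altSeq <- paste0(substr(ctx, 1L, relPos - 1L), alt,
                     substring(ctx, relPos + nchar(ref)))
    sR <- relativeScore(pwm, refSeq)
    sA <- relativeScore(pwm, altSeq)
    delta <- sA$score - sR$score
    mp <- min(sR$match_p, sA$match_p)
    best <- if (sA$score >= sR$score) sA else sR
    data.frame(variant_id = if (!is.null(variant$variant_id))
                   as.character(variant$variant_id)
               else sprintf("%s:%d:%s:%s", chrom, pos, ref, alt),
               tf = pwm$name, ref_score = sR$score, alt_score = sA$score,
               delta = delta, match_p = mp, strand = best$strand,
               offset = best$offset - relPos,
               allelic = abs(delta) > allelicThreshold & mp <= pThreshold)
}

#' @rdname allelicEffect
#' @param pwms list of `mgaPWM`.
#' @param variants data.frame of variants.
#' @return `allelicEffectsAll`: row-bound predictions over all
#'   (variant, motif) pairs.
#' @export
allelicEffectsAll <- function(pwms, variants, genome, flank = 30,
                              allelicThreshold = 0.7, pThreshold = 1e-4) {
    out <- lapply(seq_len(nrow(variants)), function(i)
        do.call(rbind, lapply(pwms, allelicEffect,
                              variant = variants[i, , drop = FALSE],
                              genome = genome, flank = flank,
                              allelicThreshold = allelicThreshold,
                              pThreshold = pThreshold)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Abundant-TF assessment per cell type
#'
#' A TF is "abundant" in a cell type when (1) it is expressed in more
#' than half of that type's cells and (2) its log-normalized mean
#' expression in the type exceeds the 75th percentile (type-7 linear
#' interpolation) of the means over the whole universe of predicted
#' (TF, cell type) pairs.
#'
#' @param rna genes x cells count matrix with rownames = gene names.
#' @param cellTypes character vector per cell.
#' @param universe data.frame with columns `tf`, `cell_type`: the
#'   predicted pairs over which the percentile is taken.
#' @param scaleFactor library-size normalization target (default 1e4).
#' @return data.frame tf, cell_type, frac_expressing, mean_expr,
#'   abundant, for every universe pair.
#' @export
tfAbundance <- function(rna, cellTypes, universe, scaleFactor = 1e4) {
    .assert(nrow(universe) > 0, "empty prediction universe",
            "mgatlas_validation_error")
    libSize <- Matrix::colSums(rna)
    libSize[libSize == 0] <- 1
    missing <- setdiff(unique(universe$tf), rownames(rna))
    if (length(missing))
        warning("TF(s) absent from expression matrix: ",
                paste(missing, collapse = ", "))
    stat <- function(tf, type) {
        cells <- which(cellTypes == type)
        if (!tf %in% rownames(rna) || !length(cells))
            return(c(frac = 0, mean = 0))
        x <- rna[tf, cells]
        c(frac = mean(x > 0),
          mean = mean(log1p(x / libSize[cells] * scaleFactor)))
    }
    st <- t(mapply(stat, universe$tf, universe$cell_type))
    q75 <- .q75(st[, "mean"])
    data.frame(tf = universe$tf, cell_type = universe$cell_type,
               frac_expressing = unname(st[, "frac"]),
               mean_expr = unname(st[, "mean"]),
               abundant = unname(st[, "frac"] > 0.5 & st[, "mean"] > q75))
}

#' Bias-corrected Tn5 footprint profile at motif sites
#'
#' Aggregates per-base Tn5 insertion frequency (fragment cut sites)
#' around motif centres across sites, for the given cells, normalizes to
#' mean 1 over the outer flank (200 <= |d| <= 250), subtracts the
#' expected Tn5 profile under the bias model (default: the flat
#' outer-flank expectation), and calls a footprint when the motif flank
#' (20 <= |d| <= 100) is enriched and the centre (|d| <= 10) dips below
#' it.
#'
#' @param fragments fragment data.frame (chrom, start, end, barcode,
#'   count; 0-based half-open).
#' @param centers data.frame with columns `chrom` and `center` (1-based
#'   motif centre positions).
#' @param cells barcodes of the cell type under test.
#' @param window half-window in bp (default 250).
#' @param minSites minimal motif occurrences (default 20); fewer returns
#'   an insufficient-data profile with `detected = FALSE`.
#' @param flankTheta minimal flank enrichment (default 0.05).
#' @param dipTheta minimal relative centre dip (default 0.2): detection
#'   requires `center_depletion <= flank_enrichment * (1 - dipTheta)`.
#' @param biasModel optional numeric vector of length `2*window + 1`
#'   giving the expected positional insertion intensity.
#' @param tf,cellType labels carried through to the output.
#' @return object of class `FootprintProfile`: observed / expected /
#'   corrected arrays (length `2*window+1`), flank_enrichment,
#'   center_depletion, n_sites, n_insertions, detected, insufficient.
#' @export
footprintProfile <- function(fragments, centers, cells, window = 250,
                             minSites = 20, flankTheta = 0.05,
                             dipTheta = 0.2, biasModel = NULL,
                             tf = NA_character_, cellType = NA_character_) {
    W <- as.integer(window)
    .assert(W >= 150, "window must be >= 150 bp",
            "mgatlas_parameter_error")
    len <- 2L * W + 1L
    d <- seq(-W, W)
    outer <- abs(d) >= W - 50 & abs(d) <= W   # outer flank band
    mk <- function(observed, expected, nSites, nIns, insufficient) {
        corrected <- observed - expected
        fl <- mean(corrected[abs(d) >= 20 & abs(d) <= 100])
        ce <- mean(corrected[abs(d) <= 10])
        structure(list(tf = tf, cell_type = cellType, window = W,
                       observed = observed, expected = expected,
                       corrected = corrected,
                       flank_enrichment = fl, center_depletion = ce,
                       n_sites = nSites, n_insertions = nIns,
                       insufficient = insufficient,
                       detected = !insufficient && is.finite(fl) &&
                           fl >= flankTheta && ce <= fl * (1 - dipTheta)),
                  class = "FootprintProfile")
    }
    nSites <- nrow(centers)
    fr <- fragments[fragments$barcode %in% cells, , drop = FALSE]
    cuts <- data.frame(chrom = rep(fr$chrom, 2L),
                       pos = c(fr$start + 1L, fr$end),
                       n = rep(fr$count, 2L))
    counts <- numeric(len)
    nIns <- 0L
    for (ch in unique(centers$chrom)) {
        cc <- centers$center[centers$chrom == ch]
        pp <- cuts$pos[cuts$chrom == ch]
        nn <- cuts$n[cuts$chrom == ch]
        if (!length(cc) || !length(pp)) next
        for (m in cc) {
            rel <- pp - m
            keep <- rel >= -W & rel <= W
            if (!any(keep)) next
            tb <- tapply(nn[keep], rel[keep] + W + 1L, sum)
            counts[as.integer(names(tb))] <-
                counts[as.integer(names(tb))] + tb
            nIns <- nIns + sum(nn[keep])
        }
    }
    if (nSites < minSites || sum(counts[outer]) == 0)
        return(mk(counts, rep(0, len), nSites, nIns, TRUE))
    obs <- counts / mean(counts[outer])
    if (is.null(biasModel)) exp <- rep(1, len)
    else {
        .assert(length(biasModel) == len,
                "biasModel must have length 2*window + 1",
                "mgatlas_parameter_error")
        exp <- biasModel / mean(biasModel[outer])
    }
    mk(obs, exp, nSites, nIns, FALSE)
}

#' @export
print.FootprintProfile <- function(x, ...) {
    cat(sprintf(
        "FootprintProfile %s / %s: %d sites, %d insertions, flank %+.3f, center %+.3f, %s\n",
        x$tf, x$cell_type, x$n_sites, x$n_insertions,
        x$flank_enrichment, x$center_depletion,
        if (isTRUE(x$detected)) "footprint detected"
        else if (isTRUE(x$insufficient)) "insufficient data"
        else "no footprint"))
    invisible(x)
}

#' Per-cell-type footprint profiles for one TF
#'
#' Restricts the TF's motif occurrences to peaks detected in each cell
#' type (via the atlas), computes one [footprintProfile()] per type, and
#' ranks the types by flank enrichment (insufficient profiles rank
#' last).
#'
#' @param fragments fragment data.frame.
#' @param occurrences data.frame with columns tf, peak (index into the
#'   bundle's peaks), chrom, center.
#' @param atlas a [PeakAtlas-class] built from `bundle`.
#' @param bundle the [MultiomeBundle-class].
#' @param tf TF name to profile.
#' @inheritParams footprintProfile
#' @return list with `profiles` (per cell type) and `summary`
#'   (data.frame tf, cell_type, n_sites, flank_enrichment,
#'   center_depletion, detected, rank).
#' @export
tfFootprints <- function(fragments, occurrences, atlas, bundle, tf,
                         window = 250, minSites = 20, flankTheta = 0.05,
                         dipTheta = 0.2, biasModel = NULL) {
    occ <- occurrences[occurrences$tf == tf, , drop = FALSE]
    det <- detectionMatrix(atlas)
    atlasIdx <- peakRanges(atlas)$peak_index
    ct <- as.character(cellMeta(bundle)$cell_type)
    bcs <- rownames(cellMeta(bundle))
    profiles <- list()
    for (type in colnames(det)) {
        detPeaks <- atlasIdx[det[, type]]
        sites <- occ[occ$peak %in% detPeaks, , drop = FALSE]
        profiles[[type]] <- footprintProfile(
            fragments, sites[, c("chrom", "center")], bcs[ct == type],
            window, minSites, flankTheta, dipTheta, biasModel,
            tf = tf, cellType = type)
    }
    fl <- vapply(profiles, function(p)
        if (p$insufficient) -Inf else p$flank_enrichment, numeric(1))
    summary <- data.frame(
        tf = tf, cell_type = names(profiles),
        n_sites = vapply(profiles, `[[`, numeric(1), "n_sites"),
        flank_enrichment = vapply(profiles, `[[`, numeric(1),
                                  "flank_enrichment"),
        center_depletion = vapply(profiles, `[[`, numeric(1),
                                  "center_depletion"),
        detected = vapply(profiles, function(p) isTRUE(p$detected),
                          logical(1)),
        rank = rank(-fl, ties.method = "first"))
    rownames(summary) <- NULL
    list(profiles = profiles, summary = summary)
}
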