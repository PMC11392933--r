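#' @include AllClasses.R utils.R
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#' @importFrom IRanges IRanges
#' @importFrom utils read.delim write.table
NULL

## ---- interval conventions -------------------------------------------------
## On disk peaks are BED 0-based half-open; in memory they are GRanges
## (1-based closed). A 1-based variant position p overlaps a BED interval
## [s, e) iff s < p <= e, which is exactly GRanges overlap after the +1
## start shift. Conversion happens only here at the parse/serialize edge.

.bedToGRanges <- function(df) {
    .assert(all(df[[2]] >= 0), "BED start must be >= 0", "mgatlas_format_error")
    .assert(all(df[[2]] < df[[3]]), "BED start must be < end",
            "mgatlas_format_error")
    GenomicRanges::GRanges(as.character(df[[1]]),
                           IRanges::IRanges(df[[2]] + 1L, df[[3]]))
}

.grangesToBed <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
}

## ---- multiome bundle ------------------------------------------------------

#' Write / load a multiome bundle directory
#'
#' The on-disk layout is an MTX triplet pair with TSV sidecars:
#' `atac.mtx` (peaks x cells), `rna.mtx` (genes x cells), `barcodes.tsv`,
#' `peaks.bed` (BED3, 0-based half-open), `genes.tsv` (gene_id, gene_name,
#' chrom, strand, tss, tes, 1-based), and `cell_metadata.tsv`.
#'
#' @param bundle a [MultiomeBundle-class].
#' @param dir directory to write to / read from.
#' @return `loadMultiomeBundle` returns a validated
#'   [MultiomeBundle-class] with row/column order preserved from the
#'   files; `writeMultiomeBundle` returns `dir` invisibly.
#' @export
writeMultiomeBundle <- function(bundle, dir) {
    stopifnot(is(bundle, "MultiomeBundle"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Matrix::writeMM(bundle@atac, file.path(dir, "atac.mtx"))
    Matrix::writeMM(bundle@rna, file.path(dir, "rna.mtx"))
    writeLines(rownames(bundle@cellMeta), file.path(dir, "barcodes.tsv"))
    pk <- .grangesToBed(bundle@peaks)
    mc <- GenomicRanges::mcols(bundle@peaks)
    if ("gc" %in% colnames(mc)) pk$gc <- mc$gc
    write.table(pk, file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    g <- bundle@genes
    gdf <- data.frame(gene_id = g$gene_id, gene_name = g$gene_name,
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      strand = as.character(GenomicRanges::strand(g)),
                      tss = g$tss, tes = g$tes)
    if (!is.null(g$exons))
        gdf$exons <- vapply(g$exons, function(e)
            paste(sprintf("%d-%d", IRanges::start(e), IRanges::end(e)),
                  collapse = ";"), character(1))
    write.table(gdf, file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cm <- as.data.frame(bundle@cellMeta)
    cm <- cbind(barcode = rownames(bundle@cellMeta), cm)
    write.table(cm, file.path(dir, "cell_metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeMultiomeBundle
#' @param scheme optional [CategoryScheme-class]; by default rebuilt from
#'   the metadata's observed type-to-category pairs.
#' @export
loadMultiomeBundle <- function(dir, scheme = NULL) {
    need <- c("atac.mtx", "rna.mtx", "barcodes.tsv", "peaks.bed",
              "genes.tsv", "cell_metadata.tsv")
    for (f in need)
        if (!file.exists(file.path(dir, f)))
            .formatError(paste0("missing bundle file: ", f))
    ## `* 1` forces numeric storage (pattern MTX reads back as ngCMatrix)
    atac <- as(Matrix::readMM(file.path(dir, "atac.mtx")) * 1,
               "CsparseMatrix")
    rna <- as(Matrix::readMM(file.path(dir, "rna.mtx")) * 1,
              "CsparseMatrix")
    bc <- readLines(file.path(dir, "barcodes.tsv"))
    if (ncol(atac) != length(bc))
        .formatError(sprintf(
            "atac.mtx declares %d cells but barcodes.tsv has %d entries",
            ncol(atac), length(bc)))
    if (ncol(rna) != length(bc))
        .formatError(sprintf(
            "rna.mtx declares %d cells but barcodes.tsv has %d entries",
            ncol(rna), length(bc)))
    pk <- read.delim(file.path(dir, "peaks.bed"))
    if (nrow(atac) != nrow(pk))
        .formatError(sprintf(
            "atac.mtx declares %d peaks but peaks.bed has %d",
            nrow(atac), nrow(pk)))
    peaks <- .bedToGRanges(pk)
    if ("gc" %in% colnames(pk)) peaks$gc <- pk$gc
    gdf <- read.delim(file.path(dir, "genes.tsv"))
    if (nrow(rna) != nrow(gdf))
        .formatError(sprintf(
            "rna.mtx declares %d genes but genes.tsv has %d",
            nrow(rna), nrow(gdf)))
    genes <- .geneModelGRanges(gdf)
    cm <- read.delim(file.path(dir, "cell_metadata.tsv"),
                     colClasses = "character")
    if (nrow(cm) != length(bc) || any(cm$barcode != bc))
        .formatError("cell_metadata.tsv barcodes do not match barcodes.tsv")
    bad <- setdiff(unique(cm$category), .CATEGORIES)
    if (length(bad))
        .validationError(paste0("unknown category label(s): ",
                                paste(bad, collapse = ", ")))
    meta <- S4Vectors::DataFrame(sample_id = cm$sample_id,
                                 cell_type = cm$cell_type,
                                 category = cm$category,
                                 smoking_status = cm$smoking_status,
                                 row.names = bc)
    if (is.null(scheme)) {
        map <- tapply(cm$category, cm$cell_type, function(x) x[1])
        scheme <- CategoryScheme(stats::setNames(as.character(map),
                                                 names(map)))
    }
    new("MultiomeBundle", atac = atac, rna = rna, peaks = peaks,
        genes = genes, cellMeta = meta, scheme = scheme)
}

#' Build gene-model GRanges from a gene table
#'
#' @param gdf data.frame with gene_id, gene_name, chrom, strand, tss, tes
#'   (1-based; tss >= tes on the minus strand).
#' @return `GRanges` spanning each gene with `tss`/`tes` metadata.
#' @export
.geneModelGRanges <- function(gdf) {
    .assert(all(ifelse(gdf$strand == "+", gdf$tss <= gdf$tes,
                       gdf$tss >= gdf$tes)),
            "tss/tes orientation inconsistent with strand",
            "mgatlas_validation_error")
    gr <- GenomicRanges::GRanges(gdf$chrom,
        IRanges::IRanges(pmin(gdf$tss, gdf$tes), pmax(gdf$tss, gdf$tes)),
        strand = gdf$strand)
    gr$gene_id <- gdf$gene_id
    gr$gene_name <- gdf$gene_name
    gr$tss <- gdf$tss
    gr$tes <- gdf$tes
    if ("exons" %in% colnames(gdf)) {
        ex <- lapply(gdf$exons, function(s) {
            if (is.na(s) || !nzchar(s)) return(IRanges::IRanges())
            parts <- do.call(rbind, strsplit(strsplit(s, ";")[[1]], "-"))
            IRanges::IRanges(as.integer(parts[, 1]), as.integer(parts[, 2]))
        })
        gr$exons <- methods::as(ex, "IRangesList")
    }
    gr
}

## ---- fragments ------------------------------------------------------------

#' Load a Tn5 fragment file
#'
#' Tab-separated 5 columns (chrom, start, end, barcode, count), 0-based
#' half-open, plain or gzip. Records with barcodes outside the whitelist
#' are dropped; unknown chromosomes are skipped with a warning when
#' `chroms` is given.
#'
#' @param path fragment file path.
#' @param whitelist character vector of cell barcodes to keep (`NULL`
#'   keeps everything).
#' @param chroms optional character vector of known chromosomes.
#' @return data.frame with columns chrom, start, end, barcode, count.
#' @export
loadFragments <- function(path, whitelist = NULL, chroms = NULL) {
    con <- gzfile(path)
    df <- tryCatch(
        read.delim(con, header = FALSE,
                   col.names = c("chrom", "start", "end", "barcode", "count"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer")),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                data.frame(chrom = character(), start = integer(),
                           end = integer(), barcode = character(),
                           count = integer())
            else stop(e)
        })
    if (nrow(df)) {
        bad <- which(df$end <= df$start)
        if (length(bad))
            .formatError(sprintf("fragment end <= start at line %d", bad[1]))
        .assert(all(df$count >= 1), "fragment count must be >= 1",
                "mgatlas_format_error")
        if (!is.null(chroms)) {
            drop <- !(df$chrom %in% chroms)
            if (any(drop)) {
                warning(sum(drop),
                        " fragment(s) on unknown chromosomes skipped")
                df <- df[!drop, , drop = FALSE]
            }
        }
        if (!is.null(whitelist))
            df <- df[df$barcode %in% whitelist, , drop = FALSE]
        rownames(df) <- NULL
    }
    df
}

#' @rdname loadFragments
#' @param fragments data.frame as returned by `loadFragments`.
#' @param gzip compress the output.
#' @export
writeFragments <- function(fragments, path, gzip = grepl("\\.gz$", path)) {
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    write.table(fragments, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## ---- position weight matrices --------------------------------------------

#' Construct a position weight matrix record
#'
#' Columns are normalized to probabilities with a pseudocount distributed
#' by the background base composition; per-position information content
#' (bits, relative to the background) is precomputed.
#'
#' @param name motif / TF name.
#' @param counts 4 x L numeric matrix (rows A, C, G, T) of counts or
#'   probabilities.
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background length-4 base composition (default uniform).
#' @return an object of class `mgaPWM`: list with `name`, `probs`
#'   (4 x L), `ic` (length L) and `background`.
#' @export
newPWM <- function(name, counts, pseudocount = 0.8,
                   background = rep(0.25, 4)) {
    counts <- as.matrix(counts)
    .assert(nrow(counts) == 4, "PWM must have 4 rows (A,C,G,T)",
            "mgatlas_format_error")
    cs <- colSums(counts)
    if (any(!is.finite(cs)) || any(cs <= 0))
        .formatError(paste0("PWM ", name,
                            ": column not summing to a positive value"))
    bg <- background / sum(background)
    probs <- sweep(counts + pseudocount * bg, 2L, cs + pseudocount, `/`)
    rownames(probs) <- c("A", "C", "G", "T")
    ic <- colSums(probs * log2(probs / bg))
    structure(list(name = name, probs = probs, ic = pmax(ic, 0),
                   background = bg),
              class = "mgaPWM")
}

#' Load PWMs from JASPAR or MEME text
#'
#' The format is auto-detected: files whose first non-empty line starts
#' with `>` are parsed as JASPAR count matrices; files containing a
#' `MEME version` header are parsed as MEME minimal motif format.
#'
#' @inheritParams newPWM
#' @param path motif file.
#' @return list of `mgaPWM` objects.
#' @export
loadPWMs <- function(path, pseudocount = 0.8, background = rep(0.25, 4)) {
    lines <- readLines(path)
    nonEmpty <- lines[nzchar(trimws(lines))]
    .assert(length(nonEmpty) > 0, "empty motif file", "mgatlas_format_error")
    if (startsWith(trimws(nonEmpty[1]), ">"))
        .parseJaspar(lines, pseudocount, background)
    else if (any(grepl("^MEME version", lines)))
        .parseMeme(lines, pseudocount, background)
    else .formatError("unrecognized motif file format")
}

.parseJaspar <- function(lines, pseudocount, background) {
    idx <- grep("^>", lines)
    out <- list()
    for (i in seq_along(idx)) {
        hdr <- sub("^>\\s*", "", lines[idx[i]])
        name <- strsplit(trimws(hdr), "\\s+")[[1]]
        name <- name[length(name)]   # "MA0001.1 NAME" -> NAME
        to <- if (i < length(idx)) idx[i + 1] - 1L else length(lines)
        block <- lines[(idx[i] + 1L):to]
        block <- block[nzchar(trimws(block))]
        .assert(length(block) >= 4, paste0("JASPAR motif ", name,
                                           ": expected 4 matrix rows"),
                "mgatlas_format_error")
        rows <- lapply(block[1:4], function(l) {
            l <- gsub("[][ACGTacgt]", " ", l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1]])
        })
        w <- unique(lengths(rows))
        .assert(length(w) == 1, paste0("JASPAR motif ", name,
                                       ": ragged matrix rows"),
                "mgatlas_format_error")
        out[[name]] <- newPWM(name, do.call(rbind, rows), pseudocount,
                              background)
    }
    out
}

.parseMeme <- function(lines, pseudocount, background) {
    idx <- grep("^MOTIF", lines)
    .assert(length(idx) > 0, "MEME file with no MOTIF blocks",
            "mgatlas_format_error")
    out <- list()
    for (i in seq_along(idx)) {
        name <- strsplit(trimws(sub("^MOTIF", "", lines[idx[i]])),
                         "\\s+")[[1]][1]
        to <- if (i < length(idx)) idx[i + 1] - 1L else length(lines)
        block <- lines[idx[i]:to]
        hdr <- grep("letter-probability matrix", block)
        .assert(length(hdr) == 1, paste0("MEME motif ", name,
                                         ": missing probability matrix"),
                "mgatlas_format_error")
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr]))
        rows <- block[(hdr + 1L):(hdr + w)]
        mat <- t(vapply(rows, function(l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1]])[1:4], numeric(4)))
        out[[name]] <- newPWM(name, t(mat), pseudocount, background)
    }
    out
}

## ---- GWAS bundle ----------------------------------------------------------

#' Load GWAS summary statistics and LD-to-lead tables
#'
#' `stats` must carry locus_id, variant_id, chrom, pos, ref, alt, a
#' p-value column `p` (or a z-score column `z`), and an `is_lead` flag;
#' `ld` carries locus_id, variant_id, r2_to_lead and a population tag.
#' Absent z-scores are filled by the inverse-normal transform of the
#' two-sided p-value (magnitude only).
#'
#' @param statsPath,ldPath TSV file paths.
#' @return a data.frame with one row per (locus, variant), columns
#'   locus_id, variant_id, chrom, pos, ref, alt, p, z, is_lead,
#'   r2_to_lead, population.
#' @export
loadGwasBundle <- function(statsPath, ldPath) {
    st <- read.delim(statsPath)
    ld <- read.delim(ldPath)
    .assert(all(c("locus_id", "variant_id", "is_lead") %in% colnames(st)),
            "stats table lacks required columns", "mgatlas_format_error")
    if (!"z" %in% colnames(st)) st$z <- NA_real_
    if (!"p" %in% colnames(st)) st$p <- NA_real_
    if (any(!is.na(st$p) & (st$p <= 0 | st$p > 1)))
        .validationError("p-values must lie in (0, 1]")
    fill <- is.na(st$z) & !is.na(st$p)
    st$z[fill] <- stats::qnorm(st$p[fill] / 2, lower.tail = FALSE)
    st$p[is.na(st$p)] <- 2 * stats::pnorm(-abs(st$z[is.na(st$p)]))
    leads <- tapply(st$is_lead != 0, st$locus_id, sum)
    if (any(leads != 1))
        .validationError(paste0("locus without exactly one lead: ",
            paste(names(leads)[leads != 1], collapse = ", ")))
    .assert(all(c("locus_id", "variant_id", "r2_to_lead") %in% colnames(ld)),
            "LD table lacks required columns", "mgatlas_format_error")
    if (any(ld$r2_to_lead < 0 | ld$r2_to_lead > 1, na.rm = TRUE))
        .validationError("r2_to_lead outside [0, 1]")
    if (!"population" %in% colnames(ld)) ld$population <- "ALL"
    out <- merge(st, ld[, c("locus_id", "variant_id", "r2_to_lead",
                            "population")],
                 by = c("locus_id", "variant_id"), all.x = TRUE, sort = FALSE)
    out <- out[order(out$locus_id, out$pos, out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' @rdname loadGwasBundle
#' @param gwas merged GWAS table (as returned by `loadGwasBundle` or the
#'   synthetic generator).
#' @param dir output directory; writes `gwas_stats.tsv` and `gwas_ld.tsv`.
#' @export
writeGwasBundle <- function(gwas, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    st <- gwas[, c("locus_id", "variant_id", "chrom", "pos", "ref", "alt",
                   "p", "z", "is_lead")]
    ld <- gwas[, c("locus_id", "variant_id", "r2_to_lead", "population")]
    write.table(st, file.path(dir, "gwas_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ld, file.path(dir, "gwas_ld.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

## ---- result tables --------------------------------------------------------

#' Write a result table deterministically
#'
#' Rows are sorted by whichever of locus_id, chrom, pos/start, peak,
#' variant_id, gene are present (in that precedence); the same records
#' always produce byte-identical files.
#'
#' @param records a data.frame of one homogeneous result type.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(records, path) {
    stopifnot(is.data.frame(records))
    keys <- intersect(c("locus_id", "chrom", "pos", "start", "peak",
                        "variant_id", "gene", "tf", "cell_type", "level"),
                      colnames(records))
    if (length(keys) && nrow(records))
        records <- records[do.call(order, records[keys]), , drop = FALSE]
    flat <- as.data.frame(lapply(records, function(col) {
        if (is.list(col)) vapply(col, function(x)
            paste(as.character(x), collapse = ";"), character(1))
        else if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                         scientific = FALSE)
        else as.character(col)
    }), optional = TRUE, stringsAsFactors = FALSE)
    colnames(flat) <- colnames(records)
    con <- file(path, "wb")   # "wb": byte-identical across platforms
    on.exit(close(con))
    write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
    invisible(path)
}
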