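## Internal numerical helpers shared across modules.

#' @importFrom Matrix Diagonal t rowSums colSums crossprod
#' @importFrom stats quantile rnorm pnorm rbinom rpois rnbinom runif sd cor
NULL

## TF-IDF (log-scaled) normalization of a peaks x cells binary-ish matrix,
## as used for LSI embeddings of snATAC data.
.tfidf <- function(mat) {
    cs <- Matrix::colSums(mat)
    cs[cs == 0] <- 1
    tf <- mat %*% Matrix::Diagonal(x = 1 / cs)
    idf <- ncol(mat) / pmax(Matrix::rowSums(mat > 0), 1)
    res <- Matrix::Diagonal(x = idf) %*% tf
    res@x <- log1p(res@x * 1e4)
    res
}

## LSI embedding of a bundle's ATAC matrix: TF-IDF + truncated SVD,
## dropping the first (depth-correlated) component. Returns cells x d.
## Deterministic given the RNG state (irlba is seeded by the caller).
.lsiEmbedding <- function(atac, nComponents = 30L) {
    nc <- min(nComponents, ncol(atac) - 1L, nrow(atac) - 1L)
    x <- .tfidf(atac)
    sv <- irlba::irlba(x, nv = nc, nu = nc)
    emb <- sv$v %*% diag(sv$d, nc, nc)
    ## component 1 tracks sequencing depth; use 2..nc
    emb <- emb[, -1L, drop = FALSE]
    ## fix sign for reproducibility across BLAS variants
    idx <- apply(abs(emb), 2L, which.max)
    sgn <- sign(emb[cbind(idx, seq_along(idx))])
    sgn[sgn == 0] <- 1
    sweep(emb, 2L, sgn, `*`)
}

## Standardize columns of a numeric matrix; zero-variance columns -> 0.
.zscale <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2L, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    scale(m, center = mu, scale = s)
}

## Type-7 (linear interpolation) quantile, stated convention for the
## abundant-TF 75th percentile.
.q75 <- function(x) as.numeric(stats::quantile(x, 0.75, type = 7, names = FALSE))

## GC fraction of DNA strings (character vector).
.gcFraction <- function(seqs) {
    g <- vapply(strsplit(toupper(seqs), ""), function(s)
        sum(s %in% c("G", "C")) / max(length(s), 1), numeric(1))
    g
}

.assert <- function(cond, msg, class = "mgatlas_error") {
    if (!isTRUE(cond))
        stop(errorCondition(msg, class = c(class, "error", "condition")))
    invisible(TRUE)
}

.formatError <- function(msg) .assert(FALSE, msg, "mgatlas_format_error")
.validationError <- function(msg) .assert(FALSE, msg, "mgatlas_validation_error")
.parameterError <- function(msg) .assert(FALSE, msg, "mgatlas_parameter_error")
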