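#' @include utils.R
NULL

#' Log-likelihood-ratio inclusion rule for candidate causal variants
#'
#' A variant stays within a 1:`ratioThreshold` likelihood ratio of the
#' lead under the normal approximation when
#' `exp((z_var^2 - z_lead^2) / 2) >= 1 / ratioThreshold`, i.e.
#' `z_lead^2 - z_var^2 < 2 * log(ratioThreshold)`.
#'
#' @param zLead,zVar z-scores of the lead and the tested variant.
#' @param ratioThreshold likelihood-ratio cutoff (default 1000).
#' @return logical vector (vectorized over `zVar`).
#' @examples
#' llrInclude(6, 5)   # 36 - 25 = 11 < 2*log(1000) = 13.8155 -> TRUE
#' llrInclude(6, 4)   # 36 - 16 = 20 -> FALSE
#' @export
llrInclude <- function(zLead, zVar, ratioThreshold = 1000) {
    if (ratioThreshold <= 1)
        .parameterError("ratioThreshold must be > 1")
    .assert(all(is.finite(zLead)) && all(is.finite(zVar)),
            "z-scores must be finite", "mgatlas_parameter_error")
    zLead^2 - zVar^2 < 2 * log(ratioThreshold)
}

#' Select candidate causal variants in one GWAS locus
#'
#' The lead is always included (reason `lead`); declared conditional
#' leads are included (reason `conditional`) and never acquire LD
#' proxies; remaining variants are included when within the LLR band of
#' the lead and/or in LD with it. Each variant is reported once with the
#' strongest applicable reason (precedence lead > conditional > llr >
#' ld).
#'
#' @param locus data.frame for one locus with columns variant_id, chrom,
#'   pos, ref, alt, z (or p), is_lead, r2_to_lead, and optionally
#'   is_conditional; one `locus_id` value.
#' @param mode `llr_or_ld` (LLR < 1:1000 OR r2 rule) or `ld_only`
#'   (r2 rule alone, the replication-stage variant of the selection).
#' @param ratioThreshold LLR cutoff (default 1000).
#' @param r2Threshold LD cutoff (default 0.8); `r2Inclusive` controls the
#'   boundary (default inclusive, `>=`).
#' @return data.frame of CCVs: locus_id, variant_id, chrom, pos, ref,
#'   alt, inclusion_reason, llr_stat (`z_lead^2 - z_var^2`), r2_to_lead.
#' @export
selectCcvs <- function(locus, mode = c("llr_or_ld", "ld_only"),
                       ratioThreshold = 1000, r2Threshold = 0.8,
                       r2Inclusive = TRUE) {
    mode <- match.arg(mode)
    stopifnot(is.data.frame(locus), "is_lead" %in% colnames(locus))
    .assert(length(unique(locus$locus_id)) == 1L,
            "selectCcvs expects a single locus", "mgatlas_validation_error")
    if (!"z" %in% colnames(locus)) {
        .assert("p" %in% colnames(locus), "locus needs z or p",
                "mgatlas_format_error")
        locus$z <- stats::qnorm(locus$p / 2, lower.tail = FALSE)
    }
    leadRow <- which(locus$is_lead != 0)
    .assert(length(leadRow) == 1L, "locus must have exactly one lead",
            "mgatlas_validation_error")
    cond <- if ("is_conditional" %in% colnames(locus))
        locus$is_conditional != 0 else rep(FALSE, nrow(locus))
    zLead <- locus$z[leadRow]
    llrStat <- zLead^2 - locus$z^2
    r2 <- if ("r2_to_lead" %in% colnames(locus)) locus$r2_to_lead
          else rep(NA_real_, nrow(locus))
    ldPass <- !is.na(r2) &
        (if (r2Inclusive) r2 >= r2Threshold else r2 > r2Threshold)
    llrPass <- llrInclude(zLead, locus$z, ratioThreshold)
    if (mode == "ld_only" && any(is.na(r2) & !locus$is_lead & !cond))
        warning(sum(is.na(r2) & !locus$is_lead & !cond),
                " variant(s) without r2 skipped under ld_only")
    reason <- rep(NA_character_, nrow(locus))
    if (mode == "llr_or_ld") {
        reason[ldPass] <- "ld"
        reason[llrPass] <- "llr"
    } else {
        reason[ldPass] <- "ld"
    }
    reason[cond] <- "conditional"
    reason[leadRow] <- "lead"
    keep <- !is.na(reason)
    out <- data.frame(locus_id = locus$locus_id[keep],
                      variant_id = locus$variant_id[keep],
                      chrom = locus$chrom[keep], pos = locus$pos[keep],
                      ref = locus$ref[keep], alt = locus$alt[keep],
                      inclusion_reason = reason[keep],
                      llr_stat = ifelse(reason[keep] == "llr",
                                        llrStat[keep], NA_real_),
                      r2_to_lead = r2[keep])
    out <- out[order(out$pos, out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Select CCVs across all loci of a GWAS table
#'
#' @param gwas merged table as returned by [loadGwasBundle()] or
#'   [generateGwas()].
#' @inheritParams selectCcvs
#' @return row-bound CCV table over all loci.
#' @export
selectCcvsAll <- function(gwas, mode = "llr_or_ld", ratioThreshold = 1000,
                          r2Threshold = 0.8, r2Inclusive = TRUE) {
    out <- lapply(split(gwas, gwas$locus_id), selectCcvs, mode = mode,
                  ratioThreshold = ratioThreshold,
                  r2Threshold = r2Threshold, r2Inclusive = r2Inclusive)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Merge CCV sets across studies
#'
#' Deduplicates by variant identity (chrom, pos, ref, alt); a variant
#' found in several loci or studies keeps all locus memberships on one
#' record (semicolon-joined, with per-locus reasons).
#'
#' @param ... CCV data.frames from [selectCcvs()]/[selectCcvsAll()].
#' @return data.frame with one row per unique variant: variant key
#'   columns, `loci` and `reasons` (semicolon-joined, locus-sorted),
#'   `n_loci`.
#' @export
mergeCcvs <- function(...) {
    all <- do.call(rbind, list(...))
    .assert(nrow(all) > 0, "no CCVs to merge", "mgatlas_validation_error")
    key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = ":")
    byId <- split(seq_len(nrow(all)), all$variant_id)
    for (rows in byId)
        if (length(unique(key[rows])) > 1L)
            .validationError(paste0("conflicting alleles for variant ",
                                    all$variant_id[rows[1]]))
    out <- do.call(rbind, lapply(split(seq_len(nrow(all)), key),
        function(rows) {
            o <- rows[order(all$locus_id[rows])]
            data.frame(variant_id = all$variant_id[o[1]],
                       chrom = all$chrom[o[1]], pos = all$pos[o[1]],
                       ref = all$ref[o[1]], alt = all$alt[o[1]],
                       loci = paste(unique(all$locus_id[o]),
                                    collapse = ";"),
                       reasons = paste(all$inclusion_reason[o],
                                       collapse = ";"),
                       n_loci = length(unique(all$locus_id[o])))
        }))
    out <- out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
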