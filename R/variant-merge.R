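#' Merge per-tissue call sets into a unique-variant table
#'
#' Takes the union over tissues keyed by (chrom, pos, ref, alt), recording
#' per-tissue presence.  A sample genotyped in several tissues at the same
#' variant is resolved by majority vote over its non-missing calls; ties
#' become missing.  Minor-allele frequency (folded to <= 0.5) and call
#' rate are computed over the pooled samples after merging.  The merge is
#' idempotent and invariant to tissue input order (variants are sorted by
#' position, samples by id).
#'
#' @param callsets list of per-tissue call sets from
#'   \code{\link{readTissueVcf}}.
#' @return A \linkS4class{UniqueVariantTable}.
#' @export
mergeUnique <- function(callsets) {
  stopifnot(length(callsets) >= 1)
  tissues <- vapply(callsets, `[[`, character(1), "tissue")
  if (anyDuplicated(tissues)) stop("duplicate tissue labels")
  allV <- do.call(rbind, lapply(callsets, `[[`, "variants"))
  key <- paste(allV$chrom, allV$pos, allV$ref, allV$alt, sep = ":")
  uKey <- !duplicated(key)
  variants <- allV[uKey, , drop = FALSE]
  vkey <- key[uKey]

  # identical (chrom, pos, alt) with different ref is irreconcilable
  pa <- paste(variants$chrom, variants$pos, variants$alt, sep = ":")
  if (anyDuplicated(pa)) {
    stop("data-integrity error: conflicting ref alleles at ",
         pa[duplicated(pa)][1])
  }
  o <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[o, , drop = FALSE]
  vkey <- vkey[o]
  rownames(variants) <- NULL
  nV <- nrow(variants)

  samples <- sort(unique(unlist(lapply(callsets,
                                       function(cs) colnames(cs$geno)))))
  nS <- length(samples)
  presence <- matrix(FALSE, nV, length(tissues),
                     dimnames = list(vkey, tissues))
  altVotes <- array(0L, c(nV, nS, 3L),
                    dimnames = list(vkey, samples, c("0", "1", "2")))
  for (cs in callsets) {
    k <- paste(cs$variants$chrom, cs$variants$pos, cs$variants$ref,
               cs$variants$alt, sep = ":")
    vi <- match(k, vkey)
    presence[vi, cs$tissue] <- TRUE
    si <- match(colnames(cs$geno), samples)
    for (g in 0:2) {
      hit <- which(cs$geno == g, arr.ind = TRUE)
      if (nrow(hit)) {
        idx <- cbind(vi[hit[, 1]], si[hit[, 2]], g + 1L)
        altVotes[idx] <- altVotes[idx] + 1L
      }
    }
  }
  top <- apply(altVotes, c(1, 2), function(v) {
    if (all(v == 0L)) return(NA_integer_)
    w <- which(v == max(v))
    if (length(w) > 1L) NA_integer_ else w - 1L
  })
  geno <- matrix(as.integer(top), nV, nS, dimnames = list(vkey, samples))

  stats <- variantStats(geno)
  variants$maf <- stats$maf
  variants$callRate <- stats$callRate
  new("UniqueVariantTable", variants = variants, presence = presence,
      geno = geno)
}

# pooled folded MAF and call rate from an allele-count matrix
variantStats <- function(geno) {
  nS <- ncol(geno)
  nonMiss <- rowSums(!is.na(geno))
  altFreq <- ifelse(nonMiss > 0,
                    rowSums(geno, na.rm = TRUE) / (2 * nonMiss), NA_real_)
  list(maf = pmin(altFreq, 1 - altFreq),
       callRate = if (nS > 0) nonMiss / nS else rep(0, nrow(geno)))
}

#' Filter a unique-variant table on MAF and call rate
#'
#' Default retention keeps variants with pooled minor-allele frequency at
#' or above \code{mafThreshold} and call rate strictly above
#' \code{callrateThreshold}; variants with undefined MAF (no genotypes)
#' are removed.  Setting \code{keepAboveMaf = FALSE} flips the MAF
#' direction (retain MAF below the threshold).
#'
#' @param uvt a \linkS4class{UniqueVariantTable}.
#' @param mafThreshold minor-allele frequency threshold.
#' @param callrateThreshold call-rate threshold (strict >).
#' @param keepAboveMaf logical, direction of the MAF filter.
#' @return The filtered \code{UniqueVariantTable}; warns (not errors) when
#'   nothing survives.
#' @export
filterMafCallrate <- function(uvt, mafThreshold = 0.40,
                              callrateThreshold = 0.50,
                              keepAboveMaf = TRUE) {
  v <- uvt@variants
  mafPass <- if (keepAboveMaf) v$maf >= mafThreshold else v$maf < mafThreshold
  keep <- !is.na(v$maf) & mafPass & v$callRate > callrateThreshold
  if (!any(keep)) warning("no variants pass the MAF/call-rate filter")
  uvt[keep]
}

#' Venn cardinalities of tissue presence
#'
#' Counts variants by their exact tissue-presence pattern, for the full
#' table or any variant subset (e.g. significant variants), and reports
#' the cumulative "present in all tissues" count.
#'
#' @param uvt a \linkS4class{UniqueVariantTable}.
#' @param subset optional logical/integer variant index.
#' @return A list with \code{pattern} (named integer vector of exact-set
#'   counts, names like "liver+muscle") and \code{inAll} (variants present
#'   in every tissue).
#' @export
tissueOverlap <- function(uvt, subset = NULL) {
  pres <- uvt@presence
  if (!is.null(subset)) pres <- pres[subset, , drop = FALSE]
  tis <- colnames(pres)
  lab <- apply(pres, 1, function(r) paste(tis[r], collapse = "+"))
  combos <- unlist(lapply(seq_along(tis), function(k) {
    apply(utils::combn(tis, k), 2, paste, collapse = "+")
  }))
  pattern <- setNames(integer(length(combos)), combos)
  tab <- table(lab[lab != ""])
  pattern[names(tab)] <- as.integer(tab)
  list(pattern = pattern, inAll = sum(rowSums(pres) == ncol(pres)))
}
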