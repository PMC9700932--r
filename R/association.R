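#' Allele-frequency association between extreme groups
#'
#' For each variant, compares the high and low feed-efficiency groups
#' without assuming Hardy-Weinberg equilibrium.  \code{method = "allelic"}
#' is the 1-df chi-square on the 2x2 allele-count table (alleles counted
#' as two per non-missing genotype); \code{method = "trend"} is the
#' Cochran-Armitage trend statistic on the 2x3 genotype table with scores
#' 0, 1, 2.  P-values come from the chi-square(1) reference; significance
#' is declared at unadjusted p < alpha.  Monomorphic variants (or empty
#' margins) give chi2 = 0, p = 1.
#'
#' @param uvt a \linkS4class{UniqueVariantTable}.
#' @param hfeIds,lfeIds sample ids of the two groups (must be disjoint and
#'   present in the genotype matrix).
#' @param method "allelic" or "trend".
#' @param alpha significance level.
#' @param adjust optional p.adjust method (e.g. "BH"); "none" (the
#'   default) declares significance on raw p-values.
#' @return data.frame with the variant key columns, the allele counts
#'   (altHfe, refHfe, altLfe, refLfe), chi2, p and significant.
#' @export
allelicAssociation <- function(uvt, hfeIds, lfeIds,
                               method = c("allelic", "trend"),
                               alpha = 0.05, adjust = "none") {
  method <- match.arg(method)
  geno <- uvt@geno
  hfeIds <- intersect(as.character(hfeIds), colnames(geno))
  lfeIds <- intersect(as.character(lfeIds), colnames(geno))
  if (length(intersect(hfeIds, lfeIds))) stop("groups must be disjoint")
  if (!length(hfeIds) || !length(lfeIds)) {
    stop("both groups need genotyped samples")
  }
  gH <- geno[, hfeIds, drop = FALSE]
  gL <- geno[, lfeIds, drop = FALSE]

  nH <- rowSums(!is.na(gH)); nL <- rowSums(!is.na(gL))
  altH <- rowSums(gH, na.rm = TRUE); altL <- rowSums(gL, na.rm = TRUE)

  if (method == "allelic") {
    chi2 <- allelicChi2(altH, 2 * nH, altL, 2 * nL)
  } else {
    cnt <- function(g) {
      matrix(vapply(0:2, function(k) rowSums(g == k, na.rm = TRUE),
                    numeric(nrow(g))), nrow = nrow(g), ncol = 3)
    }
    chi2 <- trendChi2(cnt(gH), cnt(gL))
  }
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p[chi2 == 0] <- 1
  pAdj <- if (identical(adjust, "none")) p else stats::p.adjust(p, adjust)
  out <- cbind(uvt@variants[c("chrom", "pos", "ref", "alt")],
               data.frame(altHfe = altH, refHfe = 2 * nH - altH,
                          altLfe = altL, refLfe = 2 * nL - altL,
                          chi2 = chi2, p = p,
                          significant = pAdj < alpha))
  rownames(out) <- rownames(geno)
  out
}

# 1-df Pearson chi-square on the 2x2 allele-count table, vectorised;
# degenerate margins give 0
allelicChi2 <- function(alt1, n1, alt2, n2) {
  N <- n1 + n2
  altT <- alt1 + alt2
  refT <- N - altT
  num <- N * (alt1 * (n2 - alt2) - alt2 * (n1 - alt1))^2
  den <- n1 * n2 * altT * refT
  ifelse(den == 0 | N == 0, 0, num / den)
}

# Cochran-Armitage trend statistic, scores (0,1,2), matrices rows=variants
trendChi2 <- function(grp1, grp2) {
  s <- c(0, 1, 2)
  n <- grp1 + grp2            # genotype-column totals
  N <- rowSums(n)
  R <- rowSums(grp1)
  pbar <- ifelse(N > 0, R / N, 0)
  U <- as.numeric(grp1 %*% s) - pbar * as.numeric(n %*% s)
  denom <- pbar * (1 - pbar) *
    (as.numeric(n %*% s^2) - as.numeric(n %*% s)^2 / pmax(N, 1))
  ifelse(denom <= 0, 0, U^2 / denom)
}

#' Aggregate per-organ counts into report totals and percentages
#'
#' Sums per-organ stage counts (column-wise totals over organs) and, when
#' the unique-variant stage counts are supplied, derives the reporting
#' percentages of the detection pipeline: filtered/total,
#' significant/filtered, moderate/significant and high/significant.  The
#' printed forms follow the reporting convention of rounding to two
#' decimals, except the moderate share which is printed to one.
#'
#' @param organCounts data.frame of non-negative counts, one row per
#'   organ, numeric columns = pipeline stages.
#' @param uniqueCounts optional named numeric with elements total,
#'   filtered, significant, moderate, high — the unique-variant counts
#'   (the union over organs, which column sums cannot reproduce because a
#'   variant may be called in several organs).
#' @return A list with \code{totals} (named numeric), and when
#'   \code{uniqueCounts} is given, \code{percentages} (raw) and
#'   \code{printed} (character, rounded as reported).
#' @examples
#' tab <- organCountTables()$variants
#' aggregateReport(tab[tab$organ != "Unique", -1],
#'                 unlist(tab[tab$organ == "Unique", -1]))
#' @export
aggregateReport <- function(organCounts, uniqueCounts = NULL) {
  num <- organCounts[vapply(organCounts, is.numeric, logical(1))]
  if (any(unlist(num) < 0)) stop("data-integrity error: negative counts")
  totals <- colSums(num)
  out <- list(totals = totals)
  if (!is.null(uniqueCounts)) {
    u <- uniqueCounts
    stopifnot(all(c("total", "filtered", "significant", "moderate",
                    "high") %in% names(u)))
    pct <- c(
      filteredOfTotal = 100 * u[["filtered"]] / u[["total"]],
      significantOfFiltered = 100 * u[["significant"]] / u[["filtered"]],
      moderateOfSignificant = 100 * u[["moderate"]] / u[["significant"]],
      highOfSignificant = 100 * u[["high"]] / u[["significant"]]
    )
    digits <- c(2, 2, 1, 2)
    out$percentages <- pct
    out$printed <- setNames(sprintf("%.*f%%", digits, round(pct, digits)),
                            names(pct))
  }
  out
}

#' Published per-organ count tables
#'
#' Loads the per-organ variant counts shipped with the package for the
#' five-organ bovine feed-efficiency variant-calling study: per-organ
#' totals through the pipeline stages (called, filtered, significant,
#' moderate impact, high impact; plus the unique-variant union row) and
#' the per-organ missense / affected-gene summary of the consequence
#' analysis.
#'
#' @return A list of two data.frames, \code{variants} and
#'   \code{consequences}.
#' @export
organCountTables <- function() {
  dir <- system.file("extdata", package = "PFVcattle")
  list(
    variants = read.delim(file.path(dir, "tissue_variant_counts.tsv")),
    consequences = read.delim(file.path(dir, "consequence_counts.tsv"))
  )
}
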