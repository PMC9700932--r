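#' Record-level quality-control thresholds
#'
#' GATK-style per-record thresholds: variant quality (QUAL), depth (DP),
#' quality by depth (QD), FisherStrand phred p (FS) and RMS mapping
#' quality (MQ).  A record is retained when QUAL > qual, DP > dp, QD > qd
#' and, by default, FS < fs and MQ > mq (high strand bias and low mapping
#' quality are evidence against a call).  With \code{literal = TRUE} the
#' last two comparisons are flipped to FS > fs and MQ < mq, matching tools
#' that publish the thresholds in that direction.
#'
#' @param qual,dp,qd,fs,mq numeric thresholds (all strict inequalities).
#' @param literal logical, flip the FS/MQ retention directions.
#' @return A named list of thresholds.
#' @export
qcThresholds <- function(qual = 30, dp = 4, qd = 3, fs = 30, mq = 35,
                         literal = FALSE) {
  th <- list(qual = qual, dp = dp, qd = qd, fs = fs, mq = mq,
             literal = isTRUE(literal))
  if (any(unlist(th[1:5]) < 0)) stop("thresholds must be non-negative")
  th
}

#' Read a per-tissue VCF and apply record-level QC
#'
#' Parses a VCF v4.2 file, drops records failing any
#' \code{\link{qcThresholds}} comparison (strict inequalities, so a record
#' exactly at a boundary is removed), assigns SNP/INDEL class from ref/alt
#' lengths, and converts GT fields to alternative-allele counts.
#'
#' @param path VCF file path.
#' @param thresholds from \code{\link{qcThresholds}}; NULL skips QC.
#' @param tissue optional tissue label (defaults to the file base name).
#' @return A list with \code{tissue}, \code{variants} (chrom, pos, ref,
#'   alt, class), \code{geno} (variants x samples, 0/1/2/NA),
#'   \code{nRemoved} and \code{removedBy} (per-field removal counts;
#'   a record failing several fields counts once per field).
#' @export
readTissueVcf <- function(path, thresholds = qcThresholds(),
                          tissue = sub("\\.vcf(\\.gz)?$", "",
                                       basename(path))) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info <- lapply(c(DP = "DP", QD = "QD", FS = "FS", MQ = "MQ"),
                 function(k) {
                   suppressWarnings(
                     vcfR::extract.info(vcf, element = k, as.numeric = TRUE))
                 })
  keep <- rep(TRUE, nrow(fix))
  removedBy <- c(QUAL = 0L, DP = 0L, QD = 0L, FS = 0L, MQ = 0L)
  if (!is.null(thresholds)) {
    pass <- list(
      QUAL = qual > thresholds$qual,
      DP = info$DP > thresholds$dp,
      QD = info$QD > thresholds$qd,
      FS = if (thresholds$literal) info$FS > thresholds$fs
           else info$FS < thresholds$fs,
      MQ = if (thresholds$literal) info$MQ < thresholds$mq
           else info$MQ > thresholds$mq
    )
    for (k in names(pass)) {
      p <- pass[[k]]
      p[is.na(p)] <- FALSE
      removedBy[k] <- sum(!p)
      keep <- keep & p
    }
  }
  gt <- vcfR::extract.gt(vcf)
  if (is.null(gt)) gt <- matrix(character(0), nrow(fix), 0)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL"),
    stringsAsFactors = FALSE
  )
  list(tissue = tissue,
       variants = variants[keep, , drop = FALSE],
       geno = dosage[keep, , drop = FALSE],
       nRemoved = sum(!keep), removedBy = removedBy)
}
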