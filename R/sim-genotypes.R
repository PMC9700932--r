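#' Simulate genotypes by gene dropping through a pedigree
#'
#' Founder gametes draw alleles independently per locus with frequencies
#' uniform on \code{founderMafRange}; offspring inherit, independently for
#' each cosegregating block of \code{blockBp} bases, one whole block
#' haplotype from each parent (free recombination between blocks, none
#' within).  Chip SNPs and transcribed variants occupy distinct positions
#' on a shared coordinate map.  \code{nQtl} transcribed variants are
#' pre-designated as causal candidates and each receives
#' \code{tagSnpsPerQtl} chip SNPs within \code{tagWindowBp} whose founder
#' alleles copy the causal allele with probability \code{tagFidelity},
#' inducing the local linkage disequilibrium that chip-based prediction
#' relies on.
#'
#' @param ped pedigree data.frame (parents before offspring); validated
#'   with \code{\link{validatePedigree}}.
#' @param config a \linkS4class{SimConfig}.
#' @param geneModel optional \linkS4class{GeneModel}; when supplied,
#'   transcribed variants are placed in exons and their ref/alt alleles are
#'   read off the reference sequence.
#' @return A list with elements \code{chipGeno}, \code{txGeno} (integer
#'   allele-count matrices, rows named by animal), \code{chipMap} and
#'   \code{txMap} (\code{GRanges} with tag/QTL annotation and, for
#'   transcribed variants, ref/alt alleles).
#' @examples
#' cfg <- simConfig(nFounders = 4, nGenerations = 1, nChipSnps = 20,
#'                  nTranscribedVariants = 10, nQtl = 2, seed = 3)
#' g <- simulateGenotypes(simulatePedigree(cfg), cfg)
#' dim(g$chipGeno)
#' @export
simulateGenotypes <- function(ped, config, geneModel = NULL) {
  validatePedigree(ped)
  set.seed(config@seed + 1L)
  glen <- config@genomeLengthBp
  nTx <- config@nTranscribedVariants
  nChip <- config@nChipSnps
  nQtl <- config@nQtl

  # --- positions -----------------------------------------------------------
  if (!is.null(geneModel)) {
    exonPos <- unlist(lapply(geneModel@exons, function(ex) {
      unlist(lapply(seq_len(nrow(ex)), function(i) {
        seq.int(ex$start[i], ex$end[i])
      }))
    }), use.names = FALSE)
    # keep indel anchors away from the last bases of the contig
    exonPos <- exonPos[exonPos < glen - 10L]
    if (length(exonPos) < nTx) {
      stop("gene model has fewer exonic bases than transcribed variants")
    }
    txPos <- sort(sample(exonPos, nTx))
  } else {
    txPos <- sort(sample.int(glen - 10L, nTx))
  }

  qtlTxIdx <- if (nQtl > 0) sort(sample.int(nTx, nQtl)) else integer(0)
  blockOf <- function(pos) (pos - 1L) %/% config@blockBp

  # tag SNPs share the QTL's cosegregating block and lie within the window
  tagPos <- integer(0); tagOfQtl <- integer(0)
  for (q in seq_along(qtlTxIdx)) {
    qp <- txPos[qtlTxIdx[q]]
    blk <- blockOf(qp)
    lo <- max(blk * config@blockBp + 1L, qp - config@tagWindowBp)
    hi <- min((blk + 1L) * config@blockBp, qp + config@tagWindowBp)
    cand <- setdiff(seq.int(lo, hi), c(txPos, tagPos))
    k <- min(config@tagSnpsPerQtl, length(cand), nChip - length(tagPos))
    if (k > 0) {
      tp <- sample(cand, k)
      tagPos <- c(tagPos, tp)
      tagOfQtl <- c(tagOfQtl, rep(q, k))
    }
  }
  nFree <- nChip - length(tagPos)
  taken <- c(txPos, tagPos)
  freePos <- integer(0)
  while (length(freePos) < nFree) {
    cand <- sample.int(glen, 2L * (nFree - length(freePos)))
    freePos <- c(freePos, setdiff(unique(cand), c(taken, freePos)))
  }
  freePos <- freePos[seq_len(nFree)]
  chipPos <- c(tagPos, freePos)
  ord <- order(chipPos)
  chipPos <- chipPos[ord]
  chipTagOf <- c(tagOfQtl, rep(NA_integer_, nFree))[ord]

  # --- joint locus map -----------------------------------------------------
  allPos <- c(chipPos, txPos)
  isChip <- c(rep(TRUE, nChip), rep(FALSE, nTx))
  o <- order(allPos)
  allPos <- allPos[o]; isChip <- isChip[o]
  L <- length(allPos)
  chipIdx <- which(isChip)
  txIdx <- which(!isChip)
  blkId <- match(blockOf(allPos), unique(blockOf(allPos)))
  nBlk <- max(blkId)

  p <- runif(L, config@founderMafRange[1], config@founderMafRange[2])

  n <- nrow(ped)
  H1 <- matrix(0L, n, L)
  H2 <- matrix(0L, n, L)
  founder <- is.na(ped$sire)
  nF <- sum(founder)
  H1[founder, ] <- matrix(rbinom(nF * L, 1L, rep(p, each = nF)), nF, L)
  H2[founder, ] <- matrix(rbinom(nF * L, 1L, rep(p, each = nF)), nF, L)

  # founder tag alleles copy the causal allele with probability tagFidelity
  qtlLoc <- txIdx[qtlTxIdx]
  tagLoc <- chipIdx[!is.na(chipTagOf)]
  tagQtlLoc <- qtlLoc[chipTagOf[!is.na(chipTagOf)]]
  for (j in seq_along(tagLoc)) {
    for (H in c("H1", "H2")) {
      M <- get(H)
      keep <- rbinom(nF, 1L, config@tagFidelity) == 1L
      src <- M[founder, tagQtlLoc[j]]
      M[founder, tagLoc[j]] <- ifelse(keep, src, 1L - src)
      assign(H, M)
    }
  }

  rowOf <- seq_len(n)
  names(rowOf) <- as.character(ped$animal)
  for (i in which(!founder)) {
    s <- rowOf[as.character(ped$sire[i])]
    d <- rowOf[as.character(ped$dam[i])]
    pickS <- (runif(nBlk) < 0.5)[blkId]
    pickD <- (runif(nBlk) < 0.5)[blkId]
    H1[i, ] <- ifelse(pickS, H1[s, ], H2[s, ])
    H2[i, ] <- ifelse(pickD, H1[d, ], H2[d, ])
  }
  G <- H1 + H2
  rownames(G) <- as.character(ped$animal)

  # --- alleles for transcribed variants ------------------------------------
  bases <- c("A", "C", "G", "T")
  nIndel <- round(config@indelFraction * nTx)
  indel <- rep(FALSE, nTx)
  if (nIndel > 0) indel[sample.int(nTx, nIndel)] <- TRUE
  refBase <- function(pos, len = 1L) {
    if (!is.null(geneModel)) {
      as.character(Biostrings::subseq(geneModel@genome[[1]], pos,
                                      pos + len - 1L))
    } else {
      paste(sample(bases, len, replace = TRUE), collapse = "")
    }
  }
  ref <- alt <- character(nTx)
  for (v in seq_len(nTx)) {
    pos <- txPos[v]
    if (!indel[v]) {
      ref[v] <- refBase(pos)
      alt[v] <- sample(setdiff(bases, ref[v]), 1)
    } else if (runif(1) < 0.5) {           # deletion, VCF left-anchored
      len <- sample(1:3, 1)
      ref[v] <- refBase(pos, len + 1L)
      alt[v] <- substr(ref[v], 1, 1)
    } else {                               # insertion
      ref[v] <- refBase(pos)
      alt[v] <- paste0(ref[v],
                       paste(sample(bases, sample(1:3, 1), replace = TRUE),
                             collapse = ""))
    }
  }

  chipMap <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(chipPos, width = 1),
    tagOf = chipTagOf
  )
  names(chipMap) <- sprintf("SNP%05d", seq_len(nChip))
  txQtl <- rep(FALSE, nTx); txQtl[qtlTxIdx] <- TRUE
  txMap <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(txPos, width = 1),
    ref = ref, alt = alt,
    class = ifelse(indel, "INDEL", "SNP"),
    qtlCandidate = txQtl
  )
  names(txMap) <- sprintf("VAR%05d", seq_len(nTx))

  chipGeno <- G[, chipIdx, drop = FALSE]
  txGeno <- G[, txIdx, drop = FALSE]
  colnames(chipGeno) <- names(chipMap)
  colnames(txGeno) <- names(txMap)
  list(chipGeno = chipGeno, txGeno = txGeno,
       chipMap = chipMap, txMap = txMap)
}
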