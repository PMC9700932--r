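#' Write per-tissue VCFs for the extreme-group animals
#'
#' Emulates multi-organ RNA-seq variant calling: each organ exposes a fixed
#' random subset of the transcribed variants (drawn once per simulation with
#' its configured callability), genotypes are written for that organ's
#' sampled animals with per-genotype missingness, and every record carries
#' QUAL plus DP, QD, FS and MQ INFO fields.  A configurable fraction of
#' records is written with one deliberately failing quality field so that
#' record-level QC is exercisable downstream.
#'
#' @param herd a \linkS4class{Herd}.
#' @param sampleIds character, animals to genotype (typically the pooled
#'   high/low feed-efficiency extremes).
#' @param dir output directory (created if needed).
#' @return A list of per-tissue call sets, each with elements
#'   \code{tissue}, \code{path}, \code{sampleIds} and \code{callableIds}.
#' @export
writeTissueVcfs <- function(herd, sampleIds, dir) {
  config <- herd@config
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir)
  }
  sampleIds <- as.character(sampleIds)
  stopifnot(all(sampleIds %in% rownames(herd@txGeno)))
  set.seed(config@seed + 4L)
  nTx <- ncol(herd@txGeno)
  m <- GenomicRanges::mcols(herd@txMap)
  pos <- GenomicRanges::start(herd@txMap)

  failField <- c("QUAL", "DP", "QD", "FS", "MQ")
  out <- vector("list", config@nTissues)
  for (t in seq_len(config@nTissues)) {
    tis <- config@tissueNames[t]
    nSamp <- min(config@tissueSamples[t], length(sampleIds))
    samp <- sort(sample(sampleIds, nSamp))
    callable <- which(runif(nTx) < config@tissueCallability[t])

    nV <- length(callable)
    qual <- round(runif(nV, 60, 2000), 1)
    dp <- round(runif(nV, 8, 100))
    qd <- round(runif(nV, 5, 30), 2)
    fs <- round(runif(nV, 0, 10), 2)
    mq <- round(runif(nV, 40, 60), 1)
    fail <- runif(nV) < config@qcFailRate
    for (v in which(fail)) {
      switch(sample(failField, 1),
             QUAL = { qual[v] <- 10 }, DP = { dp[v] <- 2 },
             QD = { qd[v] <- 1 }, FS = { fs[v] <- 60 }, MQ = { mq[v] <- 20 })
    }

    gt <- herd@txGeno[samp, callable, drop = FALSE]
    miss <- matrix(runif(length(gt)) < config@perSampleMissingRate,
                   nrow(gt), ncol(gt))
    gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
    gtStr[miss] <- "./."

    path <- file.path(dir, paste0(tis, ".vcf"))
    header <- c(
      "##fileformat=VCFv4.2",
      paste0("##contig=<ID=1,length=", config@genomeLengthBp, ">"),
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
      "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
      "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand phred p\">",
      "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", samp), collapse = "\t")
    )
    body <- vapply(seq_len(nV), function(i) {
      v <- callable[i]
      paste(c("1", pos[v], names(herd@txMap)[v], m$ref[v], m$alt[v],
              qual[i], ".",
              sprintf("DP=%d;QD=%s;FS=%s;MQ=%s", dp[i], qd[i], fs[i], mq[i]),
              "GT", gtStr[, i]), collapse = "\t")
    }, character(1))
    con <- tryCatch(file(path, "w"), error = function(e) {
      stop("cannot write VCF to ", path, ": ", conditionMessage(e))
    })
    writeLines(c(header, body), con)
    close(con)
    out[[t]] <- list(tissue = tis, path = path, sampleIds = samp,
                     callableIds = names(herd@txMap)[callable])
  }
  names(out) <- config@tissueNames
  out
}
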