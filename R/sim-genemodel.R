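#' Simulate a toy genome and gene model
#'
#' Builds a single random contig and tiles it with evenly spaced
#' protein-coding genes of three 300-bp exons separated by 500-bp introns
#' (CDS = exons, 300 codons).  Coding regions are sanitised: the CDS starts
#' with ATG, ends with a TAA stop, and contains no internal stop codons, so
#' every consequence class is reachable by mutation.  Strand alternates
#' between genes to exercise minus-strand classification.
#'
#' @param config a \linkS4class{SimConfig}; \code{genomeLengthBp} sets the
#'   contig length.
#' @param nGenes number of genes to place; the default scales with the
#'   transcribed-variant panel so exonic space is ample.
#' @param seed RNG seed; defaults to \code{config@seed + 7}.
#' @return A \linkS4class{GeneModel}.
#' @examples
#' gm <- simulateGeneModel(simConfig(genomeLengthBp = 1e5, seed = 1),
#'                         nGenes = 4)
#' gm
#' @export
simulateGeneModel <- function(config,
                              nGenes = max(20L, ceiling(
                                config@nTranscribedVariants / 150)),
                              seed = config@seed + 7L) {
  set.seed(seed)
  glen <- config@genomeLengthBp
  bases <- c("A", "C", "G", "T")
  seqChars <- sample(bases, glen, replace = TRUE)

  exonLen <- 300L; intronLen <- 500L; nExons <- 3L
  footprint <- nExons * exonLen + (nExons - 1L) * intronLen
  spacing <- (glen - 2000L) %/% nGenes
  if (spacing <= footprint) {
    stop("genome too short for ", nGenes, " genes; increase genomeLengthBp")
  }
  codons <- names(Biostrings::GENETIC_CODE)
  senseCodons <- codons[Biostrings::GENETIC_CODE != "*"]
  senseCodons <- setdiff(senseCodons, "ATG")

  transcripts <- data.frame(
    txId = sprintf("TX%04d", seq_len(nGenes)),
    geneId = sprintf("G%04d", seq_len(nGenes)),
    chrom = "1",
    strand = rep_len(c("+", "-"), nGenes),
    stringsAsFactors = FALSE
  )
  exons <- cds <- vector("list", nGenes)
  names(exons) <- names(cds) <- transcripts$txId

  for (i in seq_len(nGenes)) {
    gStart <- (i - 1L) * spacing + 1000L
    exStart <- gStart + (seq_len(nExons) - 1L) * (exonLen + intronLen)
    ex <- data.frame(start = exStart, end = exStart + exonLen - 1L)
    exons[[i]] <- cds[[i]] <- ex
    # sanitised coding sequence in transcription order
    nCodon <- nExons * exonLen / 3L
    cdsSeq <- c("ATG", sample(senseCodons, nCodon - 2L, replace = TRUE), "TAA")
    cdsChars <- strsplit(paste(cdsSeq, collapse = ""), "")[[1]]
    if (transcripts$strand[i] == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      cdsChars <- rev(unname(comp[cdsChars]))
    }
    genomicPos <- unlist(lapply(seq_len(nExons), function(e) {
      seq.int(ex$start[e], ex$end[e])
    }))
    seqChars[genomicPos] <- cdsChars
  }

  genome <- Biostrings::DNAStringSet(paste(seqChars, collapse = ""))
  names(genome) <- "1"
  new("GeneModel", transcripts = transcripts, exons = exons, cds = cds,
      genome = genome)
}

#' Write a gene model to GFF3 and FASTA
#'
#' @param model a \linkS4class{GeneModel}.
#' @param gffPath,fastaPath output file paths.
#' @return Invisibly, the two paths.
#' @export
writeGeneModel <- function(model, gffPath, fastaPath) {
  lines <- c("##gff-version 3")
  tr <- model@transcripts
  for (i in seq_len(nrow(tr))) {
    tx <- tr$txId[i]
    ex <- model@exons[[tx]]
    cd <- model@cds[[tx]]
    g <- function(type, s, e, id, parent = NULL) {
      attr <- if (is.null(parent)) paste0("ID=", id) else
        paste0("ID=", id, ";Parent=", parent)
      s <- format(s, scientific = FALSE); e <- format(e, scientific = FALSE)
      paste(tr$chrom[i], "toy", type, s, e, ".", tr$strand[i],
            if (type == "CDS") "0" else ".", attr, sep = "\t")
    }
    lines <- c(lines,
               g("gene", min(ex$start), max(ex$end), tr$geneId[i]),
               g("mRNA", min(ex$start), max(ex$end), tx, tr$geneId[i]),
               vapply(seq_len(nrow(ex)), function(e) {
                 g("exon", ex$start[e], ex$end[e],
                   paste0(tx, ".exon", e), tx)
               }, character(1)),
               vapply(seq_len(nrow(cd)), function(e) {
                 g("CDS", cd$start[e], cd$end[e],
                   paste0(tx, ".cds", e), tx)
               }, character(1)))
  }
  writeLines(lines, gffPath)
  Biostrings::writeXStringSet(model@genome, fastaPath)
  invisible(c(gff = gffPath, fasta = fastaPath))
}
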