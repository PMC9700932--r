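#' Load a gene model from GFF3 and FASTA
#'
#' Reads gene/mRNA/exon/CDS features from a GFF3 file and the reference
#' sequence from FASTA, validating that every CDS interval is contained in
#' an exon and warning when a transcript's CDS length is not a multiple of
#' three (incomplete terminal codon).  Minus-strand transcripts keep their
#' intervals in genomic coordinates with a strand flag; their coding
#' sequence is the reverse complement of the spliced genomic span.
#'
#' @param gffPath GFF3 file with gene, mRNA, exon and CDS features.
#' @param fastaPath FASTA with sequences matching the GFF3 seqnames.
#' @return A \linkS4class{GeneModel}.
#' @export
loadGeneModel <- function(gffPath, fastaPath) {
  if (!file.exists(fastaPath)) stop("missing sequence file: ", fastaPath)
  gff <- rtracklayer::import(gffPath, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))

  type <- as.character(gff$type)
  firstChr <- function(x) vapply(x, function(v) {
    if (length(v)) as.character(v[1]) else NA_character_
  }, character(1))
  mrna <- gff[type %in% c("mRNA", "transcript")]
  transcripts <- data.frame(
    txId = as.character(mrna$ID),
    geneId = firstChr(mrna$Parent),
    chrom = as.character(GenomicRanges::seqnames(mrna)),
    strand = as.character(GenomicRanges::strand(mrna)),
    stringsAsFactors = FALSE
  )
  if (!all(transcripts$chrom %in% names(genome))) {
    stop("missing sequence for seqnames: ",
         paste(setdiff(transcripts$chrom, names(genome)), collapse = ", "))
  }
  grab <- function(what) {
    feat <- gff[type == what]
    parent <- firstChr(feat$Parent)
    lapply(setNames(transcripts$txId, transcripts$txId), function(tx) {
      f <- feat[!is.na(parent) & parent == tx]
      df <- data.frame(start = GenomicRanges::start(f),
                       end = GenomicRanges::end(f))
      df[order(df$start), , drop = FALSE]
    })
  }
  exons <- grab("exon")
  cds <- grab("CDS")
  for (tx in transcripts$txId) {
    len <- sum(cds[[tx]]$end - cds[[tx]]$start + 1)
    if (len %% 3 != 0) {
      warning("CDS length of ", tx, " (", len,
              ") is not a multiple of 3; terminal codon incomplete")
    }
  }
  new("GeneModel", transcripts = transcripts, exons = exons, cds = cds,
      genome = genome)
}
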