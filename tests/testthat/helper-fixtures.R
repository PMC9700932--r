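# Shared fixtures: a hand-built two-gene model (plus and minus strand
# copies of the same CDS) and small herd configurations.

# CDS in transcription order: ATG ATG AAA | TGG TAA  (M M K W *)
# plus-strand gene: exon1 101-109, intron 110-129, exon2 130-135
# minus-strand gene: exon 201-206 ("TTACCA") , intron 207-226,
#   exon 227-235 ("TTTCATCAT"); transcription right-to-left
makeToyGeneModel <- function() {
  chars <- rep("C", 400)
  put <- function(chars, at, s) {
    chars[seq.int(at, at + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    chars
  }
  chars <- put(chars, 101, "ATGATGAAA")
  chars <- put(chars, 130, "TGGTAA")
  chars <- put(chars, 227, "TTTCATCAT")
  chars <- put(chars, 201, "TTACCA")
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "T"
  transcripts <- data.frame(
    txId = c("TXP", "TXM"), geneId = c("GP", "GM"),
    chrom = "T", strand = c("+", "-"), stringsAsFactors = FALSE
  )
  exons <- list(
    TXP = data.frame(start = c(101, 130), end = c(109, 135)),
    TXM = data.frame(start = c(201, 227), end = c(206, 235))
  )
  new("GeneModel", transcripts = transcripts, exons = exons,
      cds = exons, genome = genome)
}

toyVariant <- function(pos, ref, alt, chrom = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# classify a single toy variant against one transcript; returns terms
toyTerms <- function(model, pos, ref, alt, tx = "TXP") {
  calls <- classifyVariants(toyVariant(pos, ref, alt), model,
                            allTranscripts = TRUE)
  row <- calls[!is.na(calls$txId) & calls$txId == tx, ]
  if (nrow(row) == 0) return("intergenic")
  strsplit(row$terms, ",")[[1]]
}

smallHerdConfig <- function(seed = 1, ...) {
  simConfig(nFounders = 12, nGenerations = 2, offspringPerMating = 3,
            nChipSnps = 40, nTranscribedVariants = 30, nQtl = 3,
            nCg = 2, seed = seed, ...)
}
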