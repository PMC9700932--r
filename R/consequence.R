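consequenceTerms <- c(
  "stop_gained", "frameshift", "splice_donor", "splice_acceptor",
  "stop_lost", "start_lost",
  "missense", "inframe_insertion", "inframe_deletion",
  "synonymous", "splice_region", "start_retained",
  "intron_variant", "intergenic"
)

impactLevels <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

termImpact <- c(
  stop_gained = "HIGH", frameshift = "HIGH", splice_donor = "HIGH",
  splice_acceptor = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  missense = "MODERATE", inframe_insertion = "MODERATE",
  inframe_deletion = "MODERATE",
  synonymous = "LOW", splice_region = "LOW", start_retained = "LOW",
  intron_variant = "MODIFIER", intergenic = "MODIFIER"
)

#' Impact class of a set of consequence terms
#'
#' Ensembl-style severity roll-up: HIGH terms truncate the protein or
#' destroy splicing/initiation (stop_gained, frameshift, splice_donor,
#' splice_acceptor, stop_lost, start_lost); MODERATE terms alter the
#' protein non-disruptively (missense, inframe insertion/deletion); LOW
#' terms are unlikely to change protein behaviour (synonymous,
#' splice_region, start_retained); MODIFIER covers non-coding effects.  A
#' multi-term variant takes the maximum severity.
#'
#' @param terms character vector of consequence terms.
#' @return One of "HIGH", "MODERATE", "LOW", "MODIFIER".
#' @examples
#' impactOf(c("missense", "splice_region"))
#' @export
impactOf <- function(terms) {
  if (!length(terms)) return("MODIFIER")
  bad <- setdiff(terms, names(termImpact))
  if (length(bad)) stop("unknown consequence term: ",
                        paste(bad, collapse = ", "))
  impactLevels[max(match(termImpact[terms], impactLevels))]
}

# spliced CDS of one transcript in transcription order:
# genomic positions and strand-adjusted bases
splicedCds <- function(model, tx) {
  info <- model@transcripts[model@transcripts$txId == tx, ]
  cd <- model@cds[[tx]]
  pos <- unlist(lapply(seq_len(nrow(cd)), function(i) {
    seq.int(cd$start[i], cd$end[i])
  }))
  seq <- strsplit(as.character(
    model@genome[[info$chrom]][pos]), "")[[1]]
  if (info$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    pos <- rev(pos)
    seq <- rev(unname(comp[seq]))
  }
  list(pos = pos, seq = seq, strand = info$strand, chrom = info$chrom)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# classify one variant against one transcript; returns character terms
# plus protein annotation in attributes
classifyOne <- function(chrom, pos, ref, alt, model, tx) {
  info <- model@transcripts[model@transcripts$txId == tx, ]
  ex <- model@exons[[tx]]
  terms <- character(0)
  protPos <- NA_integer_
  protAlt <- NA_character_

  isIndel <- nchar(ref) != 1L || nchar(alt) != 1L
  lenDiff <- nchar(alt) - nchar(ref)
  # genomic positions whose identity the variant changes
  affected <- if (!isIndel) pos
              else if (lenDiff < 0) seq.int(pos + 1L, pos + nchar(ref) - 1L)
              else c(pos, pos + 1L)       # insertion breakpoint flanks
  txStart <- min(ex$start); txEnd <- max(ex$end)
  if (max(affected) < txStart || min(affected) > txEnd) {
    return(structure("intergenic", proteinPosition = protPos,
                     proteinAlteration = protAlt))
  }

  # --- splice-site terms ---------------------------------------------------
  if (nrow(ex) > 1) {
    introns <- data.frame(start = ex$end[-nrow(ex)] + 1L,
                          end = ex$start[-1] - 1L)
    for (i in seq_len(nrow(introns))) {
      is <- introns$start[i]; ie <- introns$end[i]
      donor <- if (info$strand == "+") seq.int(is, is + 1L)
               else seq.int(ie - 1L, ie)
      acceptor <- if (info$strand == "+") seq.int(ie - 1L, ie)
                  else seq.int(is, is + 1L)
      safeSeq <- function(a, b) if (a <= b) seq.int(a, b) else integer(0)
      region <- c(safeSeq(is + 2L, min(is + 7L, ie)),
                  safeSeq(max(ie - 7L, is), ie - 2L),
                  safeSeq(max(is - 3L, txStart), is - 1L),
                  safeSeq(ie + 1L, min(ie + 3L, txEnd)))
      if (any(affected %in% donor)) terms <- c(terms, "splice_donor")
      if (any(affected %in% acceptor)) terms <- c(terms, "splice_acceptor")
      if (any(affected %in% setdiff(region, c(donor, acceptor)))) {
        terms <- c(terms, "splice_region")
      }
    }
  }

  # --- coding terms --------------------------------------------------------
  cdsInfo <- splicedCds(model, tx)
  cdsPos <- cdsInfo$pos; cdsSeq <- cdsInfo$seq
  nC <- length(cdsPos)
  minus <- info$strand == "-"

  if (nC == 0L) {
    if (!length(terms)) terms <- "intron_variant"
    return(structure(unique(terms), proteinPosition = protPos,
                     proteinAlteration = protAlt))
  }
  if (!isIndel) {
    i <- match(pos, cdsPos)
    if (!is.na(i)) {
      refTx <- if (minus) revComp(ref) else ref
      altTx <- if (minus) revComp(alt) else alt
      if (cdsSeq[i] != refTx) {
        stop("reference-mismatch error at ", chrom, ":", pos,
             " (expected ", if (minus) revComp(cdsSeq[i]) else cdsSeq[i],
             ", got ", ref, ")")
      }
      codonIdx <- (i - 1L) %/% 3L + 1L
      cFrom <- 3L * (codonIdx - 1L) + 1L
      refCodon <- paste(cdsSeq[cFrom:(cFrom + 2L)], collapse = "")
      altSeq <- cdsSeq; altSeq[i] <- altTx
      altCodon <- paste(altSeq[cFrom:(cFrom + 2L)], collapse = "")
      refAa <- translateCodon(refCodon)
      altAa <- translateCodon(altCodon)
      protPos <- codonIdx
      protAlt <- paste0(refAa, "/", altAa)
      if (codonIdx == 1L) {
        terms <- c(terms,
                   if (altCodon == "ATG") "start_retained" else "start_lost")
      } else if (refAa == "*") {
        terms <- c(terms, if (altAa == "*") "synonymous" else "stop_lost")
      } else if (altAa == "*") {
        terms <- c(terms, "stop_gained")
      } else if (refAa == altAa) {
        terms <- c(terms, "synonymous")
      } else {
        terms <- c(terms, "missense")
      }
    }
  } else if (lenDiff < 0) {                       # deletion
    delPos <- seq.int(pos + 1L, pos + nchar(ref) - 1L)
    idx <- sort(match(delPos, cdsPos))
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      protPos <- (min(idx) - 1L) %/% 3L + 1L
      if (length(idx) %% 3L != 0L) {
        terms <- c(terms, "frameshift")
      } else {
        terms <- c(terms, "inframe_deletion")
      }
      if (any(idx <= 3L)) {
        newStart <- paste(cdsSeq[setdiff(seq_len(nC), idx)][1:3],
                          collapse = "")
        terms <- c(terms,
                   if (identical(newStart, "ATG")) "start_retained"
                   else "start_lost")
      }
      if (any(idx > nC - 3L)) terms <- c(terms, "stop_lost")
    }
  } else {                                        # insertion
    iLeft <- match(pos, cdsPos)
    iRight <- match(pos + 1L, cdsPos)
    inside <- !is.na(iLeft) && !is.na(iRight) && abs(iLeft - iRight) == 1L
    if (inside) {
      protPos <- (min(iLeft, iRight) - 1L) %/% 3L + 1L
      terms <- c(terms, if (lenDiff %% 3L != 0L) "frameshift"
                        else "inframe_insertion")
      insAt <- min(iLeft, iRight)      # insertion after this CDS index
      if (insAt < 3L) {
        insBases <- substr(alt, 2L, nchar(alt))
        if (minus) insBases <- revComp(insBases)
        newSeq <- c(cdsSeq[seq_len(insAt)], strsplit(insBases, "")[[1]],
                    cdsSeq[seq.int(insAt + 1L, nC)])
        terms <- c(terms,
                   if (identical(paste(newSeq[1:3], collapse = ""), "ATG"))
                     "start_retained" else "start_lost")
      }
    }
  }

  if (!length(terms)) terms <- "intron_variant"
  structure(unique(terms), proteinPosition = protPos,
            proteinAlteration = protAlt)
}

#' Classify variants against a gene model
#'
#' Assigns sequence-ontology consequence terms and Ensembl-style impact
#' classes per variant and transcript.  Coding SNVs are translated with
#' the standard genetic code (missense, synonymous, stop_gained,
#' stop_lost, start_lost, start_retained); CDS indels are frameshift when
#' their length is not a multiple of three, otherwise inframe
#' insertion/deletion; the first two intronic bases on the 5'/3' side of
#' each intron are splice_donor/splice_acceptor; splice_region covers 3-8
#' bases into the intron or 1-3 bases into the exon.  Variants use VCF
#' conventions (1-based positions, indels left-anchored); the ref allele
#' is checked against the reference sequence.
#'
#' @param variantTable data.frame with columns chrom, pos, ref, alt.
#' @param model a \linkS4class{GeneModel}.
#' @param allTranscripts logical; by default only the canonical (first
#'   listed) transcript of each gene is consulted.
#' @return data.frame with one row per variant-transcript pair (plus
#'   intergenic rows with NA transcript): chrom, pos, ref, alt, txId,
#'   geneId, terms (comma-separated), impact, proteinPosition,
#'   proteinAlteration.
#' @export
classifyVariants <- function(variantTable, model, allTranscripts = FALSE) {
  tr <- model@transcripts
  if (!allTranscripts) tr <- tr[!duplicated(tr$geneId), , drop = FALSE]
  spans <- data.frame(
    txId = tr$txId, chrom = tr$chrom,
    start = vapply(tr$txId, function(tx) min(model@exons[[tx]]$start),
                   numeric(1)),
    end = vapply(tr$txId, function(tx) max(model@exons[[tx]]$end),
                 numeric(1))
  )
  pad <- 8L  # splice-region reach beyond nothing; margin for indel spans
  res <- vector("list", nrow(variantTable))
  for (v in seq_len(nrow(variantTable))) {
    chrom <- as.character(variantTable$chrom[v])
    pos <- as.integer(variantTable$pos[v])
    ref <- as.character(variantTable$ref[v])
    alt <- as.character(variantTable$alt[v])
    refObs <- as.character(model@genome[[chrom]][
      seq.int(pos, pos + nchar(ref) - 1L)])
    if (!identical(refObs, ref)) {
      stop("reference-mismatch error at ", chrom, ":", pos,
           " (sequence has ", refObs, ", variant claims ", ref, ")")
    }
    hit <- spans$chrom == chrom &
      pos + nchar(ref) - 1L >= spans$start - pad & pos <= spans$end + pad
    if (!any(hit)) {
      res[[v]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        txId = NA_character_, geneId = NA_character_,
        terms = "intergenic", impact = "MODIFIER",
        proteinPosition = NA_integer_,
        proteinAlteration = NA_character_, stringsAsFactors = FALSE)
      next
    }
    rows <- lapply(spans$txId[hit], function(tx) {
      cl <- classifyOne(chrom, pos, ref, alt, model, tx)
      data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        txId = tx, geneId = tr$geneId[tr$txId == tx],
        terms = paste(cl, collapse = ","),
        impact = impactOf(as.character(cl)),
        proteinPosition = attr(cl, "proteinPosition"),
        proteinAlteration = attr(cl, "proteinAlteration"),
        stringsAsFactors = FALSE)
    })
    res[[v]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select potential functional variants
#'
#' Intersects the significantly associated variants with the chosen
#' impact classes.  Impact is rolled up per variant as the most severe
#' impact over its transcript calls.
#'
#' @param assoc association results from \code{\link{allelicAssociation}}.
#' @param calls consequence calls from \code{\link{classifyVariants}}.
#' @param impactSet impact classes that qualify a variant as a PFV.
#' @return data.frame of PFVs (chrom, pos, ref, alt, impact, terms, chi2,
#'   p), one row per selected variant.
#' @export
selectPFVs <- function(assoc, calls, impactSet = c("HIGH")) {
  if (is.null(assoc) || nrow(assoc) == 0) {
    stop("invalid input: empty association results")
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  callKey <- key(calls)
  imp <- tapply(calls$impact, callKey, function(x) {
    impactLevels[max(match(x, impactLevels))]
  })
  term <- tapply(calls$terms, callKey, function(x) {
    paste(unique(unlist(strsplit(x, ","))), collapse = ",")
  })
  aKey <- key(assoc)
  sel <- assoc$significant & aKey %in% names(imp)[imp %in% impactSet]
  out <- assoc[sel, c("chrom", "pos", "ref", "alt", "chi2", "p"),
               drop = FALSE]
  out$impact <- unname(imp[aKey[sel]])
  out$terms <- unname(term[aKey[sel]])
  rownames(out) <- NULL
  out
}
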