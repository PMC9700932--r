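#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats lm coef residuals rnorm runif rbinom pchisq qchisq sd var
#'   cor model.matrix setNames aggregate binom.test complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' Simulation configuration for a synthetic herd
#'
#' Holds every tunable of the synthetic-herd generator: pedigree structure,
#' marker panel and transcribed-variant panel sizes, trait architecture,
#' feedlot-trial layout and per-tissue variant-calling behaviour.  Defaults
#' emulate a feedlot trial of 98 Nellore bulls genotyped for feed efficiency:
#' a 70-day test with fortnightly weighing, contemporary groups, five sampled
#' organs with partial per-tissue callability, and two extreme
#' residual-feed-intake groups of nine animals each.
#'
#' @slot nFounders integer, number of pedigree founders (generation 0).
#' @slot nGenerations integer, number of descendant generations.
#' @slot offspringPerMating integer, offspring produced by each mating pair.
#' @slot nChipSnps integer, chip (array) SNPs on the marker map.
#' @slot nTranscribedVariants integer, variants segregating in transcribed
#'   (exonic) sequence, callable from RNA-seq.
#' @slot nQtl integer, number of causal transcribed variants (true PFVs).
#' @slot heritability numeric in (0,1), narrow-sense heritability of the
#'   genetic feed-intake component (true RFI).
#' @slot founderMafRange numeric length 2, uniform range for founder minor
#'   allele frequencies.
#' @slot genomeLengthBp integer, length of the single toy contig.
#' @slot blockBp integer, length of a cosegregating linkage block: gametes
#'   recombine freely between blocks and never within one.
#' @slot nTissues integer, number of sampled organs.
#' @slot tissueNames character, organ labels.
#' @slot tissueCallability numeric, per-organ probability that a transcribed
#'   variant is callable in that organ (recycled to \code{nTissues}).
#' @slot tissueSamples integer, number of extreme-group animals sampled per
#'   organ (recycled; capped at the number of extreme animals).
#' @slot perSampleMissingRate numeric, probability a written genotype is
#'   missing ("./.").
#' @slot qcFailRate numeric, fraction of VCF records written with one
#'   deliberately failing QC field.
#' @slot indelFraction numeric, fraction of transcribed variants that are
#'   short indels rather than SNVs.
#' @slot nCg integer, number of contemporary groups.
#' @slot testDays integer, days in the feedlot test.
#' @slot nPerGroup integer, animals per extreme feed-efficiency group.
#' @slot tagSnpsPerQtl integer, chip SNPs placed adjacent to each QTL.
#' @slot tagWindowBp integer, maximum distance (bp) of a tag SNP from its QTL.
#' @slot tagFidelity numeric, probability a founder tag-SNP allele copies the
#'   QTL allele on the same gamete (controls tag-QTL linkage disequilibrium).
#' @slot seed integer, master RNG seed.
#' @export
setClass("SimConfig", representation(
  nFounders = "integer", nGenerations = "integer",
  offspringPerMating = "integer", nChipSnps = "integer",
  nTranscribedVariants = "integer", nQtl = "integer",
  heritability = "numeric", founderMafRange = "numeric",
  genomeLengthBp = "integer", blockBp = "integer",
  nTissues = "integer", tissueNames = "character",
  tissueCallability = "numeric", tissueSamples = "integer",
  perSampleMissingRate = "numeric", qcFailRate = "numeric",
  indelFraction = "numeric", nCg = "integer", testDays = "integer",
  nPerGroup = "integer", tagSnpsPerQtl = "integer",
  tagWindowBp = "integer", tagFidelity = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  frac <- c(
    heritability = object@heritability,
    perSampleMissingRate = object@perSampleMissingRate,
    qcFailRate = object@qcFailRate, indelFraction = object@indelFraction,
    tagFidelity = object@tagFidelity, object@tissueCallability,
    object@founderMafRange
  )
  if (any(frac < 0 | frac > 1)) {
    msg <- c(msg, "all fractions must lie in [0, 1]")
  }
  if (object@heritability <= 0 || object@heritability >= 1) {
    msg <- c(msg, "heritability must lie strictly in (0, 1)")
  }
  if (object@nQtl > object@nTranscribedVariants) {
    msg <- c(msg, "nQtl cannot exceed nTranscribedVariants")
  }
  if (object@nFounders < 2) msg <- c(msg, "need at least 2 founders")
  if (object@founderMafRange[1] > object@founderMafRange[2]) {
    msg <- c(msg, "founderMafRange must be increasing")
  }
  if (length(object@tissueNames) != object@nTissues) {
    msg <- c(msg, "tissueNames must have length nTissues")
  }
  if (object@nGenerations < 0) msg <- c(msg, "nGenerations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic herd: pedigree, genotypes, trait architecture and phenotypes
#'
#' Container for one realisation of the synthetic-herd generator.  Chip SNPs
#' and transcribed variants live on a shared coordinate map (single contig,
#' distinct positions); genotypes are allele counts of the alternative
#' allele.  The true-RFI genetic component (\code{tbv}) enters daily
#' dry-matter intake only, so true RFI is well defined as tbv + residual.
#'
#' @slot config the generating \linkS4class{SimConfig}.
#' @slot pedigree data.frame with columns animal, sire, dam, generation,
#'   sex; parents precede offspring.
#' @slot chipGeno integer matrix animals x chip SNPs, values 0/1/2.
#' @slot chipMap \link[GenomicRanges]{GRanges} of chip-SNP positions; the
#'   metadata column \code{tagOf} holds the QTL index a tag SNP was placed
#'   next to (NA otherwise).
#' @slot txGeno integer matrix animals x transcribed variants.
#' @slot txMap \code{GRanges} of transcribed-variant positions with ref/alt
#'   alleles and a \code{qtlCandidate} flag.
#' @slot qtl data.frame of causal variants: txIndex, position, effect.
#' @slot tbv numeric, true breeding value (genetic RFI component) per animal.
#' @slot residualSd numeric, residual standard deviation implied by the
#'   configured heritability.
#' @slot animals data.frame of per-animal feedlot records (cg, dmi, age,
#'   true ADG and mid-test weight).
#' @slot bodyWeight data.frame of the longitudinal weighings (animal, dit, bw).
#' @slot geneModel a \linkS4class{GeneModel} or NULL.
#' @export
setClass("Herd", representation(
  config = "SimConfig", pedigree = "data.frame",
  chipGeno = "matrix", chipMap = "GRanges",
  txGeno = "matrix", txMap = "GRanges",
  qtl = "data.frame", tbv = "numeric", residualSd = "numeric",
  animals = "data.frame", bodyWeight = "data.frame",
  geneModel = "ANY"
))

#' Toy gene model
#'
#' Transcript structures (exons and CDS, 1-based inclusive genomic
#' coordinates, strand-aware) over a reference sequence, sufficient for
#' sequence-ontology consequence classification of SNVs and short indels.
#'
#' @slot transcripts data.frame: txId, geneId, chrom, strand, cdsStart,
#'   cdsEnd.
#' @slot exons named list (by txId) of data.frames with columns start, end,
#'   ordered by genomic position, non-overlapping.
#' @slot cds named list (by txId) of data.frames with columns start, end.
#' @slot genome \link[Biostrings]{DNAStringSet} holding the reference
#'   sequence(s).
#' @export
setClass("GeneModel", representation(
  transcripts = "data.frame", exons = "list", cds = "list",
  genome = "DNAStringSet"
))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  for (tx in object@transcripts$txId) {
    ex <- object@exons[[tx]]
    if (is.null(ex)) { msg <- c(msg, paste("missing exons for", tx)); next }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      msg <- c(msg, paste("overlapping exons in", tx))
    }
    cd <- object@cds[[tx]]
    if (!is.null(cd) && nrow(cd)) {
      inExon <- vapply(seq_len(nrow(cd)), function(i) {
        any(cd$start[i] >= ex$start & cd$end[i] <= ex$end)
      }, logical(1))
      if (!all(inExon)) msg <- c(msg, paste("CDS outside exons in", tx))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Merged multi-tissue unique-variant table
#'
#' Union of per-tissue variant call sets keyed by (chrom, pos, ref, alt),
#' with per-tissue presence flags, merged per-sample genotypes over the
#' pooled extreme animals, and pooled minor-allele frequency and call rate.
#'
#' @slot variants data.frame: chrom, pos, ref, alt, class (SNP/INDEL),
#'   maf, callRate; one row per unique variant key.
#' @slot presence logical matrix variants x tissues.
#' @slot geno integer matrix variants x samples (0/1/2, NA = missing),
#'   genotype conflicts across tissues resolved by majority vote
#'   (ties become missing).
#' @export
setClass("UniqueVariantTable", representation(
  variants = "data.frame", presence = "matrix", geno = "matrix"
))

setValidity("UniqueVariantTable", function(object) {
  msg <- character(0)
  v <- object@variants
  key <- paste(v$chrom, v$pos, v$ref, v$alt)
  if (anyDuplicated(key)) msg <- c(msg, "duplicate variant keys")
  if (nrow(v) && (any(v$maf < 0 | v$maf > 0.5, na.rm = TRUE))) {
    msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (nrow(v) && any(v$callRate < 0 | v$callRate > 1)) {
    msg <- c(msg, "callRate must lie in [0, 1]")
  }
  if (nrow(object@presence) != nrow(v) || nrow(object@geno) != nrow(v)) {
    msg <- c(msg, "presence/geno rows must match variants")
  }
  if (length(msg)) msg else TRUE
})

#' Solution of Henderson's mixed-model equations
#'
#' Fixed-effect estimates, predicted breeding values, and prediction error
#' variances from a single-trait animal model y = Xb + Zu + e with
#' u ~ N(0, H sigma_a^2) and e ~ N(0, I sigma_e^2).
#'
#' @slot beta numeric, fixed-effect solutions (first level of each factor
#'   absorbed by the intercept).
#' @slot u numeric, predicted breeding values (GEBVs), named by animal.
#' @slot pev numeric, prediction error variance per animal.
#' @slot sigmaA2,sigmaE2 numeric, the (input) variance components.
#' @export
setClass("MMESolution", representation(
  beta = "numeric", u = "numeric", pev = "numeric",
  sigmaA2 = "numeric", sigmaE2 = "numeric"
))
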