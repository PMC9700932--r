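#' Create a synthetic-herd simulation configuration
#'
#' Constructor for \linkS4class{SimConfig}.  The defaults describe the
#' feedlot design the pipeline targets: 98 bulls (28 founders plus one
#' generation of 70 offspring), a 70-day test, five organs sampled on two
#' extreme residual-feed-intake groups of nine animals, and moderate
#' per-organ callability of transcribed variants.
#'
#' @param nFounders,nGenerations,offspringPerMating pedigree structure;
#'   founders are generation 0 and matings pair males and females of the
#'   previous generation.
#' @param nChipSnps,nTranscribedVariants,nQtl marker-panel sizes; the
#'   \code{nQtl} causal variants are drawn from the transcribed panel.
#' @param heritability narrow-sense heritability of the genetic
#'   feed-intake component, in (0,1).
#' @param founderMafRange uniform sampling range of founder minor allele
#'   frequencies.
#' @param genomeLengthBp,blockBp toy-genome length and cosegregating-block
#'   length (free recombination between blocks, none within).
#' @param nTissues,tissueNames,tissueCallability,tissueSamples per-organ
#'   variant-calling structure; callability and sample counts are recycled
#'   to \code{nTissues}.
#' @param perSampleMissingRate probability a written genotype is missing.
#' @param qcFailRate fraction of VCF records written with a failing QC field.
#' @param indelFraction fraction of transcribed variants that are indels.
#' @param nCg number of contemporary groups.
#' @param testDays days in the feedlot test.
#' @param nPerGroup animals per extreme feed-efficiency group.
#' @param tagSnpsPerQtl,tagWindowBp,tagFidelity placement and linkage
#'   disequilibrium of the chip SNPs tagging each QTL.
#' @param seed master RNG seed (integer below 2^31 - 100).
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(nFounders = 28, nGenerations = 1,
                      offspringPerMating = 5, nChipSnps = 1000,
                      nTranscribedVariants = 2000, nQtl = 5,
                      heritability = 0.3, founderMafRange = c(0.05, 0.5),
                      genomeLengthBp = 10e6, blockBp = 1e5,
                      nTissues = 5,
                      tissueNames = c("liver", "muscle", "hypothalamus",
                                      "pituitary", "adrenal"),
                      tissueCallability = 0.5,
                      tissueSamples = c(18L, 17L, 18L, 18L, 15L),
                      perSampleMissingRate = 0.1, qcFailRate = 0.05,
                      indelFraction = 0.1, nCg = 4, testDays = 70,
                      nPerGroup = 9, tagSnpsPerQtl = 3,
                      tagWindowBp = 10000, tagFidelity = 0.9,
                      seed = 20220101) {
  if (nFounders < 1) stop("invalid configuration: nFounders must be >= 1")
  if (seed >= 2^31 - 100) stop("seed must be below 2^31 - 100")
  tissueNames <- rep_len(tissueNames, nTissues)
  if (anyDuplicated(tissueNames)) {
    tissueNames <- make.unique(tissueNames, sep = "_")
  }
  new("SimConfig",
      nFounders = as.integer(nFounders),
      nGenerations = as.integer(nGenerations),
      offspringPerMating = as.integer(offspringPerMating),
      nChipSnps = as.integer(nChipSnps),
      nTranscribedVariants = as.integer(nTranscribedVariants),
      nQtl = as.integer(nQtl),
      heritability = heritability,
      founderMafRange = founderMafRange,
      genomeLengthBp = as.integer(genomeLengthBp),
      blockBp = as.integer(blockBp),
      nTissues = as.integer(nTissues),
      tissueNames = tissueNames,
      tissueCallability = rep_len(tissueCallability, nTissues),
      tissueSamples = as.integer(rep_len(tissueSamples, nTissues)),
      perSampleMissingRate = perSampleMissingRate,
      qcFailRate = qcFailRate,
      indelFraction = indelFraction,
      nCg = as.integer(nCg),
      testDays = as.integer(testDays),
      nPerGroup = as.integer(nPerGroup),
      tagSnpsPerQtl = as.integer(tagSnpsPerQtl),
      tagWindowBp = as.integer(tagWindowBp),
      tagFidelity = tagFidelity,
      seed = as.integer(seed))
}
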