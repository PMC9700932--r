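#' Assign a trait architecture to simulated genotypes
#'
#' Samples additive effects for the designated causal transcribed variants
#' (the true PFVs) and computes every animal's true breeding value as the
#' centred sum of effect times allele count.  The residual standard
#' deviation is set so that, on the founder cohort,
#' var(tbv) / (var(tbv) + residualSd^2) equals the configured
#' heritability.
#'
#' @param geno genotype list from \code{\link{simulateGenotypes}}.
#' @param ped the pedigree the genotypes were dropped through.
#' @param config a \linkS4class{SimConfig}.
#' @param effects optional vector of QTL effects (trait units per allele
#'   copy).  By default effects are drawn normal and rescaled so the
#'   founder phenotypic variance (genetic plus residual) equals
#'   \code{phenotypicVar}; explicit effects are used as given.
#' @param phenotypicVar target phenotypic variance of the true RFI on the
#'   founder cohort (kg^2 DM/day; the default corresponds to an RFI SD of
#'   0.8 kg DM/day).
#' @return A list with \code{qtl} (data.frame: txIndex, id, pos, effect),
#'   \code{tbv} (named numeric) and \code{residualSd}.
#' @export
assignTraitArchitecture <- function(geno, ped, config, effects = NULL,
                                    phenotypicVar = 0.64) {
  if (config@heritability <= 0 || config@heritability >= 1) {
    stop("invalid configuration: heritability must lie in (0, 1)")
  }
  set.seed(config@seed + 2L)
  qtlIdx <- which(GenomicRanges::mcols(geno$txMap)$qtlCandidate)
  if (length(qtlIdx) == 0 && config@nQtl > 0) {
    qtlIdx <- sort(sample.int(ncol(geno$txGeno), config@nQtl))
  }
  scaleToTarget <- is.null(effects)
  if (is.null(effects)) effects <- rnorm(length(qtlIdx))
  stopifnot(length(effects) == length(qtlIdx))

  founders <- as.character(ped$animal[is.na(ped$sire)])
  raw <- as.numeric(geno$txGeno[, qtlIdx, drop = FALSE] %*% effects)
  names(raw) <- rownames(geno$txGeno)
  if (scaleToTarget && length(qtlIdx) && var(raw[founders]) > 0) {
    effects <- effects * sqrt(config@heritability * phenotypicVar /
                              var(raw[founders]))
    raw <- as.numeric(geno$txGeno[, qtlIdx, drop = FALSE] %*% effects)
    names(raw) <- rownames(geno$txGeno)
  }
  tbv <- raw - mean(raw)

  vF <- var(tbv[founders])
  if (length(qtlIdx) == 0 || !is.finite(vF) || vF == 0) {
    if (any(effects != 0)) {
      warning("true breeding values are constant; residual SD set to 1")
    }
    residualSd <- 1
  } else {
    h2 <- config@heritability
    residualSd <- sqrt(vF * (1 - h2) / h2)
  }
  qtlDf <- data.frame(
    txIndex = qtlIdx,
    id = names(geno$txMap)[qtlIdx],
    pos = GenomicRanges::start(geno$txMap)[qtlIdx],
    effect = effects
  )
  list(qtl = qtlDf, tbv = tbv, residualSd = residualSd)
}

#' Simulate feedlot records
#'
#' Generates, per animal, a fortnightly body-weight series over the test
#' (linear growth plus weighing noise) and a test-average daily dry-matter
#' intake.  DMI is built as intercept + b1 * true ADG + b2 * true
#' metabolic weight + contemporary-group effect + genetic component (the
#' animal's tbv) + residual, so the true residual feed intake is exactly
#' tbv + residual and RFI recovery is testable.
#'
#' @param ped pedigree data.frame.
#' @param arch trait architecture from \code{\link{assignTraitArchitecture}}.
#' @param config a \linkS4class{SimConfig}.
#' @param w0Mean,w0Sd initial body weight distribution (kg); the defaults
#'   match a 376 +/- 29 kg cohort entering the feedlot.
#' @param adgMean,adgSd distribution of true growth rate (kg/day).
#' @param bwNoiseSd weighing noise SD (kg); zero gives exactly linear series.
#' @param dmiIntercept,bAdg,bMw partial regression structure of DMI on
#'   growth (kg DM per kg ADG) and metabolic weight (kg DM per kg^0.75).
#' @param cgSd SD of contemporary-group effects (kg DM/day).
#' @param cgEffects optional explicit vector of CG effects (length nCg).
#' @param weighIntervalDays days between weighings.
#' @return A list with \code{animals} (animal, cg, dmi, age, adgTrue,
#'   mwTrue, cgEffect) and \code{bodyWeight} (animal, dit, bw) data.frames.
#' @export
simulateFeedlotRecords <- function(ped, arch, config,
                                   w0Mean = 376, w0Sd = 29,
                                   adgMean = 1.1, adgSd = 0.15,
                                   bwNoiseSd = 4,
                                   dmiIntercept = 0.5, bAdg = 1.5,
                                   bMw = 0.09, cgSd = 0.3,
                                   cgEffects = NULL,
                                   weighIntervalDays = 14) {
  if (config@testDays < 2) {
    stop("invalid configuration: testDays must be >= 2 to fit a growth line")
  }
  set.seed(config@seed + 3L)
  ids <- as.character(ped$animal)
  n <- length(ids)
  tbv <- arch$tbv[ids]

  cg <- rep_len(seq_len(config@nCg), n)[sample.int(n)]
  if (is.null(cgEffects)) cgEffects <- rnorm(config@nCg, 0, cgSd)
  stopifnot(length(cgEffects) == config@nCg)

  w0 <- rnorm(n, w0Mean, w0Sd)
  g <- rnorm(n, adgMean, adgSd)
  dit <- seq(0, config@testDays, by = weighIntervalDays)
  if (dit[length(dit)] != config@testDays) dit <- c(dit, config@testDays)

  bw <- data.frame(
    animal = rep(ids, each = length(dit)),
    dit = rep(dit, n),
    bw = rep(w0, each = length(dit)) + rep(g, each = length(dit)) *
      rep(dit, n) + rnorm(n * length(dit), 0, bwNoiseSd)
  )
  mwTrue <- (w0 + g * config@testDays / 2)^0.75
  dmi <- dmiIntercept + bAdg * g + bMw * mwTrue + cgEffects[cg] + tbv +
    rnorm(n, 0, arch$residualSd)
  animals <- data.frame(
    animal = ids, cg = cg, dmi = dmi,
    age = round(rnorm(n, 500, 30)),
    adgTrue = g, mwTrue = mwTrue, cgEffect = cgEffects[cg],
    stringsAsFactors = FALSE
  )
  list(animals = animals, bodyWeight = bw)
}

#' Simulate a complete synthetic herd
#'
#' Convenience wrapper running pedigree simulation, toy gene-model and
#' genotype generation, trait-architecture assignment and feedlot-record
#' simulation under one configuration, returning a \linkS4class{Herd}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param withGeneModel logical; skip the toy genome (faster) when the
#'   downstream analysis does not need sequence or consequence calls.
#' @param ... passed to \code{\link{simulateFeedlotRecords}}.
#' @return A \linkS4class{Herd}.
#' @examples
#' herd <- simulateHerd(simConfig(nChipSnps = 50,
#'                                nTranscribedVariants = 40, seed = 1),
#'                      withGeneModel = FALSE)
#' herd
#' @export
simulateHerd <- function(config, withGeneModel = TRUE, ...) {
  ped <- simulatePedigree(config)
  gm <- if (withGeneModel) simulateGeneModel(config) else NULL
  geno <- simulateGenotypes(ped, config, gm)
  arch <- assignTraitArchitecture(geno, ped, config)
  rec <- simulateFeedlotRecords(ped, arch, config, ...)
  new("Herd", config = config, pedigree = ped,
      chipGeno = geno$chipGeno, chipMap = geno$chipMap,
      txGeno = geno$txGeno, txMap = geno$txMap,
      qtl = arch$qtl, tbv = arch$tbv, residualSd = arch$residualSd,
      animals = rec$animals, bodyWeight = rec$bodyWeight,
      geneModel = if (is.null(gm)) NULL else gm)
}
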