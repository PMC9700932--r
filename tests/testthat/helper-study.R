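# Replicated genomic-prediction study on synthetic herds, shared between
# test files (computed once per session and cached).
# Conditions: ~2000 animals (120 founders + 4 generations), 3000 chip
# SNPs, 5 QTLs, h2 = 0.3.

.studyCache <- new.env(parent = emptyenv())

studyConfig <- function(seed) {
  simConfig(nFounders = 120, nGenerations = 4, offspringPerMating = 8,
            nChipSnps = 3000, nTranscribedVariants = 100, nQtl = 5,
            heritability = 0.3, nCg = 20, seed = seed)
}

predictionStudy <- function(nSeeds = 20, baseSeed = 1000) {
  key <- paste0("s", nSeeds, "_", baseSeed)
  if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
  rows <- vector("list", nSeeds)
  for (s in seq_len(nSeeds)) {
    herd <- simulateHerd(studyConfig(baseSeed + s), withGeneModel = FALSE)
    pd <- predictionData(herd)
    pfvTrue <- data.frame(chrom = "1", pos = qtl(herd)$pos)
    grid <- runScenarioGrid(pd, pfv = pfvTrue)
    acc <- setNames(grid$acc, grid$scenario)
    cors <- setNames(grid$corTbv, grid$scenario)
    b <- setNames(grid$b, grid$scenario)

    # negative control: random non-causal transcribed variants as PFVs
    set.seed(baseSeed + s)
    nonQtl <- which(!GenomicRanges::mcols(transcribedMap(herd))$qtlCandidate)
    pfvRand <- data.frame(
      chrom = "1",
      pos = GenomicRanges::start(transcribedMap(herd))[
        sample(nonQtl, nrow(qtl(herd)))])
    rnd3 <- runScenario(pd, useWeights = TRUE, pfvFold = 3, pfv = pfvRand)

    # pedigree-only BLUP (H = A), training records
    useT <- pd$recordAnimal %in% pd$training
    pedFit <- solveMME(pd$y[useT], pd$X[useT, , drop = FALSE],
                       pd$recordAnimal[useT], pd$Ainv, pd$sigmaA2,
                       pd$sigmaE2)
    corPed <- cor(gebv(pedFit)[pd$validation], pd$tbv[pd$validation])

    # tag-SNP weight enrichment after the 2-iteration ssGWAS
    tagged <- !is.na(GenomicRanges::mcols(pd$chipMap)$tagOf)
    rows[[s]] <- data.frame(
      seed = baseSeed + s,
      accSs = acc[["ssGBLUP"]], accWg = acc[["ssGBLUP+wG"]],
      accRec = acc[["ssGBLUP+records"]],
      accWgRec = acc[["ssGBLUP+wG+records"]],
      accF1 = acc[["ssGBLUP+wG+QTN:1-fold"]],
      accF2 = acc[["ssGBLUP+wG+QTN:2-fold"]],
      accF3 = acc[["ssGBLUP+wG+QTN:3-fold"]],
      accRnd3 = rnd3$acc,
      corSs = cors[["ssGBLUP"]], corWg = cors[["ssGBLUP+wG"]],
      corPed = corPed,
      bWg = b[["ssGBLUP+wG"]], bRec = b[["ssGBLUP+records"]],
      tagWeightMean = mean(pd$weights[tagged]),
      allWeightMean = mean(pd$weights)
    )
  }
  res <- do.call(rbind, rows)
  .studyCache[[key]] <- res
  res
}

# one-sided sign test p-value for "x > y" paired over replicates
signTestP <- function(x, y) {
  wins <- sum(x > y)
  n <- sum(x != y)
  binom.test(wins, n, alternative = "greater")$p.value
}
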