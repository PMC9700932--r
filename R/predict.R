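#' Split a herd into training and validation sets
#'
#' Validation animals are the youngest-generation genotyped and
#' phenotyped animals without progeny; training is every other phenotyped
#' animal.  Scenarios without "records" withhold the validation
#' phenotypes from the mixed model.
#'
#' @param ped pedigree data.frame with a generation column.
#' @param phenotypedIds,genotypedIds character vectors of animal ids.
#' @return A list with character vectors \code{training} and
#'   \code{validation}.
#' @export
splitPopulation <- function(ped, phenotypedIds, genotypedIds) {
  ids <- as.character(ped$animal)
  hasProgeny <- ids %in% c(ped$sire, ped$dam)
  young <- ped$generation == max(ped$generation)
  valid <- ids[young & !hasProgeny &
               ids %in% as.character(phenotypedIds) &
               ids %in% as.character(genotypedIds)]
  if (!length(valid)) {
    stop("invalid configuration: no childless genotyped+phenotyped ",
         "animals in the youngest generation")
  }
  list(training = setdiff(as.character(phenotypedIds), valid),
       validation = valid)
}

#' BIF accuracy from prediction error variance
#'
#' Beef Improvement Federation accuracy per animal:
#' Acc = 1 - sqrt(PEV / ((1 + F_i) sigma_a^2)).  PEV outside
#' [0, (1 + F) sigma_a^2] is clamped (with a warning) so the accuracy
#' stays in [0, 1].
#'
#' @param pevValues prediction error variances.
#' @param Fcoef inbreeding coefficients (recycled).
#' @param sigmaA2 additive genetic variance.
#' @return Numeric accuracies in [0, 1].
#' @examples
#' bifAccuracy(c(0, 0.75, 1), 0, 1)
#' @export
bifAccuracy <- function(pevValues, Fcoef, sigmaA2) {
  bound <- (1 + Fcoef) * sigmaA2
  if (any(pevValues > bound + 1e-8)) {
    warning("PEV exceeds (1 + F) sigma_a^2 for some animals; ",
            "accuracy clamped to 0")
  }
  ratio <- pmin(pmax(pevValues / bound, 0), 1)
  1 - sqrt(ratio)
}

#' Prediction inflation (dispersion) slope
#'
#' OLS regression of the reference GEBVs (whole-data, unweighted G) on
#' the scenario GEBVs over the validation animals.  A slope b < 1 flags
#' inflated (over-dispersed) scenario predictions.
#'
#' @param gebvReference,gebvScenario named GEBV vectors.
#' @param ids validation animal ids.
#' @return A list with \code{b} and \code{se}.
#' @export
inflation <- function(gebvReference, gebvScenario, ids) {
  x <- gebvScenario[ids]
  yv <- gebvReference[ids]
  if (var(x) == 0) stop("undefined slope: scenario GEBVs have no variance")
  fit <- lm(yv ~ x)
  # the reference regressed on itself is an exact fit; SE = 0 is wanted
  sm <- suppressWarnings(summary(fit))$coefficients
  list(b = unname(coef(fit)[2]), se = unname(sm["x", "Std. Error"]))
}

#' Run one genomic-prediction scenario
#'
#' Assembles H from the requested genomic weighting, solves the mixed
#' model with or without the validation records, and summarises the
#' validation animals: mean BIF accuracy, and (when true breeding values
#' are supplied) the correlation of GEBV with TBV.
#'
#' @param data prediction data from \code{\link{predictionData}}.
#' @param useWeights logical, use the WssGWAS weights.
#' @param includeValidationRecords logical, add validation phenotypes.
#' @param pfvFold 0 for no PFV weighting, otherwise the fold multiple
#'   applied to SNPs adjacent to \code{pfv} positions.
#' @param pfv data.frame (chrom, pos) of PFV positions.
#' @param windowBp PFV adjacency window.
#' @param blend G blending proportion towards A22.
#' @return A list with the scenario \code{solution}
#'   (\linkS4class{MMESolution}), \code{acc}, \code{corTbv} and the
#'   validation ids.
#' @export
runScenario <- function(data, useWeights = FALSE,
                        includeValidationRecords = FALSE, pfvFold = 0,
                        pfv = NULL, windowBp = 50000, blend = 0.05) {
  if (pfvFold > 0 && !useWeights) {
    stop("pfvFold > 0 requires useWeights = TRUE")
  }
  w <- if (useWeights) data$weights else NULL
  if (pfvFold > 0) {
    w <- applyPfvWeights(w, pfv, data$chipMap, data$p, fold = pfvFold,
                         windowBp = windowBp)
  }
  G <- genomicRelationship(data$M, p = data$p, weights = w, blend = blend,
                           A22 = data$A22)
  Hinv <- hInverse(data$Ainv, data$A22inv, spdInverse(G, "G"),
                   rownames(data$M))
  use <- if (includeValidationRecords) {
    data$recordAnimal %in% c(data$training, data$validation)
  } else {
    data$recordAnimal %in% data$training
  }
  fit <- solveMME(data$y[use], data$X[use, , drop = FALSE],
                  data$recordAnimal[use], Hinv, data$sigmaA2, data$sigmaE2)
  vId <- data$validation
  acc <- mean(bifAccuracy(pev(fit)[vId], data$F[vId], data$sigmaA2))
  corTbv <- if (!is.null(data$tbv)) {
    cor(gebv(fit)[vId], data$tbv[vId])
  } else NA_real_
  list(solution = fit, acc = acc, corTbv = corTbv, validation = vId)
}

#' Prepare a herd for the prediction scenario grid
#'
#' Computes the RFI phenotype, chooses which animals are genotyped,
#' splits training/validation, precomputes the pedigree relationship
#' pieces, and runs the training-only WssGWAS that supplies the SNP
#' weights for the weighted scenarios.  The fixed effects follow the
#' animal model: contemporary group and age covariate.
#'
#' @param herd a \linkS4class{Herd}.
#' @param genotypedIds animals carrying chip genotypes.  The default
#'   mirrors the usual validation design: the youngest generation (the
#'   selection candidates) plus every sire (the proven animals a breeding
#'   program genotypes), so the genotyped training animals are the sires
#'   with phenotyped progeny.
#' @param sigmaA2,sigmaE2 variance components; default to the simulation
#'   truth (founder genetic variance and residual variance).
#' @param nIter WssGWAS weight iterations.
#' @param blend G blending proportion.
#' @param minCgSize minimum contemporary-group size in the RFI stage.
#' @return A list bundle consumed by \code{\link{runScenario}}.
#' @export
predictionData <- function(herd, genotypedIds = NULL,
                           sigmaA2 = NULL, sigmaE2 = NULL, nIter = 2,
                           blend = 0.05, minCgSize = 4) {
  ped <- herd@pedigree
  rec <- feedlotRecords(herd)
  rfi <- computeRFI(rec$animals, rec$bodyWeight, minCgSize = minCgSize)
  ok <- !is.na(rfi$rfi)
  y <- setNames(rfi$rfi[ok], rfi$animal[ok])
  X <- data.frame(cg = factor(rec$animals$cg[ok]),
                  age = rec$animals$age[ok])
  recordAnimal <- rfi$animal[ok]

  if (is.null(genotypedIds)) {
    young <- ped$generation == max(ped$generation)
    isSire <- ped$animal %in% ped$sire
    genotypedIds <- ped$animal[young | isSire]
  }
  gIds <- as.character(genotypedIds)
  M <- herd@chipGeno[gIds, , drop = FALSE]
  # drop monomorphic chip SNPs (undefined weights/frequencies)
  poly <- apply(M, 2, function(x) length(unique(x)) > 1)
  M <- M[, poly, drop = FALSE]
  map <- herd@chipMap[poly]

  split <- splitPopulation(ped, names(y), gIds)
  founders <- as.character(ped$animal[is.na(ped$sire)])
  if (is.null(sigmaA2)) sigmaA2 <- var(herd@tbv[founders])
  if (is.null(sigmaE2)) sigmaE2 <- herd@residualSd^2

  train <- recordAnimal %in% split$training
  wss <- runWssgwas(y[train], X[train, , drop = FALSE],
                    recordAnimal[train], ped, M, sigmaA2, sigmaE2,
                    nIter = nIter, blend = blend)
  list(y = y, X = X, recordAnimal = recordAnimal, ped = ped, M = M,
       chipMap = map, p = wss$p, weights = wss$weights,
       Ainv = wss$Ainv, A22inv = wss$A22inv, A22 = wss$A22, F = wss$F,
       training = split$training, validation = split$validation,
       sigmaA2 = sigmaA2, sigmaE2 = sigmaE2, tbv = herd@tbv,
       wssSolution = wss$solution, snpEffects = wss$snpEffects)
}

#' Run the full prediction scenario grid on one herd
#'
#' Evaluates the base scenarios (ssGBLUP, ssGBLUP+wG, ssGBLUP+records,
#' ssGBLUP+wG+records) and the PFV fold-weighting scenarios
#' (ssGBLUP+wG+QTN:k-fold), reporting mean validation BIF accuracy, the
#' inflation slope b against the whole-data unweighted reference, and
#' the GEBV-TBV correlation diagnostic.
#'
#' @param data bundle from \code{\link{predictionData}}.
#' @param pfv data.frame (chrom, pos) of PFV positions; defaults to no
#'   fold scenarios when NULL.
#' @param folds fold multiples to evaluate.
#' @param windowBp PFV adjacency window.
#' @param blend G blending proportion.
#' @return data.frame with one row per scenario: name, acc, b, bSe,
#'   corTbv.
#' @export
runScenarioGrid <- function(data, pfv = NULL, folds = c(1, 2, 3),
                            windowBp = 50000, blend = 0.05) {
  scen <- list(
    "ssGBLUP" = list(useWeights = FALSE, records = FALSE, fold = 0),
    "ssGBLUP+wG" = list(useWeights = TRUE, records = FALSE, fold = 0),
    "ssGBLUP+records" = list(useWeights = FALSE, records = TRUE,
                             fold = 0),
    "ssGBLUP+wG+records" = list(useWeights = TRUE, records = TRUE,
                                fold = 0)
  )
  if (!is.null(pfv)) {
    for (f in folds) {
      scen[[sprintf("ssGBLUP+wG+QTN:%d-fold", f)]] <-
        list(useWeights = TRUE, records = FALSE, fold = f)
    }
  }
  runs <- lapply(scen, function(s) {
    runScenario(data, useWeights = s$useWeights,
                includeValidationRecords = s$records, pfvFold = s$fold,
                pfv = pfv, windowBp = windowBp, blend = blend)
  })
  ref <- gebv(runs[["ssGBLUP+records"]]$solution)
  out <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    infl <- inflation(ref, gebv(r$solution), r$validation)
    data.frame(scenario = nm, acc = r$acc, b = infl$b, bSe = infl$se,
               corTbv = r$corTbv, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}

#' Format a scenario-metrics table
#'
#' @param results data.frame from \code{\link{runScenarioGrid}} (or rows
#'   of several, combined).
#' @param digits decimals for the printed values.
#' @return data.frame with columns scenario, Acc and "b (SE)" as printed
#'   strings.
#' @export
scenarioTable <- function(results, digits = 2) {
  if (is.null(results) || nrow(results) == 0) {
    return(data.frame(scenario = character(0), Acc = character(0),
                      `b (SE)` = character(0), check.names = FALSE))
  }
  data.frame(
    scenario = results$scenario,
    Acc = sprintf("%.*f", digits, results$acc),
    `b (SE)` = sprintf("%.*f (%.*f)", digits, results$b, digits,
                       results$bSe),
    check.names = FALSE
  )
}
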