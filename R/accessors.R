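#' Accessors for package classes
#'
#' Small accessor generics for the central S4 containers: pedigree and
#' genotype access on a \linkS4class{Herd}, variant metadata on a
#' \linkS4class{UniqueVariantTable}, and solution components of an
#' \linkS4class{MMESolution}.
#'
#' @param object an object of the documented class.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pedigree", function(object) standardGeneric("pedigree"))
#' @rdname accessors
#' @export
setMethod("pedigree", "Herd", function(object) object@pedigree)

#' @rdname accessors
#' @export
setGeneric("chipGenotypes", function(object) standardGeneric("chipGenotypes"))
#' @rdname accessors
#' @export
setMethod("chipGenotypes", "Herd", function(object) object@chipGeno)

#' @rdname accessors
#' @export
setGeneric("chipMap", function(object) standardGeneric("chipMap"))
#' @rdname accessors
#' @export
setMethod("chipMap", "Herd", function(object) object@chipMap)

#' @rdname accessors
#' @export
setGeneric("transcribedGenotypes",
           function(object) standardGeneric("transcribedGenotypes"))
#' @rdname accessors
#' @export
setMethod("transcribedGenotypes", "Herd", function(object) object@txGeno)

#' @rdname accessors
#' @export
setGeneric("transcribedMap", function(object) standardGeneric("transcribedMap"))
#' @rdname accessors
#' @export
setMethod("transcribedMap", "Herd", function(object) object@txMap)

#' @rdname accessors
#' @export
setGeneric("trueBreedingValues",
           function(object) standardGeneric("trueBreedingValues"))
#' @rdname accessors
#' @export
setMethod("trueBreedingValues", "Herd", function(object) object@tbv)

#' @rdname accessors
#' @export
setGeneric("qtl", function(object) standardGeneric("qtl"))
#' @rdname accessors
#' @export
setMethod("qtl", "Herd", function(object) object@qtl)

#' @rdname accessors
#' @export
setGeneric("feedlotRecords", function(object) standardGeneric("feedlotRecords"))
#' @rdname accessors
#' @export
setMethod("feedlotRecords", "Herd", function(object) {
  list(animals = object@animals, bodyWeight = object@bodyWeight)
})

#' @rdname accessors
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))
#' @rdname accessors
#' @export
setMethod("variants", "UniqueVariantTable", function(object) object@variants)

#' @rdname accessors
#' @export
setGeneric("tissuePresence", function(object) standardGeneric("tissuePresence"))
#' @rdname accessors
#' @export
setMethod("tissuePresence", "UniqueVariantTable",
          function(object) object@presence)

#' @rdname accessors
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "UniqueVariantTable", function(object) object@geno)

#' @rdname accessors
#' @export
setGeneric("gebv", function(object) standardGeneric("gebv"))
#' @rdname accessors
#' @export
setMethod("gebv", "MMESolution", function(object) object@u)

#' @rdname accessors
#' @export
setGeneric("pev", function(object) standardGeneric("pev"))
#' @rdname accessors
#' @export
setMethod("pev", "MMESolution", function(object) object@pev)

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setMethod("fixedEffects", "MMESolution", function(object) object@beta)

#' Subset a unique-variant table by row
#'
#' @param x a \linkS4class{UniqueVariantTable}.
#' @param i logical or integer row (variant) index.
#' @param j,...,drop ignored.
#' @return A \code{UniqueVariantTable} restricted to the selected variants.
#' @export
setMethod("[", "UniqueVariantTable", function(x, i, j, ..., drop = FALSE) {
  new("UniqueVariantTable",
      variants = x@variants[i, , drop = FALSE],
      presence = x@presence[i, , drop = FALSE],
      geno = x@geno[i, , drop = FALSE])
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFounders, "founders,",
      object@nGenerations, "generations x",
      object@offspringPerMating, "offspring/mating\n")
  cat("  markers:", object@nChipSnps, "chip SNPs,",
      object@nTranscribedVariants, "transcribed variants,",
      object@nQtl, "QTLs, h2 =", object@heritability, "\n")
  cat("  tissues:", paste(object@tissueNames, collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "Herd", function(object) {
  cat("Herd:", nrow(object@pedigree), "animals (",
      max(object@pedigree$generation) + 1, "generations ),",
      ncol(object@chipGeno), "chip SNPs,",
      ncol(object@txGeno), "transcribed variants\n")
  cat("  QTLs:", nrow(object@qtl),
      " residual SD:", signif(object@residualSd, 4), "\n")
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel:", nrow(object@transcripts), "transcripts on",
      length(object@genome), "sequence(s)\n")
})

setMethod("show", "UniqueVariantTable", function(object) {
  cat("UniqueVariantTable:", nrow(object@variants), "unique variants x",
      ncol(object@presence), "tissues,", ncol(object@geno), "samples\n")
  if (nrow(object@variants)) {
    cat("  SNP:", sum(object@variants$class == "SNP"),
        " INDEL:", sum(object@variants$class == "INDEL"), "\n")
  }
})

setMethod("show", "MMESolution", function(object) {
  cat("MMESolution:", length(object@u), "animals,",
      length(object@beta), "fixed effects; sigma_a2 =", object@sigmaA2,
      ", sigma_e2 =", object@sigmaE2, "\n")
})
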