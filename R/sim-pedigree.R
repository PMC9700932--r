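#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) are assigned alternating sexes; each later
#' generation is produced by randomly pairing the males and females of the
#' previous generation, every pair leaving \code{offspringPerMating}
#' offspring of random sex.  The returned records are topologically
#' ordered (parents precede offspring) and deterministic given
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return data.frame with columns animal, sire, dam (NA for founders),
#'   generation and sex.
#' @examples
#' ped <- simulatePedigree(simConfig(nFounders = 10, nGenerations = 2,
#'                                   offspringPerMating = 2, seed = 1))
#' head(ped)
#' @export
simulatePedigree <- function(config) {
  stopifnot(is(config, "SimConfig"))
  if (config@nFounders < 2 && config@nGenerations >= 1) {
    stop("invalid configuration: need at least 2 founders to mate")
  }
  set.seed(config@seed)
  nF <- config@nFounders
  ped <- data.frame(
    animal = seq_len(nF), sire = NA_integer_, dam = NA_integer_,
    generation = 0L, sex = rep_len(c("M", "F"), nF),
    stringsAsFactors = FALSE
  )
  nextId <- nF + 1L
  for (g in seq_len(config@nGenerations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    # cap matings so cohort sizes stay near the founder cohort
    nm <- min(length(males), length(females), config@nFounders %/% 2L)
    if (nm == 0L) {
      stop("generation ", g - 1L, " has no mating pairs (single-sex cohort)")
    }
    sires <- sample(males)[seq_len(nm)]
    dams <- sample(females)[seq_len(nm)]
    nOff <- nm * config@offspringPerMating
    off <- data.frame(
      animal = seq.int(nextId, length.out = nOff),
      sire = rep(sires, each = config@offspringPerMating),
      dam = rep(dams, each = config@offspringPerMating),
      generation = g,
      sex = sample(c("M", "F"), nOff, replace = TRUE),
      stringsAsFactors = FALSE
    )
    ped <- rbind(ped, off)
    nextId <- nextId + nOff
  }
  rownames(ped) <- NULL
  ped
}

#' Validate pedigree ordering and structure
#'
#' Checks that parents precede their offspring in the record order, that
#' founders have both parents unknown, and that generation labels strictly
#' increase along every parent-to-child edge.
#'
#' @param ped a pedigree data.frame as returned by
#'   \code{\link{simulatePedigree}}.
#' @return Invisibly TRUE; stops with an informative error otherwise.
#' @export
validatePedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  idx <- match(ped$animal, ped$animal)
  if (anyDuplicated(ped$animal)) stop("duplicate animal ids in pedigree")
  pos <- seq_len(nrow(ped))
  names(pos) <- as.character(ped$animal)
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    bad <- known & is.na(pos[as.character(p)])
    if (any(bad)) stop("pedigree ordering error: unknown ", col, " id(s)")
    after <- known & pos[as.character(p)] >= pos[as.character(ped$animal)]
    if (any(after)) {
      stop("pedigree ordering error: ", col,
           " listed after offspring for animal ",
           ped$animal[which(after)[1]])
    }
  }
  onePar <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(onePar)) stop("animals must have either both or no known parents")
  if ("generation" %in% names(ped)) {
    for (col in c("sire", "dam")) {
      known <- !is.na(ped[[col]])
      gp <- ped$generation[pos[as.character(ped[[col]][known])]]
      if (any(gp >= ped$generation[known])) {
        stop("generation labels must increase along parent-child edges")
      }
    }
  }
  invisible(TRUE)
}
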