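#' Solve Henderson's mixed-model equations
#'
#' Single-trait animal model y = Xb + Zu + e with u ~ N(0, H sigma_a^2)
#' and e ~ N(0, I sigma_e^2).  Solves
#' [X'X, X'Z; Z'X, Z'Z + H^-1 k] [b; u] = [X'y; Z'y] with
#' k = sigma_e^2 / sigma_a^2 by dense symmetric factorisation, and
#' returns the prediction error variance PEV_i = (LHS^-1)_{uu,ii}
#' sigma_e^2 from the explicit inverse diagonal.  Rank deficiency in X
#' (e.g. contemporary groups nested in the intercept) is handled by
#' dropping the first level of each factor via treatment contrasts.
#'
#' @param y numeric vector of phenotypic records.
#' @param X fixed-effect design matrix (rows = records), or a data.frame
#'   of covariates/factors from which a full-rank design is built.
#' @param recordAnimal character vector: the animal of each record.
#' @param Hinv relationship inverse over all animals (dimnames = ids).
#' @param sigmaA2,sigmaE2 additive and residual variance components.
#' @return An \linkS4class{MMESolution}.
#' @export
solveMME <- function(y, X, recordAnimal, Hinv, sigmaA2, sigmaE2) {
  stopifnot(sigmaA2 > 0, sigmaE2 > 0)
  ids <- rownames(Hinv)
  recordAnimal <- as.character(recordAnimal)
  stopifnot(all(recordAnimal %in% ids))
  if (is.data.frame(X)) X <- model.matrix(~ ., X)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(recordAnimal) == length(y))
  # drop aliased fixed-effect columns, keeping a note of the constraint
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    X <- X[, -drop, drop = FALSE]
  }
  n <- length(ids)
  p <- ncol(X)
  k <- sigmaE2 / sigmaA2
  ri <- match(recordAnimal, ids)

  ZtZ <- matrix(0, n, n)
  tab <- tabulate(ri, nbins = n)
  diag(ZtZ) <- tab
  XtZ <- matrix(0, p, n)
  xAgg <- rowsum(X, ri)                      # sums of X rows per animal
  XtZ[, as.integer(rownames(xAgg))] <- t(xAgg)
  Zty <- numeric(n)
  yAgg <- rowsum(y, ri)
  Zty[as.integer(rownames(yAgg))] <- yAgg

  LHS <- rbind(
    cbind(crossprod(X), XtZ),
    cbind(t(XtZ), ZtZ + Hinv * k)
  )
  RHS <- c(crossprod(X, y), Zty)
  Cinv <- spdInverse(LHS, "mixed-model coefficient matrix")
  sol <- as.numeric(Cinv %*% RHS)
  beta <- sol[seq_len(p)]
  names(beta) <- colnames(X)
  u <- sol[p + seq_len(n)]
  names(u) <- ids
  pevDiag <- diag(Cinv)[p + seq_len(n)] * sigmaE2
  names(pevDiag) <- ids
  new("MMESolution", beta = beta, u = u, pev = pevDiag,
      sigmaA2 = sigmaA2, sigmaE2 = sigmaE2)
}
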