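#' Numerator relationship matrix by the tabular method
#'
#' Recursive (tabular) construction of the pedigree relationship matrix A
#' with inbreeding: for animal i with parents s and d,
#' a_ii = 1 + a_sd / 2 and a_ij = (a_js + a_jd) / 2 for j earlier than i.
#' The inbreeding coefficient is F_i = a_ii - 1.
#'
#' @param ped pedigree data.frame (animal, sire, dam; parents precede
#'   offspring — validated).
#' @return A list with \code{A} (symmetric matrix, dimnames = animal ids)
#'   and \code{F} (named inbreeding coefficients).
#' @examples
#' ped <- data.frame(animal = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
#' numeratorRelationship(ped)$A
#' @export
numeratorRelationship <- function(ped) {
  validatePedigree(ped)
  n <- nrow(ped)
  ids <- as.character(ped$animal)
  rowOf <- setNames(seq_len(n), ids)
  s <- ifelse(is.na(ped$sire), 0L, rowOf[as.character(ped$sire)])
  d <- ifelse(is.na(ped$dam), 0L, rowOf[as.character(ped$dam)])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (si > 0L) {
      prev <- seq_len(i - 1L)
      rel <- (A[prev, si] + A[prev, di]) / 2
      A[prev, i] <- rel
      A[i, prev] <- rel
      A[i, i] <- 1 + A[si, di] / 2
    } else {
      A[i, i] <- 1
    }
  }
  list(A = A, F = setNames(diag(A) - 1, ids))
}

#' Genomic relationship matrix (VanRaden), optionally SNP-weighted
#'
#' With Z = M - P (P = matrix of twice the alternative-allele frequency)
#' and lambda = 1 / sum(2 p_j (1 - p_j)), returns G = Z D Z' lambda where
#' D is the diagonal of per-SNP weights (D = I gives the unweighted
#' VanRaden G).  Optionally blends with the pedigree relationships of the
#' genotyped animals before inversion-sensitive use:
#' G* = (1 - blend) G + blend A22.
#'
#' @param M allele-count matrix (n genotyped x m markers, 0/1/2), rows
#'   named by animal.
#' @param p allele frequencies per marker; computed from M when NULL.
#' @param weights per-SNP weights d (diagonal of D); NULL means D = I.
#' @param blend blending proportion towards A22 (0 = none).
#' @param A22 pedigree relationship submatrix of the genotyped animals
#'   (required when blend > 0).
#' @return The genomic relationship matrix, with \code{lambda} and
#'   \code{p} as attributes.
#' @export
genomicRelationship <- function(M, p = NULL, weights = NULL, blend = 0,
                                A22 = NULL) {
  stopifnot(ncol(M) >= 1)
  if (is.null(p)) p <- colMeans(M) / 2
  twoPq <- 2 * p * (1 - p)
  if (sum(twoPq) == 0) {
    stop("all markers are monomorphic: zero denominator in lambda")
  }
  lambda <- 1 / sum(twoPq)
  Z <- sweep(M, 2, 2 * p)
  if (is.null(weights)) {
    G <- tcrossprod(Z) * lambda
  } else {
    stopifnot(length(weights) == ncol(M), all(weights >= 0))
    G <- tcrossprod(sweep(Z, 2, sqrt(weights), `*`)) * lambda
  }
  if (blend > 0) {
    stopifnot(!is.null(A22), all(dim(A22) == dim(G)))
    G <- (1 - blend) * G + blend * A22
  }
  attr(G, "lambda") <- lambda
  attr(G, "p") <- p
  G
}

#' Single-step H-inverse
#'
#' The combined pedigree-genomic relationship inverse:
#' H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1], with the genomic block indexed by
#' the genotyped animals.
#'
#' @param Ainv inverse of the full pedigree relationship matrix.
#' @param A22inv inverse of the pedigree relationships among genotyped
#'   animals.
#' @param Ginv inverse of the (blended) genomic relationship matrix, rows
#'   in the same order as \code{genoIdx}.
#' @param genoIdx integer or character index of the genotyped animals in
#'   the row order of \code{Ainv}.
#' @return The symmetric H-inverse matrix.
#' @export
hInverse <- function(Ainv, A22inv, Ginv, genoIdx) {
  if (is.character(genoIdx)) genoIdx <- match(genoIdx, rownames(Ainv))
  Hinv <- Ainv
  if (length(genoIdx)) {
    stopifnot(all(dim(Ginv) == length(genoIdx)),
              all(dim(A22inv) == length(genoIdx)))
    Hinv[genoIdx, genoIdx] <- Hinv[genoIdx, genoIdx] + Ginv - A22inv
  }
  (Hinv + t(Hinv)) / 2
}

# symmetric positive-definite inverse via Cholesky with an informative
# failure message
spdInverse <- function(X, what = "matrix") {
  ch <- tryCatch(chol(X), error = function(e) {
    stop("cannot invert ", what, " (", conditionMessage(e),
         "); consider blending with A22", call. = FALSE)
  })
  chol2inv(ch)
}
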