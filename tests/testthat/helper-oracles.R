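# Independent oracles used across tests.

# recursive kinship oracle: phi(i, j) with memoisation; A = 2 * phi
kinshipOracleA <- function(ped) {
  ids <- as.character(ped$animal)
  n <- length(ids)
  sire <- match(as.character(ped$sire), ids)
  dam <- match(as.character(ped$dam), ids)
  memo <- new.env()
  phi <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      if (is.na(sire[i])) 0.5
      else 0.5 * (1 + phi(sire[i], dam[i]))
    } else {
      # j is the later-listed animal; recurse through its parents
      if (is.na(sire[j])) 0
      else 0.5 * (phi(i, sire[j]) + phi(i, dam[j]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# random valid pedigree for oracle comparisons
randomPedigree <- function(n, nFounders = 5, seed = 1) {
  set.seed(seed)
  animal <- seq_len(n)
  sire <- dam <- rep(NA_integer_, n)
  for (i in (nFounders + 1):n) {
    pair <- sample(seq_len(i - 1L), 2)
    sire[i] <- pair[1]; dam[i] <- pair[2]
  }
  data.frame(animal = animal, sire = sire, dam = dam)
}

# 2x2 Pearson chi-square oracle via sum (O - E)^2 / E
chi2Oracle <- function(alt1, n1, alt2, n2) {
  O <- c(alt1, n1 - alt1, alt2, n2 - alt2)
  N <- n1 + n2
  E <- c(n1 * (alt1 + alt2) / N, n1 * (N - alt1 - alt2) / N,
         n2 * (alt1 + alt2) / N, n2 * (N - alt1 - alt2) / N)
  if (any(E == 0)) return(0)
  sum((O - E)^2 / E)
}

# GLS oracle for the animal model: V = Z H Z' sa2 + I se2
glsOracle <- function(y, X, Z, H, sa2, se2) {
  V <- Z %*% H %*% t(Z) * sa2 + diag(length(y)) * se2
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- sa2 * H %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = as.numeric(beta), u = as.numeric(u))
}

# exact type-I error of the allelic test by enumeration (binomial
# allele counts per group under the null)
exactAllelicLevel <- function(nAlleles, p, alpha = 0.05) {
  crit <- qchisq(1 - alpha, 1)
  pr <- dbinom(0:nAlleles, nAlleles, p)
  rej <- 0
  for (a in 0:nAlleles) for (b in 0:nAlleles) {
    if (chi2Oracle(a, nAlleles, b, nAlleles) > crit) {
      rej <- rej + pr[a + 1] * pr[b + 1]
    }
  }
  rej
}
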