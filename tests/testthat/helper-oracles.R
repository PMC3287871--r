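# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Exact kinship by exhaustive enumeration of inheritance vectors: founders'
# alleles get distinct labels, every meiosis (2 per non-founder) is enumerated,
# and phi(i,j) is the average over configurations of the probability that one
# randomly drawn allele from each matches. Exact for pedigrees where every
# individual has both parents known or both missing.
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fa <- idx[ped$father]
  mo <- idx[ped$mother]
  founder <- is.na(fa) & is.na(mo)
  stopifnot(all(founder | (!is.na(fa) & !is.na(mo))))
  nonf <- which(!founder)
  K <- length(nonf)
  stopifnot(2 * K <= 20)
  # order non-founders so parents are always assigned first
  ord <- integer(0)
  assigned <- founder
  while (length(ord) < K) {
    ready <- which(!assigned & assigned[fa] & assigned[mo])
    ord <- c(ord, ready)
    assigned[ready] <- TRUE
  }
  nc <- 2^(2 * K)
  bits <- matrix(0L, nc, 2 * K)
  for (b in seq_len(2 * K)) {
    bits[, b] <- rep(rep(0:1, each = 2^(b - 1)), length.out = nc)
  }
  P <- matrix(0L, nc, n)
  M <- matrix(0L, nc, n)
  for (i in which(founder)) {
    P[, i] <- 2L * i - 1L
    M[, i] <- 2L * i
  }
  for (k in seq_along(ord)) {
    j <- ord[k]
    bp <- bits[, 2 * k - 1]
    bm <- bits[, 2 * k]
    P[, j] <- ifelse(bp == 0L, P[, fa[j]], M[, fa[j]])
    M[, j] <- ifelse(bm == 0L, P[, mo[j]], M[, mo[j]])
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- (P[, i] == P[, j]) + (P[, i] == M[, j]) +
        (M[, i] == P[, j]) + (M[, i] == M[, j])
      phi[i, j] <- phi[j, i] <- mean(share) / 4
    }
  }
  phi
}

# Dense-matrix REML: builds and inverts V = K + delta * I explicitly and
# maximises the restricted likelihood over log10(delta) with a fine grid plus
# Brent polish. Completely separate numerics from the spectral fitter.
oracle_reml <- function(y, F, K, lo = -10, hi = 10) {
  n <- length(y)
  p <- ncol(F)
  ldFF <- as.numeric(determinant(crossprod(F))$modulus)
  pll <- function(lg) {
    delta <- 10^lg
    Vs <- K + diag(delta, n)
    Vi <- solve(Vs)
    A <- t(F) %*% Vi %*% F
    b <- solve(A, t(F) %*% (Vi %*% y))
    r <- drop(y - F %*% b)
    R <- drop(t(r) %*% Vi %*% r)
    s2 <- R / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
              as.numeric(determinant(Vs)$modulus) +
              as.numeric(determinant(A)$modulus) - ldFF)
  }
  grid <- seq(lo, hi, by = 0.05)
  vals <- vapply(grid, pll, 0)
  i <- which.max(vals)
  opt <- stats::optimize(pll, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                         maximum = TRUE, tol = 1e-9)
  best <- if (opt$objective > vals[i]) opt else list(maximum = grid[i], objective = vals[i])
  list(delta = 10^best$maximum, loglik = best$objective)
}

# Double-loop IBS with pairwise deletion.
oracle_ibs <- function(D) {
  n <- nrow(D)
  s <- matrix(NA_real_, n, n, dimnames = list(rownames(D), rownames(D)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ok <- !is.na(D[i, ]) & !is.na(D[j, ])
      s[i, j] <- mean(1 - abs(D[i, ok] - D[j, ok]) / 2)
    }
  }
  diag(s) <- 1
  s
}

# Per-subject any()-over-rare-variants collapsing.
oracle_collapse <- function(D, genes, mafs, gene, threshold) {
  rare <- which(!is.na(genes) & genes == gene & mafs < threshold)
  out <- integer(nrow(D))
  for (i in seq_len(nrow(D))) {
    carried <- FALSE
    for (v in rare) {
      dv <- D[i, v]
      if (!is.na(dv) && dv >= 1) carried <- TRUE
    }
    out[i] <- as.integer(carried)
  }
  out
}
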