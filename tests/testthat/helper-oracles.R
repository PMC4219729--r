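# Independent oracles used across tests. Each is a deliberately naive
# implementation (double loops, closed forms, quaternion method) kept
# separate from the package's own code paths.

KE_ORACLE <- 332.0636

# Quaternion (Horn) method for optimal rigid superposition RMSD.
quaternionRmsd <- function(ref, mov) {
  a <- scale(ref, scale = FALSE)
  b <- scale(mov, scale = FALSE)
  m <- t(b) %*% a
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4)
  lmax <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e <- sum(a^2) + sum(b^2) - 2 * lmax
  sqrt(max(0, e) / nrow(ref))
}

# Brute-force pairwise Coulomb energy (cross-partition when B given).
bruteCoulomb <- function(co, q, eps = 1, idxA = NULL, idxB = NULL) {
  e <- 0
  if (is.null(idxA)) {
    n <- nrow(co)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- sqrt(sum((co[i, ] - co[j, ])^2))
      e <- e + KE_ORACLE * q[i] * q[j] / (eps * r)
    }
  } else {
    for (i in idxA) for (j in idxB) {
      r <- sqrt(sum((co[i, ] - co[j, ])^2))
      e <- e + KE_ORACLE * q[i] * q[j] / (eps * r)
    }
  }
  e
}

# Brute-force 12-6 Lennard-Jones with Lorentz-Berthelot combining.
bruteLJ <- function(co, eps, rmh, idxA = NULL, idxB = NULL,
                    exclude = NULL) {
  e <- 0
  pair <- function(i, j) {
    r <- sqrt(sum((co[i, ] - co[j, ])^2))
    e12 <- sqrt(eps[i] * eps[j])
    rm <- rmh[i] + rmh[j]
    e12 * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  if (is.null(idxA)) {
    n <- nrow(co)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.null(exclude) && exclude[i, j]) next
      e <- e + pair(i, j)
    }
  } else {
    for (i in idxA) for (j in idxB) e <- e + pair(i, j)
  }
  e
}

# Brute-force trailing-window statistics.
bruteWindow <- function(series, fraction = 0.4) {
  nWin <- floor(length(series) * fraction)
  w <- rev(rev(series)[seq_len(nWin)])
  m <- sum(w) / nWin
  s <- sqrt(sum((w - m)^2) / (nWin - 1))
  list(mean = m, sd = s, median = sort(w)[c((nWin + 1) %/% 2,
                                            nWin %/% 2 + 1)] |> mean())
}

# A small random parameterized structure (uncharged optional).
randomStructure <- function(n, seed, spread = 8, charged = TRUE) {
  set.seed(seed)
  atoms <- data.frame(serial = seq_len(n),
                      name = sprintf("X%d", seq_len(n)), element = "C",
                      resName = "XXX", resSeq = seq_len(n), insert = "",
                      chainId = "Z", het = FALSE, stringsAsFactors = FALSE)
  repeat {
    co <- matrix(runif(3 * n, 0, spread), n, 3)
    if (n < 2 || min(dist(co)) > 1.2) break
  }
  ionpocket:::newStructure(
    atoms, co,
    charge = if (charged) round(runif(n, -1, 1), 3) else rep(0, n),
    radius = runif(n, 1.2, 2), ljEpsilon = runif(n, 0.05, 0.3),
    ljRminHalf = runif(n, 1.5, 2.2))
}
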