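# Shared helpers: an independent numeric first-focal-value oracle (the
# classical curvature-coefficient formula, a different derivation from the
# package's exact Lyapunov recursion), and a seeded random-network sampler
# over the raw enumeration space.

# first focal value, numerically, for the trace-zero-curve Hopf point at a
# given cross-section parameter
l1_numeric_oracle <- function(ctx, alpha) {
  h <- alpha * ctx$r1 + (1 - alpha) * ctx$r2
  M <- ctx$gamma %*% diag(h) %*% ctx$A
  s <- -M[2, 2] / M[1, 1]
  x <- c(1, s)
  kappa <- h / apply(ctx$A, 1, function(a) prod(x^a))
  J <- matrix(0, 2, 2)
  for (j in seq_along(kappa)) for (k in 1:2) {
    a <- ctx$A[j, ]
    if (a[k] == 0) next
    e <- a; e[k] <- e[k] - 1
    J[, k] <- J[, k] + kappa[j] * ctx$gamma[, j] * a[k] * prod(x^e)
  }
  om <- sqrt(det(J))
  f2 <- function(u) {
    out <- c(0, 0)
    for (j in seq_along(kappa)) {
      a <- ctx$A[j, ]
      if (sum(a) != 2) next
      out <- out + kappa[j] * ctx$gamma[, j] * prod(u^a)
    }
    out
  }
  P <- cbind(c(0, om), c(J[1, 2], -J[1, 1]))
  Pi <- solve(P)
  Bv <- function(u, v) f2(u + v) - f2(u) - f2(v)
  Fxx <- 2 * Pi %*% f2(P[, 1]); Fyy <- 2 * Pi %*% f2(P[, 2])
  Fxy <- Pi %*% Bv(P[, 1], P[, 2])
  (Fxy[1] * (Fxx[1] + Fyy[1]) - Fxy[2] * (Fxx[2] + Fyy[2]) -
     Fxx[1] * Fxx[2] + Fyy[1] * Fyy[2]) / (16 * om)
}

# random four-reaction network from the raw space (bimolecular reactants,
# trimolecular products), as a census-style representative list
random_raw_network <- function() {
  reactants <- enumerate_complexes(2, 2)
  products <- enumerate_complexes(2, 3)
  repeat {
    ridx <- sample(ncol(reactants), 4, replace = TRUE)
    reac <- reactants[, ridx, drop = FALSE]
    prod <- matrix(0, 2, 4)
    ok <- TRUE
    for (j in 1:4) {
      cand <- which(colSums(abs(products - reac[, j])) > 0)
      prod[, j] <- products[, sample(cand, 1)]
    }
    gam <- prod - reac
    if (any(colSums(abs(gam)) == 0)) next
    return(list(reactant = reac, gamma = gam, product = prod))
  }
}

# dense numeric scan used as the sampling side of the oracle-equivalence
# check (can confirm feasibility, never certify infeasibility)
numeric_core_scan <- function(rep, n_grid = 2001) {
  rays <- kernel_rays(rep$gamma)
  if (ncol(rays) == 0 || !all(rowSums(rays) > 0)) return(NULL)
  r1 <- rays[, 1]
  r2 <- if (ncol(rays) >= 2) rays[, 2] else rays[, 1]
  A <- t(rep$reactant)
  alphas <- seq(1 / n_grid, 1 - 1 / n_grid, length.out = n_grid)
  m11 <- m22 <- dets <- numeric(n_grid)
  for (i in seq_along(alphas)) {
    h <- alphas[i] * r1 + (1 - alphas[i]) * r2
    M <- rep$gamma %*% diag(h) %*% A
    m11[i] <- M[1, 1]; m22[i] <- M[2, 2]; dets[i] <- det(M)
  }
  list(
    zero_eig_seen = any(diff(sign(dets)) != 0) || any(dets == 0),
    min_absdet = min(abs(dets)),
    hopf_seen = any(dets > 0 & m11 * m22 < 0))
}
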