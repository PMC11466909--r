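# The positive kernel cone of the stoichiometric matrix and the reduced
# Jacobian core M(alpha) = Gamma diag(h(alpha)) A on its cross-section.

#' Is a network dynamically nontrivial?
#'
#' A mass-action network admits positive limit sets only if the kernel of its
#' stoichiometric matrix meets the open positive orthant.  Decided exactly:
#' for a rank-two planar network by Stiemke's lemma (no vector `y` with
#' `t(gamma) y` nonnegative and nonzero), in general from the extreme rays of
#' `ker gamma` intersected with the nonnegative orthant.
#'
#' @param net a [crn] object.
#' @return logical.
#' @export
is_dynamically_nontrivial <- function(net) {
  G <- net$gamma
  if (nrow(G) == 2 && net$rank == 2) {
    # Stiemke certificate: candidate separating directions are the
    # perpendiculars of the reaction vectors
    for (j in seq_len(ncol(G))) {
      for (sg in c(1, -1)) {
        y <- sg * c(-G[2, j], G[1, j])
        d <- drop(y %*% G)
        if (all(d >= 0) && any(d > 0)) return(FALSE)
      }
    }
    return(TRUE)
  }
  rays <- kernel_rays(G)
  if (ncol(rays) == 0) return(FALSE)
  all(rowSums(rays) > 0)
}

#' Extreme rays of ker(G) intersected with the nonnegative orthant
#'
#' Small-scale exact double description: every extreme ray of the pointed
#' polyhedral cone \{v >= 0, Gv = 0\} is the one-dimensional solution set of
#' `Gv = 0` with a subset of coordinates pinned to zero.
#'
#' @param G integer matrix (n x m).
#' @return m x k matrix of primitive integer rays (k may be 0).
#' @export
kernel_rays <- function(G) {
  G <- as.matrix(G)
  m <- ncol(G)
  found <- list()
  for (mask in 0:(2^m - 1)) {
    zero <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) != 0)
    keep <- setdiff(seq_len(m), zero)
    if (!length(keep)) next
    sub <- G[, keep, drop = FALSE]
    kb <- int_kernel(sub)
    if (ncol(kb) != 1) next
    v <- numeric(m)
    v[keep] <- kb[, 1]
    if (all(v >= 0)) {
      # nothing to do
    } else if (all(v <= 0)) {
      v <- -v
    } else next
    v <- primitive(v)
    key <- paste(v, collapse = ",")
    found[[key]] <- v
  }
  if (!length(found)) return(matrix(0, m, 0))
  rays <- do.call(cbind, found[order(names(found))])
  # drop non-extreme duplicates-by-support (a ray whose support strictly
  # contains another ray's support is not extreme)
  keep <- rep(TRUE, ncol(rays))
  for (i in seq_len(ncol(rays))) for (j in seq_len(ncol(rays))) {
    if (i == j || !keep[i]) next
    si <- rays[, i] != 0; sj <- rays[, j] != 0
    if (all(sj[si]) && any(sj & !si)) keep[j] <- FALSE
  }
  rays[, keep, drop = FALSE]
}

#' Kernel cone of a dynamically nontrivial network
#'
#' Returns the extreme rays and the affine cross-section
#' `h(alpha) = alpha r1 + (1 - alpha) r2` (for a two-dimensional kernel) or
#' the single fixed ray (one-dimensional kernel).
#'
#' @param net a [crn] object.
#' @return list with `rays` (m x k primitive integer matrix), `dim`
#'   (`m - rank`), and `r1`, `r2` (the cross-section endpoints; equal when
#'   the kernel is one-dimensional).
#' @export
kernel_cone <- function(net) {
  rays <- kernel_rays(net$gamma)
  if (ncol(rays) == 0 || !all(rowSums(rays) > 0))
    stop("empty positive kernel: network is dynamically trivial")
  k <- ncol(net$gamma) - net$rank
  if (ncol(rays) == 1) {
    list(rays = rays, dim = k, r1 = rays[, 1], r2 = rays[, 1])
  } else if (ncol(rays) == 2) {
    list(rays = rays, dim = k, r1 = rays[, 1], r2 = rays[, 2])
  } else {
    stop("kernel cone with more than two extreme rays is not supported here")
  }
}

#' Reduced Jacobian core M(alpha) on the kernel-cone cross-section
#'
#' `M(alpha) = Gamma diag(h(alpha)) A`; at a positive equilibrium the
#' Jacobian equals `lambda M(alpha) diag(1/x)`, so the signs of `det M`,
#' `M11` and `M22` drive every eigenvalue-feasibility decision.
#'
#' @param net a planar [crn]; @param cone result of [kernel_cone] (computed
#'   if missing).
#' @return list of ascending coefficient vectors `M11, M12, M21, M22`
#'   (affine in alpha) and `detM` (quadratic), plus the cone.
#' @export
reduced_core <- function(net, cone = NULL) {
  stopifnot(nrow(net$gamma) == 2)
  if (is.null(cone)) cone <- kernel_cone(net)
  G <- net$gamma; A <- net$A
  ent <- function(i, k) {
    # constant term from r2, slope from r1 - r2
    c0 <- sum(G[i, ] * cone$r2 * A[, k])
    c1 <- sum(G[i, ] * (cone$r1 - cone$r2) * A[, k])
    chk_int(c(c0, c1))
  }
  M11 <- ent(1, 1); M12 <- ent(1, 2); M21 <- ent(2, 1); M22 <- ent(2, 2)
  pmul <- function(a, b) {
    r <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) for (j in seq_along(b))
      r[i + j - 1] <- r[i + j - 1] + a[i] * b[j]
    chk_int(r)
  }
  detM <- pmul(M11, M22) - pmul(M12, M21)
  list(M11 = M11, M12 = M12, M21 = M21, M22 = M22, detM = detM, cone = cone)
}

#' Rank condition for nondegenerate positive equilibria
#'
#' A planar full-rank network admits a positive nondegenerate equilibrium
#' only if `rank [A | 1] = 3`, i.e. the reactant complexes do not lie on an
#' affine line.
#' @param net a [crn] object.
#' @export
rank_condition <- function(net) {
  int_rank(cbind(net$A, 1)) == nrow(net$gamma) + 1
}

#' Are the distinct reactant complexes affinely collinear?
#' @param net a planar [crn] object.
#' @export
reactants_collinear <- function(net) {
  stopifnot(nrow(net$gamma) == 2)
  pts <- unique(t(net$reactant))
  if (nrow(pts) <= 2) return(TRUE)
  base <- pts[1, ]
  d <- sweep(pts[-1, , drop = FALSE], 2, base)
  all(d[, 1] * d[1, 2] - d[, 2] * d[1, 1] == 0) &&
    int_rank(t(d)) <= 1
}

#' Does some reaction vector lie in the positive span of the other reaction
#' vectors on the same reactant complex?
#' @param net a [crn] object.
#' @export
has_redundant_reaction <- function(net) {
  m <- ncol(net$gamma)
  key <- apply(net$reactant, 2, paste, collapse = ",")
  for (j in seq_len(m)) {
    others <- setdiff(which(key == key[j]), j)
    if (!length(others)) next
    if (in_positive_span(net$gamma[, j], net$gamma[, others, drop = FALSE]))
      return(TRUE)
  }
  FALSE
}

# is the 2-vector v a nonnegative combination of the columns of W (2 x k)?
in_positive_span <- function(v, W) {
  k <- ncol(W)
  # single generators
  for (j in seq_len(k)) {
    w <- W[, j]
    cross <- v[1] * w[2] - v[2] * w[1]
    if (cross == 0 && sum(v * w) > 0) return(TRUE)
  }
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      w1 <- W[, i]; w2 <- W[, j]
      d <- w1[1] * w2[2] - w1[2] * w2[1]
      if (d == 0) next
      # solve a w1 + b w2 = v exactly
      a <- (v[1] * w2[2] - v[2] * w2[1]) / d
      b <- (w1[1] * v[2] - w1[2] * v[1]) / d
      if (a >= 0 && b >= 0) return(TRUE)
    }
  }
  FALSE
}
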