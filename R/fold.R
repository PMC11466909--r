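# Fold bifurcation classification: nondegenerate folds, forced double
# zeros, vertical folds (lines of equilibria), the rank-one combinatorial
# pattern, and origin stability for the bimolecular multistability count.

#' Classify fold-type behaviour of a census network
#'
#' @param net a planar rank-two [crn] (or census representative).
#' @return list (`FoldRecord`): `fold_feasible` (a det-root exists at which
#'   the reduced core is not nilpotent), `forced_double_zero` (every
#'   det-root has both diagonal entries zero: the zero eigenvalue always has
#'   algebraic multiplicity two), `fold_nondegenerate` (exact witness check:
#'   nonzero quadratic normal-form coefficient and transversal unfolding of
#'   det J by the rate constants), `second_eigenvalue_signs`.
#' @export
classify_fold <- function(net) {
  ca <- core_analysis(net)
  ctx <- ca$ctx
  fold_feasible <- ca$zero_eigenvalue && !ca$forced_double_zero
  rec <- list(
    zero_eigenvalue = ca$zero_eigenvalue,
    fold_feasible = fold_feasible,
    forced_double_zero = ca$forced_double_zero,
    second_eigenvalue_signs = c(if (ca$neg_possible) "negative",
                                if (ca$pos_possible) "positive"),
    fold_nondegenerate = FALSE)
  if (fold_feasible) {
    w <- fold_witness_cpp(ctx$gamma, ctx$A, ctx$r1, ctx$r2)
    rec$fold_nondegenerate <- w$nondegenerate
  }
  rec
}

#' Line type of a vertical fold (curve of equilibria at critical rates)
#'
#' For a census network admitting no positive nondegenerate equilibrium
#' (det M identically zero, or rank [A|1] < 3), the solvability condition
#' holds either never or on the whole cross-section; at the critical rate
#' constants the equilibrium set is a curve.  Its type is decided exactly
#' from the monomial parameterisation `x(alpha) = (h(alpha)/kappa)^G`.
#'
#' @param net a planar rank-two [crn] (or census representative) without
#'   positive nondegenerate equilibria.
#' @return one of `"through-origin"`, `"vertical"`, `"horizontal"` (or
#'   `"none"` if the equilibrium set is not a line).
#' @export
vertical_fold <- function(net) {
  ctx <- as_ctx(net)
  A <- ctx$A
  A1 <- cbind(A, 1)
  if (int_rank(A1) < 3) {
    ker <- int_kernel(A1)
    if (ncol(ker) != 1) return("none")
    u <- ker[1:2, 1]
    if (u[1] == 0 && u[2] != 0) return("vertical")
    if (u[2] == 0 && u[1] != 0) return("horizontal")
    if (u[1] == u[2] && u[1] != 0) return("through-origin")
    return("none")
  }
  # detM identically zero case: the solvability function h(alpha)^W must be
  # constant for a curve of equilibria to exist
  rc <- reduced_core(list(gamma = ctx$gamma, A = A, rank = 2),
                     list(r1 = ctx$r1, r2 = ctx$r2))
  if (any(rc$detM != 0))
    stop("network admits nondegenerate equilibria: not a vertical fold")
  W <- int_kernel(t(A1))
  stopifnot(ncol(W) == 1)
  w <- W[, 1]
  hpoly <- lapply(seq_len(4), function(j)
    c(ctx$r2[j], ctx$r1[j] - ctx$r2[j]))  # u + v alpha
  # h^w constant <=> for each proportionality class of non-constant affine
  # factors, the net exponent vanishes
  if (!affine_power_constant(hpoly, w))
    return("none")
  # left inverse of [A|1] from three independent rows
  rows <- independent_rows(A1)
  Gi <- int_inverse(A1[rows, , drop = FALSE])
  # G entries as rationals: G[i, j] nonzero only for j in rows
  Gnum <- matrix(0, 3, 4); Gden <- Gi$den
  Gnum[, rows] <- Gi$num
  e_vert <- Gnum[1, ]               # exponents of x1(alpha) (times Gden)
  e_horz <- Gnum[2, ]
  e_orig <- Gnum[2, ] - Gnum[1, ]
  if (affine_power_constant(hpoly, e_vert)) return("vertical")
  if (affine_power_constant(hpoly, e_horz)) return("horizontal")
  if (affine_power_constant(hpoly, e_orig)) return("through-origin")
  "none"
}

# is prod_j (u_j + v_j alpha)^(e_j) constant in alpha?
affine_power_constant <- function(hpoly, e) {
  used <- which(e != 0)
  classes <- list()
  for (j in used) {
    f <- hpoly[[j]]
    if (length(f) < 2 || f[2] == 0) next  # constant factor
    placed <- FALSE
    for (k in seq_along(classes)) {
      g <- classes[[k]]$form
      if (f[1] * g[2] - f[2] * g[1] == 0) {
        classes[[k]]$e <- classes[[k]]$e + e[j]
        placed <- TRUE
        break
      }
    }
    if (!placed) classes[[length(classes) + 1]] <- list(form = f, e = e[j])
  }
  all(vapply(classes, function(cl) cl$e == 0, logical(1)))
}

independent_rows <- function(M) {
  rows <- integer(0)
  for (i in seq_len(nrow(M))) {
    cand <- c(rows, i)
    if (int_rank(M[cand, , drop = FALSE]) == length(cand)) rows <- cand
    if (length(rows) == ncol(M)) break
  }
  rows
}

#' Combinatorial rank-one fold / multistationarity test
#'
#' A quadratic rank-one mass-action network admits multiple positive
#' nondegenerate equilibria (equivalently a nondegenerate fold bifurcation)
#' iff, after removing trivial species, it has at most two species and
#' contains three reactions matching one of the canonical patterns: in one
#' species `0 -> aX, X -> 0, 2X -> bX` (a >= 1, b >= 3); in two species the
#' consuming reaction `X+Y -> 0` together with a doubling reaction
#' `2X -> (2+b)X + bY` (or its mirror) and a third production reaction, all
#' up to simple equivalence (positive column scaling).
#'
#' @param net a quadratic rank-one [crn] object.
#' @return logical.
#' @export
rank_one_fold <- function(net) {
  if (net$rank != 1) stop("rank_one_fold requires a rank-one network")
  if (!structural_predicates(net)$quadratic) stop("network must be quadratic")
  keep <- which(rowSums(net$gamma != 0) > 0)
  if (length(keep) > 2) return(FALSE)
  R <- net$reactant[keep, , drop = FALSE]
  G <- net$gamma[keep, , drop = FALSE]
  if (length(keep) == 1) {
    dirs <- sign(G[1, ])
    has <- function(reac, d) any(R[1, ] == reac & dirs == d)
    return(has(0, 1) && has(1, -1) && has(2, 1))
  }
  # two nontrivial species: stoichiometric direction must be +-(1,1)
  v <- primitive(G[, which(colSums(G != 0) > 0)[1]], keep_sign = FALSE)
  if (!all(abs(v) == c(1, 1)) || v[1] != v[2]) return(FALSE)
  d <- vapply(seq_len(ncol(G)), function(j) {
    if (all(G[, j] == 0)) 0 else sign(sum(G[, j] * v))
  }, numeric(1))
  reac_is <- function(j, a, b) R[1, j] == a && R[2, j] == b
  has <- function(a, b, dd) any(vapply(seq_len(ncol(G)), function(j)
    reac_is(j, a, b) && d[j] == dd, logical(1)))
  consuming <- has(1, 1, -1)
  if (!consuming) return(FALSE)
  (has(2, 0, 1) && (has(0, 0, 1) || has(0, 1, 1) || has(0, 2, 1))) ||
    (has(0, 2, 1) && (has(0, 0, 1) || has(1, 0, 1) || has(2, 0, 1)))
}

#' Stability of the origin for a planar mass-action network, over all rates
#'
#' Classifies the origin for every choice of positive rate constants:
#' `"not-equilibrium"` if an inflow reaction (reactant 0) is present,
#' `"linearly-stable"` / `"saddle"` / `"unstable"` when the linearisation
#' decides uniformly in the rates, `"stable-via-center-manifold"` when a
#' zero eigenvalue is resolved by the flow on an invariant axis, and
#' `"depends"` / `"undecided"` otherwise.
#'
#' @param net a planar [crn] object.
#' @return character scalar.
#' @export
origin_stability <- function(net) {
  stopifnot(nrow(net$gamma) == 2)
  m <- ncol(net$gamma)
  reac_mol <- molecularity(net$reactant)
  if (any(reac_mol == 0)) return("not-equilibrium")
  RX <- which(net$reactant[1, ] == 1 & net$reactant[2, ] == 0)
  RY <- which(net$reactant[1, ] == 0 & net$reactant[2, ] == 1)
  trc <- c(net$gamma[1, RX], net$gamma[2, RY])
  if (length(RX) && length(RY)) {
    dets <- outer(RX, RY, Vectorize(function(j, k)
      net$gamma[1, j] * net$gamma[2, k] - net$gamma[2, j] * net$gamma[1, k]))
    if (all(dets >= 0) && any(dets > 0)) {
      if (all(trc <= 0) && any(trc < 0)) return("linearly-stable")
      if (all(trc >= 0) && any(trc > 0)) return("unstable")
      return("depends")
    }
    if (all(dets <= 0) && any(dets < 0)) return("saddle")
    if (all(dets == 0)) return(zero_eig_axis_rule(net, RX, RY))
    return("depends")
  }
  zero_eig_axis_rule(net, RX, RY)
}

# origin with a zero eigenvalue: decide via the flow on an invariant axis
zero_eig_axis_rule <- function(net, RX, RY) {
  if (!length(RX) && !length(RY)) return("undecided")
  if (!length(RX)) {
    # eigenvalues 0 and sum over RY of kappa gamma_2
    lam <- net$gamma[2, RY]
    if (!(all(lam <= 0) && any(lam < 0))) {
      if (all(lam >= 0) && any(lam > 0)) return("unstable")
      return("depends")
    }
    # x-axis invariant? reactions with reactant on the x-axis must not move y
    ax <- which(net$reactant[2, ] == 0)
    if (any(net$gamma[2, ax] != 0)) return("undecided")
    flow <- net$gamma[1, ax]           # signs of axis flow terms
    if (length(ax) && all(flow <= 0) && any(flow < 0))
      return("stable-via-center-manifold")
    if (length(ax) && all(flow >= 0) && any(flow > 0)) return("unstable")
    return("undecided")
  }
  if (!length(RY)) {
    lam <- net$gamma[1, RX]
    if (!(all(lam <= 0) && any(lam < 0))) {
      if (all(lam >= 0) && any(lam > 0)) return("unstable")
      return("depends")
    }
    ay <- which(net$reactant[1, ] == 0)
    if (any(net$gamma[1, ay] != 0)) return("undecided")
    flow <- net$gamma[2, ay]
    if (length(ay) && all(flow <= 0) && any(flow < 0))
      return("stable-via-center-manifold")
    if (length(ay) && all(flow >= 0) && any(flow > 0)) return("unstable")
    return("undecided")
  }
  "undecided"
}
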