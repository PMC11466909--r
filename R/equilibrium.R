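# Eigenvalue-feasibility decisions on the kernel-cone cross-section, and the
# exact parameterisation of positive equilibria.

# analysis context: integer matrices and cone rays, from a crn or a census
# representative
as_ctx <- function(x) {
  if (inherits(x, "crn")) {
    cone <- kernel_cone(x)
    list(gamma = matrix(as.integer(x$gamma), nrow = 2),
         A = matrix(as.integer(x$A), ncol = 2),
         r1 = as.numeric(cone$r1), r2 = as.numeric(cone$r2),
         reactant = x$reactant)
  } else {
    rc <- reduced_core_rep(x)
    list(gamma = matrix(as.integer(x$gamma), nrow = 2),
         A = matrix(as.integer(t(x$reactant)), ncol = 2),
         r1 = as.numeric(rc$cone$r1), r2 = as.numeric(rc$cone$r2),
         reactant = x$reactant)
  }
}

core_analysis <- function(x) {
  ctx <- if (is.list(x) && !is.null(x$r1)) x else as_ctx(x)
  out <- core_analysis_cpp(ctx$gamma, ctx$A, ctx$r1, ctx$r2)
  out$ctx <- ctx
  out
}

# rational points alpha* in (0,1) where M11 and M22 vanish simultaneously
# (there the Jacobian trace vanishes for every positive x); returns a list
# of c(num, den) pairs, plus the sign of detM at each
trace_zero_points <- function(x) {
  ctx <- if (is.list(x) && !is.null(x$r1)) x else as_ctx(x)
  net <- list(gamma = ctx$gamma, A = ctx$A, rank = 2)
  rc <- reduced_core(net, list(r1 = ctx$r1, r2 = ctx$r2))
  aff_root <- function(p) {
    # root of an affine integer polynomial as c(num, den), or NULL
    if (length(p) < 2 || p[2] == 0) return(NULL)
    rat(-p[1], p[2])
  }
  M11 <- rc$M11; M22 <- rc$M22
  z11 <- all(M11 == 0); z22 <- all(M22 == 0)
  pts <- list()
  if (z11 && z22)
    stop("both diagonal entries vanish identically: two-parameter Hopf set")
  cand <- NULL
  if (z11) cand <- aff_root(M22)
  else if (z22) cand <- aff_root(M11)
  else {
    r1 <- aff_root(M11); r2 <- aff_root(M22)
    if (!is.null(r1) && !is.null(r2) && rat_eq(r1, r2)) cand <- r1
  }
  if (!is.null(cand) && cand[1] > 0 && cand[1] < cand[2]) {
    # detM at p/q: sum detM[i] p^(i-1) q^(deg-i+1), sign only
    p <- cand[1]; q <- cand[2]; d <- length(rc$detM) - 1
    val <- sum(rc$detM * p^(0:d) * q^(d:0))
    chk_int(val)
    pts[[1]] <- list(alpha = cand, det_sign = sign(val))
  }
  pts
}

#' Does a network admit a positive nondegenerate equilibrium?
#'
#' True iff `rank [A|1] = 3` and the determinant of the reduced Jacobian
#' core is not identically zero on the open kernel-cone cross-section.
#' @param net a planar rank-two [crn] (or census representative).
#' @export
admits_nondegenerate_equilibrium <- function(net) {
  A <- if (inherits(net, "crn")) net$A else t(net$reactant)
  if (int_rank(cbind(A, 1)) != 3) return(FALSE)
  ca <- core_analysis(net)
  ca$detm_nonzero
}

#' Can a positive equilibrium have a zero eigenvalue?
#'
#' Decided exactly by isolating the real roots of `det M(alpha)` in the open
#' cross-section domain.
#' @param net a planar rank-two [crn] (or census representative).
#' @return list with `feasible` and the isolated `roots` (each with exact
#'   interval endpoints and the signs of M11, M22 there).
#' @export
zero_eigenvalue_feasible <- function(net) {
  ca <- core_analysis(net)
  list(feasible = ca$zero_eigenvalue, roots = ca$roots,
       forced_double_zero = ca$forced_double_zero)
}

#' Achievable signs of the nonzero eigenvalue at a zero-eigenvalue point
#'
#' At a root of `det M`, the other eigenvalue is the trace
#' `M11/x1 + M22/x2` with `x` free positive, so a negative (positive)
#' companion eigenvalue is achievable iff some diagonal entry is negative
#' (positive) at some root.
#' @param net a planar rank-two [crn] (or census representative).
#' @return character subset of `c("negative", "positive")`.
#' @export
second_eigenvalue_signs <- function(net) {
  ca <- core_analysis(net)
  out <- character(0)
  if (ca$neg_possible) out <- c(out, "negative")
  if (ca$pos_possible) out <- c(out, "positive")
  out
}

#' Can a positive equilibrium have purely imaginary eigenvalues?
#'
#' True iff some cross-section point has `det M > 0` together with either
#' oppositely signed diagonal entries (the trace is zeroed by the choice of
#' `x`) or both diagonal entries zero (the trace vanishes for every `x`).
#' @param net a planar rank-two [crn] (or census representative).
#' @export
purely_imaginary_feasible <- function(net) {
  ca <- core_analysis(net)
  if (ca$hopf_feasible) return(TRUE)
  tz <- trace_zero_points(ca$ctx)
  any(vapply(tz, function(p) p$det_sign > 0, logical(1)))
}

#' Rate constants realising a prescribed equilibrium
#'
#' Inverts the equilibrium condition `kappa o x^A = lambda h(alpha)`:
#' `kappa = lambda h(alpha) / x^A`.  With this `kappa`, `x` is a positive
#' equilibrium of the mass-action field.
#'
#' @param net a [crn]; @param x positive rational vector; @param alpha
#'   cross-section parameter in (0,1); @param lambda positive scale.
#' @return numeric vector of rate constants (exact rationals in doubles).
#' @export
construct_rate_constants <- function(net, x, alpha, lambda = 1) {
  cone <- kernel_cone(net)
  h <- alpha * cone$r1 + (1 - alpha) * cone$r2
  m <- ncol(net$gamma)
  kap <- numeric(m)
  for (j in seq_len(m)) {
    mono <- prod(x^net$A[j, ])
    kap[j] <- lambda * h[j] / mono
  }
  kap
}

#' Positive equilibria of a network at fixed rational rate constants
#'
#' Uses the smooth bijection between positive equilibria and cross-section
#' solutions of the solvability condition `kappa^W = h(alpha)^W`, where the
#' rows of W span the left kernel of `[A | 1]`.  Clearing denominators
#' yields a univariate polynomial whose roots in the open domain are counted
#' and isolated exactly; nondegeneracy per root is the sign of `det M`.
#'
#' @param net a planar rank-two [crn]; @param kappa positive rational rates.
#' @return list with `count`, `nondegenerate_count`, `continuum` (logical:
#'   a positive-dimensional equilibrium set), `roots` (approximate alpha
#'   locations) and `det_signs`.
#' @export
solve_equilibria <- function(net, kappa) {
  stopifnot(nrow(net$gamma) == 2, net$rank == 2)
  m <- ncol(net$gamma)
  A1 <- cbind(net$A, 1)
  if (int_rank(A1) < 3) {
    # all equilibria degenerate (rank condition fails)
    return(list(count = NA, nondegenerate_count = 0, continuum = NA,
                degenerate_rank = TRUE))
  }
  W <- int_kernel(t(A1))
  cone <- kernel_cone(net)
  rc <- reduced_core(net, cone)
  if (ncol(W) == 0) {
    # m = 3: solvability trivially satisfied, unique equilibrium
    nd <- any(rc$detM != 0)
    return(list(count = 1, nondegenerate_count = as.integer(nd),
                continuum = FALSE, roots = numeric(0)))
  }
  stopifnot(ncol(W) == 1)
  w <- W[, 1]
  # h_j(alpha) as affine integer polynomials
  hpoly <- lapply(seq_len(m), function(j)
    c(cone$r2[j], cone$r1[j] - cone$r2[j]))
  pmul <- function(a, b) {
    r <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) for (j in seq_along(b))
      r[i + j - 1] <- r[i + j - 1] + a[i] * b[j]
    chk_int(r)
  }
  # kappa as exact rationals
  kr <- lapply(kappa, function(k) {
    den <- 1
    while (abs(k * den - round(k * den)) > 1e-9 && den < 1e6) den <- den * 10
    rat(round(k * den), den)
  })
  lhs <- 1; rhs <- 1            # polynomial sides
  lnum <- 1; lden <- 1          # scalar kappa parts (exact ints)
  rnum <- 1; rden <- 1
  for (j in seq_len(m)) {
    if (w[j] > 0) {
      for (t in seq_len(w[j])) lhs <- pmul(lhs, hpoly[[j]])
      rnum <- chk_int(rnum * kr[[j]][1]^w[j]); rden <- chk_int(rden * kr[[j]][2]^w[j])
    } else if (w[j] < 0) {
      for (t in seq_len(-w[j])) rhs <- pmul(rhs, hpoly[[j]])
      lnum <- chk_int(lnum * kr[[j]][1]^(-w[j])); lden <- chk_int(lden * kr[[j]][2]^(-w[j]))
    }
  }
  # solvability kappa^W = h(alpha)^W rearranged with positive parts on each
  # side: (kpos) * hneg(alpha) = (kneg) * hpos(alpha), where hpos = lhs,
  # hneg = rhs, kpos = rnum/rden, kneg = lnum/lden
  P <- chk_int(rnum * lden) * rhs
  Qp <- chk_int(lnum * rden) * lhs
  len <- max(length(P), length(Qp))
  S <- numeric(len)
  S[seq_along(P)] <- P
  S[seq_along(Qp)] <- S[seq_along(Qp)] - Qp
  chk_int(S)
  if (all(S == 0)) {
    return(list(count = Inf, nondegenerate_count = 0, continuum = TRUE))
  }
  rt <- signs_at_roots_cpp(S, list(rc$detM), 0, 1)
  n <- rt$n_roots
  det_signs <- if (n > 0) rt$signs[, 1] else integer(0)
  list(count = n, nondegenerate_count = sum(det_signs != 0),
       continuum = FALSE, roots = rt$approx, det_signs = det_signs)
}
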