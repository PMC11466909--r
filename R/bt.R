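# Bogdanov-Takens classification: double-zero feasibility, normal-form
# coefficients a20, b11, b20, the sign sigma = sign((a20+b11) b20),
# transversality, and the explicit analysis of the vertical-BT network.

#' Does a network admit a positive equilibrium with a double zero eigenvalue?
#'
#' True iff `det M(alpha) = 0` at some cross-section point with oppositely
#' signed diagonal entries (the trace is then zeroed by the choice of `x`,
#' and the Jacobian is nilpotent of index two).
#' @param net a planar rank-two [crn] (or census representative).
#' @export
double_zero_feasible <- function(net) {
  core_analysis(net)$double_zero
}

#' Bogdanov-Takens normal form of a census network
#'
#' At each double-zero point, transforms the quadratic field to the basis
#' `(q0, q1)` with `J q0 = 0`, `J q1 = q0` and reads off the normal-form
#' coefficients exactly (in the quadratic number field of the det-root).
#' Only signs and zero/nonzero distinctions are reported; these are
#' invariant under the admissible basis scalings.
#'
#' @param net a planar rank-two [crn] (or census representative).
#' @return list (`BTRecord`): `double_zero_feasible`, `vertical_bt`
#'   (a20 + b11 = 0), `sigma` (+1 subcritical, -1 supercritical, 0
#'   degenerate), `b20_zero`, `transversal`.
#' @export
bt_normal_form <- function(net) {
  ctx <- as_ctx(net)
  res <- bt_classify_cpp(ctx$gamma, ctx$A, ctx$r1, ctx$r2)
  if (!res$double_zero_feasible)
    return(list(double_zero_feasible = FALSE))
  pts <- res$points
  sig <- unique(vapply(pts, function(p) p$sigma, integer(1)))
  vert <- any(vapply(pts, function(p) p$vertical_bt, logical(1)))
  list(double_zero_feasible = TRUE,
       vertical_bt = vert,
       sigma = if (length(sig) == 1) sig else NA_integer_,
       b20_zero = any(vapply(pts, function(p) p$b20_zero, logical(1))),
       transversal = all(vapply(pts, function(p) p$transversal, logical(1))),
       points = pts)
}

#' Analysis of the vertical Bogdanov-Takens network (catalog network 9)
#'
#' For the network `2X > 3X; X+Y > 2X; 0 > Y; X > 0` with mass-action field
#' `xdot = k1 x^2 + k2 xy - k3 x`, `ydot = -k2 xy + k4`:
#' the divergence after multiplying by the Dulac function 1/x is the
#' constant `k1 - k2`; at `k1 = k2` the system is Hamiltonian with
#' `H = k1 x y + (k1/2) y^2 - k3 y - k4 ln x`; and the number of positive
#' equilibria is 0, 1 or 2 according to the sign of `4 k1 k4 - k3^2`.
#' All identities are verified symbolically; the equilibrium trichotomy is
#' verified on exact rational rate constants.
#'
#' @param net a [crn]; defaults to network 9 of the Bogdanov-Takens catalog.
#' @return list with `dulac_divergence` (the polynomial `x^2 div((1/x) f)`),
#'   `dulac_is_constant` (it equals `(k1 - k2) x^2`),
#'   `hamiltonian_conserved` (`dH/dt` vanishes identically at `k1 = k2`),
#'   and `equilibrium_counts` for rates on both sides of `4 k1 k4 = k3^2`.
#' @export
vertical_bt_analysis <- function(net = parse_network("2X > 3X; X+Y > 2X; 0 > Y; X > 0")) {
  ma <- mass_action_rhs(net)
  vars <- ma$vars  # x, y, k1..k4
  f1 <- ma$field[[1]]; f2 <- ma$field[[2]]
  x <- mp_var(vars, vars[1]); y <- mp_var(vars, vars[2])
  # x^2 * div((1/x) f) = x d(f1)/dx - f1 + x d(f2)/dy
  div2 <- mp_add(mp_sub(mp_mul(x, mp_deriv(f1, vars[1])), f1),
                 mp_mul(x, mp_deriv(f2, vars[2])))
  k1 <- mp_var(vars, "k1"); k2 <- mp_var(vars, "k2")
  expected <- mp_mul(mp_sub(k1, k2), mp_mul(x, x))
  dulac_const <- mp_equal(div2, expected)
  # Hamiltonian check at k1 = k2, in this reaction order (inflow rate k3,
  # outflow rate k4): H = k1 x y + (k1/2) y^2 - k4 y - k3 ln x, and
  # dH/dt = Hx f1 + Hy f2 with Hx = k1 y - k3/x.  Since f1 = x g1 with
  # g1 = k1 x + k1 y - k4 (after k2 -> k1), Hx f1 = (k1 x y - k3) g1 is a
  # polynomial and conservation is checked exactly.
  k3 <- mp_var(vars, "k3"); k4 <- mp_var(vars, "k4")
  f1s <- mp_subst(f1, list(k2 = k1))
  f2s <- mp_subst(f2, list(k2 = k1))
  g1 <- mp_sub(mp_add(mp_mul(k1, x), mp_mul(k1, y)), k4)
  stopifnot(mp_equal(f1s, mp_mul(x, g1)))
  Hx_times_x <- mp_sub(mp_mul(k1, mp_mul(x, y)), k3)
  Hy <- mp_sub(mp_add(mp_mul(k1, x), mp_mul(k1, y)), k4)
  dHdt <- mp_add(mp_mul(Hx_times_x, g1), mp_mul(Hy, f2s))
  ham_ok <- mp_is_zero(dHdt)
  # reaction order is (2X>3X, X+Y>2X, 0>Y, X>0); in the displayed equation
  # k3 is the X>0 rate and k4 the 0>Y rate, i.e. positions 4 and 3 here
  counts <- c(
    negative = solve_equilibria(net, c(1, 1, 2, 3))$count,   # 4k1k4 - k3^2 = -1
    zero = solve_equilibria(net, c(1, 1, 1, 2))$count,       # = 0
    positive = solve_equilibria(net, c(1, 1, 1, 1))$count)   # = 3
  list(dulac_divergence = div2, dulac_is_constant = dulac_const,
       hamiltonian_conserved = ham_ok, equilibrium_counts = counts)
}
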