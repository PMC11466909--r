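# Kernel cone, reduced Jacobian core, and eigenvalue feasibility decisions.

net1 <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")   # catalog network 1
lva2 <- parse_network("2X > 3X; X+Y > 2Y; Y > 0")          # generalised LVA b=2
net9 <- parse_network("2X > 3X; X+Y > 2X; 0 > Y; X > 0")   # catalog network 9

test_that("kernel cones have the expected extreme rays", {
  cone <- kernel_cone(net1)
  expect_equal(ncol(cone$rays), 2)
  expect_true(all(c("0,0,1,1", "1,1,1,0") %in%
                    apply(cone$rays, 2, paste, collapse = ",")))
  cone2 <- kernel_cone(lva2)
  expect_equal(ncol(cone2$rays), 1)
  expect_equal(unname(cone2$rays[, 1]), c(1, 1, 1))
  expect_error(kernel_cone(parse_network("0 > X")), "empty positive kernel")
})

test_that("the reduced core of network 1 is det M = alpha (2 alpha - 1)", {
  cone <- kernel_cone(net1)
  rc <- crnbif:::reduced_core(net1, cone)
  # with h(alpha) = alpha (1,1,1,0) + (1-alpha) (0,0,1,1):
  # detM = 2 alpha^2 - alpha; with the rays in the other order the
  # cross-section is reparameterised alpha -> 1 - alpha: 2 alpha^2 - 3 alpha + 1
  to_poly <- function(p) { length(p) <- 3; p[is.na(p)] <- 0; unname(p) }
  d <- to_poly(rc$detM)
  if (all(cone$r1 == c(1, 1, 1, 0))) expect_equal(d, c(0, -1, 2))
  else expect_equal(d, c(1, -3, 2))
})

test_that("rank condition on [A|1] separates collinear reactant sets", {
  expect_true(rank_condition(net1))
  expect_false(rank_condition(parse_network("0 > Y; X > X+Y; 2X > 2X+Y; X > 0")))
  expect_false(rank_condition(parse_network("2X > 3X; X+Y > 2X; 2Y > X+2Y; X+Y > 0")))
})

test_that("zero-eigenvalue and purely-imaginary feasibility match hand analysis", {
  z <- zero_eigenvalue_feasible(net1)
  expect_true(z$feasible)
  expect_equal(length(z$roots), 1)
  expect_true(z$roots[[1]]$exact)
  expect_equal(z$roots[[1]]$lo_str, "1/2")
  expect_false(zero_eigenvalue_feasible(lva2)$feasible)

  expect_setequal(second_eigenvalue_signs(net1), c("negative", "positive"))
  expect_true(purely_imaginary_feasible(net1))
  expect_false(purely_imaginary_feasible(lva2))
  # a network without reactant X+Y can never have purely imaginary pairs
  expect_false(purely_imaginary_feasible(
    parse_network("2X > 3X; X > 0; Y > 0; 0 > Y")))
})

test_that("constructed rate constants put the prescribed point at equilibrium", {
  set.seed(11)
  for (i in 1:5) {
    x <- c(sample(1:4, 1), sample(1:4, 1)) / sample(1:3, 1)
    alpha <- sample(1:7, 1) / 8
    lam <- sample(1:3, 1)
    kap <- construct_rate_constants(net1, x, alpha, lam)
    expect_true(all(kap > 0))
    # field at x must vanish: gamma (kappa o x^A) = lambda gamma h = 0
    mono <- apply(net1$A, 1, function(a) prod(x^a))
    expect_equal(unname(net1$gamma %*% (kap * mono)), matrix(0, 2, 1),
                 tolerance = 1e-12)
  }
})

test_that("network 9 has 0/1/2 positive equilibria by the sign of 4k1k4 - k3^2", {
  # reaction order (2X>3X, X+Y>2X, 0>Y, X>0): the inflow rate sits third
  expect_equal(solve_equilibria(net9, c(1, 1, 2, 3))$count, 2)  # 4k1k4-k3^2 < 0
  expect_equal(solve_equilibria(net9, c(1, 1, 1, 2))$count, 1)  # = 0
  expect_equal(solve_equilibria(net9, c(1, 1, 1, 1))$count, 0)  # > 0
  # kappa = (1,1,2,3): equilibria at x = 1 and x = 2 (roots of x^2 - 3x + 2)
  sol <- solve_equilibria(net9, c(1, 1, 2, 3))
  expect_equal(sol$nondegenerate_count, 2)
  expect_setequal(sol$det_signs, c(-1, 1))
})

test_that("three or fewer distinct reactants forbid multiple nondegenerate equilibria", {
  # networks with exactly 3 distinct reactant complexes from the Hopf base
  base <- census_hopf_base()
  three <- Filter(function(r)
    length(unique(apply(r$reactant, 2, paste, collapse = ","))) == 3, base)
  set.seed(5)
  for (rep in three[sample(length(three), 25)]) {
    net <- rep_to_crn(rep)
    for (kap in list(c(1, 1, 1, 1), c(2, 1, 3, 1), c(1, 5, 2, 7))) {
      sol <- solve_equilibria(net, kap)
      if (!isTRUE(sol$continuum) && !isTRUE(sol$degenerate_rank))
        expect_lte(sol$nondegenerate_count, 1)
    }
  }
})
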