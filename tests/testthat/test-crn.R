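# Network representation, parsing and the mass-action field.

test_that("parsing recovers the printed stoichiometric matrix and round-trips", {
  net <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
  expect_equal(net$species, c("X", "Y"))
  expect_equal(unname(net$gamma),
               matrix(c(1, 0, -1, 1, 0, -1, 0, 1), 2))
  expect_equal(unname(net$reactant),
               matrix(c(2, 0, 1, 1, 0, 1, 0, 0), 2))
  expect_equal(net$rank, 2)
  expect_equal(serialise_network(net), "2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")

  s <- "X+Y > X; X > 0; 0 > 5X+Y; 2Y > X+4Y"
  expect_equal(serialise_network(parse_network(s)), s)
})

test_that("degenerate reactions and malformed complexes are rejected", {
  expect_error(parse_network("X > X"), "identical reactant and product")
  expect_error(parse_network("X + > Y"), "complex")
  expect_error(parse_network("X ? Y"), ">")
})

test_that("mass-action field matches direct expansion", {
  # catalog network 9: xdot = k1 x^2 + k2 xy - k3 x, ydot = -k2 xy + k4
  ma <- mass_action_rhs(parse_network("2X > 3X; X+Y > 2X; 0 > Y; X > 0"))
  # reaction order: k1 ~ 2X>3X, k2 ~ X+Y>2X, k3 ~ 0>Y, k4 ~ X>0
  expect_equal(format_mass_action(ma)[1], "-x*k4 + x*y*k2 + x^2*k1")
  expect_equal(format_mass_action(ma)[2], "k3 - x*y*k2")

  # generalised LVA with b = 2
  ma2 <- mass_action_rhs(parse_network("2X > 3X; X+Y > 2Y; Y > 0"))
  expect_equal(format_mass_action(ma2)[1], "-x*y*k2 + x^2*k1")
  expect_equal(format_mass_action(ma2)[2], "-y*k3 + x*y*k2")

  # single inflow: constant field
  ma3 <- mass_action_rhs(parse_network("0 > X"))
  expect_equal(format_mass_action(ma3)[1], "k1")
})

test_that("structural predicates follow the molecularity definitions", {
  n1 <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
  p1 <- structural_predicates(n1)
  expect_true(p1$quadratic)
  expect_true(p1$trimolecular)
  expect_false(p1$bimolecular)   # product 3X
  expect_false(p1$has_trivial_species)

  p2 <- structural_predicates(parse_network("0 > X; X > 0"))
  expect_true(p2$bimolecular)

  expect_true(has_reactant(n1, "X+Y"))
  expect_false(has_reactant(n1, "2Y"))
  expect_true(has_reaction(n1, "2X > 3X"))
  expect_false(has_reaction(n1, "2X > X"))
})

test_that("species permutation commutes with the mass-action field", {
  net <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
  sw <- crnbif:::swap_species(net)
  f <- mass_action_rhs(net)
  g <- mass_action_rhs(sw)
  # swapping species exchanges the components and the concentration variables
  swap_vars <- function(p) crnbif:::mp_subst(p, list(
    x = crnbif:::mp_var(f$vars, "y"), y = crnbif:::mp_var(f$vars, "x")))
  expect_true(crnbif:::mp_equal(swap_vars(f$field[[1]]), g$field[[2]]))
  expect_true(crnbif:::mp_equal(swap_vars(f$field[[2]]), g$field[[1]]))
})

test_that("rank is invariant under reaction reordering and species swap", {
  set.seed(42)
  for (i in 1:10) {
    rep <- random_raw_network()
    net <- crn(rep$reactant, rep$product)
    perm <- sample(4)
    net2 <- crn(rep$reactant[, perm], rep$product[, perm])
    net3 <- crn(rep$reactant[2:1, ], rep$product[2:1, ])
    expect_equal(net2$rank, net$rank)
    expect_equal(net3$rank, net$rank)
  }
})
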