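# Enumeration, structural filters and the dynamical-equivalence key.

test_that("complex enumeration has the closed-form counts", {
  expect_equal(ncol(enumerate_complexes(2, 2)), 6)   # C(4,2)
  expect_equal(ncol(enumerate_complexes(2, 3)), 10)  # C(5,2)
  expect_equal(ncol(enumerate_complexes(1, 3)), 4)
  # the six bimolecular complexes in census order
  expect_equal(unname(enumerate_complexes(2, 2)),
               matrix(c(0, 0, 1, 0, 0, 1, 2, 0, 1, 1, 0, 2), 2))
})

test_that("raw four-distinct-reactant space has 15 * 9^4 networks", {
  # brute-force oracle for the generator: 15 reactant 4-subsets, 9 products
  # (complexes of molecularity <= 3 other than the reactant) per reaction
  n_products <- ncol(enumerate_complexes(2, 3)) - 1
  expect_equal(choose(6, 4) * n_products^4, 98415)
})

test_that("dynamical nontriviality is decided exactly", {
  net <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
  expect_true(is_dynamically_nontrivial(net))
  # printed kernel witness
  expect_equal(unname(net$gamma %*% c(1, 1, 2, 1)), matrix(0, 2, 1))
  expect_false(is_dynamically_nontrivial(parse_network("0 > X")))
  # m = r forces triviality
  expect_false(is_dynamically_nontrivial(parse_network("0 > X; 0 > Y")))
})

test_that("redundant reactions are detected by positive-span membership", {
  expect_true(has_redundant_reaction(
    parse_network("2X > 3X; 2X > 4X; Y > 0; 0 > Y")))
  expect_false(has_redundant_reaction(
    parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")))
  # opposite rays on the same reactant are not redundant
  expect_false(has_redundant_reaction(
    parse_network("X+Y > 0; X+Y > 2X; 2X > 3X; Y > 0")))
})

test_that("reactant collinearity is an affine condition", {
  expect_true(reactants_collinear(
    parse_network("2X > 3X; X+Y > 2X; 2Y > X+2Y")))       # line a + b = 2
  expect_false(reactants_collinear(
    parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")))
  expect_true(reactants_collinear(
    parse_network("0 > X; X+Y > 2Y")))                     # two points
})

test_that("the equivalence key is invariant under the allowed moves", {
  set.seed(7)
  for (i in 1:25) {
    rep <- random_raw_network()
    key <- crnbif:::equivalence_key(rep$reactant, rep$gamma)
    perm <- sample(4)
    expect_equal(crnbif:::equivalence_key(rep$reactant[, perm], rep$gamma[, perm]), key)
    expect_equal(crnbif:::equivalence_key(rep$reactant[2:1, ], rep$gamma[2:1, ]), key)
  }
  # positive scaling of a reaction vector keeps the key: 0 > Y vs 0 > 2Y
  n1 <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
  n2 <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > 2Y")
  expect_equal(crnbif:::equivalence_key(n1$reactant, n1$gamma),
               crnbif:::equivalence_key(n2$reactant, n2$gamma))
})

test_that("census representatives are unique by key and pass their filters", {
  reps <- census_distinct_reactants(3)
  keys <- vapply(reps, function(r) r$key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  set.seed(3)
  for (rep in reps[sample(length(reps), 20)]) {
    net <- rep_to_crn(rep)
    expect_equal(net$rank, 2)
    expect_true(is_dynamically_nontrivial(net))
    expect_equal(length(unique(apply(rep$reactant, 2, paste, collapse = ","))), 4)
  }
})
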