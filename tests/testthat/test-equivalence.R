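# Diagonal equivalence and the natural-coordinates reduction.

test_that("diagonal equivalence finds witnesses and rejects mismatches", {
  n9 <- parse_network("2X > 3X; X+Y > 2X; 0 > Y; X > 0")
  n10 <- parse_network("2X > 3X; X+Y > 3X; 0 > Y; X > 0")
  res <- diagonally_equivalent(n9, n10)
  expect_true(res$equivalent)
  # identity witness on itself
  expect_true(diagonally_equivalent(n9, n9)$equivalent)
  # shape mismatch
  expect_false(diagonally_equivalent(
    n9, parse_network("2X > 3X; X+Y > 2Y; Y > 0"))$equivalent)
  # same shape, inequivalent networks (different reactant multiset)
  expect_false(diagonally_equivalent(
    n9, parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y"))$equivalent)
})

test_that("diagonal equivalence is symmetric and transitive on the catalog pairs", {
  cat3 <- bt_catalog()
  nets <- lapply(cat3$reactions[c(1, 2, 9, 10)], parse_network)
  expect_true(diagonally_equivalent(nets[[1]], nets[[2]])$equivalent)
  expect_true(diagonally_equivalent(nets[[2]], nets[[1]])$equivalent)
  expect_false(diagonally_equivalent(nets[[1]], nets[[3]])$equivalent)
  # class counting on this small set: {1,2} and {9,10}
  expect_equal(count_diagonal_classes(nets), 2L)
})

test_that("natural coordinates reproduce the printed worked example", {
  net <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
  nc <- natural_coordinates(net, U = c(2, 2, 1, 1))
  expect_equal(nc$Gbar_den, 1)
  expect_equal(unname(nc$Gbar_num), matrix(c(
    1, 0, 1, -1,
    -1, 0, -2, 2,
    1, 1, 2, -2,
    -1, -1, 0, 1), 4))
  expect_true(nc$identity_ok)
  # W spans the left kernel of [A|1] and W U = 1
  A1 <- cbind(net$A, 1)
  expect_equal(unname(nc$W %*% A1), matrix(0, 1, 3))
  expect_equal(unname(nc$W %*% nc$U), matrix(nc$Gbar_den, 1, 1))
  # reduced field is Xdot = o1 (w1^2 X^2 - w1^2 X Y),
  #                  Ydot = o2 (w1^2 X Y - w1 Y + w1)
  vars <- nc$vars
  mono <- function(ex, co) crnbif:::mp_monomial(vars, ex, co)
  expX2 <- mono(c(2, 0, 1, 0, 2), 1)     # X^2 o1 w1^2
  expXY1 <- mono(c(1, 1, 1, 0, 2), -1)   # -X Y o1 w1^2
  f1_expected <- crnbif:::mp_add(expX2, expXY1)
  f2_expected <- Reduce(crnbif:::mp_add, list(
    mono(c(1, 1, 0, 1, 2), 1),           # X Y o2 w1^2
    mono(c(0, 1, 0, 1, 1), -1),          # -Y o2 w1
    mono(c(0, 0, 0, 1, 1), 1)))          # o2 w1
  expect_true(crnbif:::mp_equal(nc$reduced_field[[1]], f1_expected))
  expect_true(crnbif:::mp_equal(nc$reduced_field[[2]], f2_expected))
})

test_that("the reduced family collapses to the printed two-parameter form", {
  # After time rescaling by o1 w1^2, the reduced field of the worked example
  # becomes Xdot = X^2 - XY, Ydot = beta (gamma X Y - Y + 1) with
  # beta = o2/(o1 w1) and gamma = w1.  Verified as cleared-denominator
  # polynomial identities.
  net <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")
  nc <- natural_coordinates(net, U = c(2, 2, 1, 1))
  vars <- nc$vars
  v <- function(nm) crnbif:::mp_var(vars, nm)
  X <- v("X"); Y <- v("Y"); o1 <- v("o1"); o2 <- v("o2"); w1 <- v("w1")
  scale <- crnbif:::mp_mul(o1, crnbif:::mp_mul(w1, w1))   # o1 w1^2
  t1 <- crnbif:::mp_sub(crnbif:::mp_mul(X, X), crnbif:::mp_mul(X, Y))
  expect_true(crnbif:::mp_equal(nc$reduced_field[[1]],
                                crnbif:::mp_mul(scale, t1)))
  # o1 w1^2 * beta (gamma XY - Y + 1) = o2 w1 (w1 XY - Y + 1)
  inner <- Reduce(crnbif:::mp_add, list(
    crnbif:::mp_mul(w1, crnbif:::mp_mul(X, Y)),
    crnbif:::mp_neg(Y), crnbif:::mp_const(vars, 1)))
  rhs <- crnbif:::mp_mul(crnbif:::mp_mul(o2, w1), inner)
  expect_true(crnbif:::mp_equal(nc$reduced_field[[2]], rhs))
})

test_that("diagonally equivalent networks share all bifurcation classifications", {
  cat3 <- bt_catalog()
  for (p in bt_catalog_diagonal_pairs()) {
    a <- parse_network(cat3$reactions[p[1]])
    b <- parse_network(cat3$reactions[p[2]])
    expect_equal(classify_fold(a)$fold_feasible, classify_fold(b)$fold_feasible)
    expect_equal(classify_hopf(a)$classification, classify_hopf(b)$classification)
  }
})
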