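# Bogdanov-Takens normal forms, the vertical-BT network, and invariance of
# the classification under diagonal equivalence.

test_that("BT normal form signs on catalog networks", {
  # network 1: supercritical (sigma = -1)
  nf1 <- bt_normal_form(parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y"))
  expect_true(nf1$double_zero_feasible)
  expect_false(nf1$vertical_bt)
  expect_equal(nf1$sigma, -1L)
  expect_true(nf1$transversal)

  # network 11: subcritical (sigma = +1)
  nf11 <- bt_normal_form(parse_network("2X > 3X; X+Y > 2X; 0 > X+2Y; X > 0"))
  expect_equal(nf11$sigma, 1L)

  # networks 9 and 10: vertical BT, a20 + b11 = 0
  nf9 <- bt_normal_form(parse_network("2X > 3X; X+Y > 2X; 0 > Y; X > 0"))
  expect_true(nf9$vertical_bt)
  expect_false(nf9$b20_zero)
  nf10 <- bt_normal_form(parse_network("2X > 3X; X+Y > 3X; 0 > Y; X > 0"))
  expect_true(nf10$vertical_bt)

  # generalised LVA admits no double zero
  expect_false(bt_normal_form(parse_network("2X > 3X; X+Y > 2Y; Y > 0"))$double_zero_feasible)
})

test_that("sigma is invariant across the printed diagonally equivalent pairs", {
  cat3 <- bt_catalog()
  for (p in bt_catalog_diagonal_pairs()) {
    a <- bt_normal_form(parse_network(cat3$reactions[p[1]]))
    b <- bt_normal_form(parse_network(cat3$reactions[p[2]]))
    expect_equal(a$vertical_bt, b$vertical_bt)
    if (!a$vertical_bt) expect_equal(a$sigma, b$sigma)
  }
})

test_that("the vertical-BT network is Hamiltonian at k1 = k2 with constant Dulac divergence", {
  res <- vertical_bt_analysis()
  expect_true(res$dulac_is_constant)
  expect_true(res$hamiltonian_conserved)
  expect_equal(unname(res$equilibrium_counts), c(2, 1, 0))
})

test_that("double-zero networks coincide with the sign-change networks of the fold track", {
  ft <- fold_track(3)
  both <- ft$fold & ft$neg & ft$pos
  dz <- ft$double_zero
  expect_equal(which(both), which(dz))
  expect_equal(sum(dz), 33)
})
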