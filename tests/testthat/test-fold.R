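# Fold classification, vertical folds, rank-one patterns, origin stability.

test_that("fold classification on worked networks", {
  rec <- classify_fold(parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y"))
  expect_true(rec$fold_feasible)
  expect_true(rec$fold_nondegenerate)
  expect_false(rec$forced_double_zero)
  expect_setequal(rec$second_eigenvalue_signs, c("negative", "positive"))

  rec2 <- classify_fold(parse_network("2X > 3X; X+Y > 2Y; Y > 0"))
  expect_false(rec2$fold_feasible)
})

test_that("forced-double-zero networks extend the generalised LVA", {
  ft <- fold_track(3)
  fdz <- ft$nondeg[ft$forced_dz]
  expect_equal(length(fdz), 3)
  # two of them contain the generalised LVA reactions (b = 2 or 3)
  has_lva <- vapply(fdz, function(rep) {
    net <- rep_to_crn(rep)
    (has_reaction(net, "2X > 3X") || has_reaction(net, "2Y > 3Y")) &&
      (has_reactant(net, "X+Y"))
  }, logical(1))
  expect_gte(sum(has_lva), 2)
})

test_that("vertical fold yields a straight equilibrium line for degenerate census networks", {
  ft <- fold_track(3)
  deg <- ft$reps[!vapply(ft$reps, crnbif:::admits_nondegenerate_equilibrium_rep,
                         logical(1))]
  expect_equal(length(deg), 33)
  types <- vapply(deg, vertical_fold, character(1))
  expect_true(all(types %in% c("through-origin", "vertical", "horizontal")))
  # a network with nondegenerate equilibria is rejected
  expect_error(vertical_fold(parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")),
               "nondegenerate")
})

test_that("rank-one fold is a combinatorial pattern match", {
  expect_true(rank_one_fold(parse_network("0 > X; X > 0; 2X > 3X")))
  expect_true(rank_one_fold(parse_network("0 > 2X; X > 0; 2X > 4X")))
  expect_true(rank_one_fold(parse_network("X+Y > 0; 2X > 4X+2Y; 0 > 2X+2Y")))
  expect_true(rank_one_fold(parse_network("X+Y > 0; 2Y > 2X+4Y; X > 2X+Y")))
  # bimolecular rank-one networks never admit a fold
  expect_false(rank_one_fold(parse_network("0 > X; X > 0; 2X > X")))
  expect_false(rank_one_fold(parse_network("X+Y > 0; 0 > X+Y; X > 2X+Y")))
  expect_error(rank_one_fold(parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")),
               "rank-one")
})

test_that("origin stability follows the linearisation and the axis rule", {
  expect_equal(origin_stability(parse_network("2X > 3X; X+Y > 2X; 0 > Y; X > 0")),
               "not-equilibrium")
  expect_equal(origin_stability(parse_network("X > 0; Y > 0; 2X > 3X; X+Y > 2Y")),
               "linearly-stable")
  # zero eigenvalue resolved on the invariant x-axis (flow -2 k x^2)
  expect_equal(origin_stability(parse_network("2X > 0; Y > 2X; X+Y > 2X+2Y; 2Y > X+2Y")),
               "stable-via-center-manifold")
  expect_equal(origin_stability(parse_network("Y > 2Y; X > 0; 2X > 3X; X+Y > 0")),
               "saddle")
})

test_that("for fold networks, paired equilibria have opposite Jacobian determinant signs", {
  ft <- fold_track(3)
  fold_reps <- ft$nondeg[ft$zero_eig]
  set.seed(13)
  found_pairs <- 0
  for (rep in fold_reps[sample(length(fold_reps), 60)]) {
    net <- rep_to_crn(rep)
    # scan rational rate constants derived from cross-section points for a
    # choice with exactly two positive equilibria
    for (aa in c(1, 3, 5, 7)) {
      kap <- construct_rate_constants(net, c(1, 1), aa / 8, 1)
      den <- vapply(kap, function(k) { f <- 1; while (abs(k * f - round(k * f)) > 1e-9) f <- f * 2; f }, numeric(1))
      sol <- try(solve_equilibria(net, kap), silent = TRUE)
      if (inherits(sol, "try-error") || isTRUE(sol$continuum)) next
      if (identical(sol$count, 2L) && sol$nondegenerate_count == 2) {
        expect_setequal(sol$det_signs, c(-1, 1))
        found_pairs <- found_pairs + 1
        break
      }
    }
  }
  expect_gte(found_pairs, 10)
})
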