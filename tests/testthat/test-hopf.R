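# Hopf variety, focal values and the Andronov-Hopf classification.

net1 <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y")

hopf_classify_cpp_safe <- function(ctx, c1, c2) {
  out <- try(crnbif:::hopf_classify_cpp(ctx$gamma, ctx$A, c1 * ctx$r1,
                                        c2 * ctx$r2, TRUE), silent = TRUE)
  if (inherits(out, "try-error") || !isTRUE(out$feasible)) NULL else out
}


test_that("Hopf variety of network 1 is the expected cross-section interval", {
  hv <- hopf_variety(net1)
  expect_true(hv$feasible)
  expect_true(hv$open_region)
  # feasible interval is alpha in (1/2, 1) with h = alpha (1,1,1,0) + ...:
  # the rational witness must satisfy detM > 0, M11 M22 < 0 (checked inside)
  w <- hv$witness()
  expect_true(w$alpha[1] / w$alpha[2] > 0 && w$alpha[1] / w$alpha[2] < 1)
  expect_true(w$x2[1] / w$x2[2] > 0)
  # no Hopf without the mixed reactant complex
  expect_false(hopf_variety(parse_network("2X > 3X; X > 0; Y > 0; 0 > Y"))$feasible)
  # generalised LVA: empty variety
  expect_false(hopf_variety(parse_network("2X > 3X; X+Y > 2Y; Y > 0"))$feasible)
})

test_that("exact L1 agrees in sign with the independent numeric oracle", {
  ht <- hopf_track()
  set.seed(2)
  n_checked <- 0
  for (rep in ht$hopf_reps[sample(length(ht$hopf_reps), 15)]) {
    hv <- hopf_variety(rep)
    if (!hv$open_region) next
    w <- hv$witness()
    ex <- focal_values(rep, w$alpha[1], w$alpha[2])
    num <- l1_numeric_oracle(crnbif:::as_ctx(rep), w$alpha[1] / w$alpha[2])
    if (abs(num) > 1e-8) {
      expect_equal(sign(ex$value_num), sign(num))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 8)
})

test_that("the vertical-BT network has an identically vanishing focal-value chain", {
  res <- classify_hopf(parse_network("2X > 3X; X+Y > 2X; 0 > Y; X > 0"))
  expect_equal(res$classification, "vertical")
  p <- res$pieces[[1]]
  expect_true(p$l1_identically_zero)
  expect_true(p$l2_identically_zero)
  expect_true(p$l3_identically_zero)
})

test_that("the Bautin network has sign-changing L1 with L2 > 0 on its zero set", {
  # catalog network 12
  res <- classify_hopf(parse_network("2X > 3X; X+Y > 3X; 0 > X+2Y; X > 0"))
  expect_equal(res$classification, "bautin")
  expect_equal(res$l2_sign, 1L)
})

test_that("Hopf transversality holds at rational witnesses", {
  ht <- hopf_track()
  set.seed(4)
  for (rep in ht$hopf_reps[sample(length(ht$hopf_reps), 12)]) {
    res <- classify_hopf(rep, transversality = TRUE)
    expect_true(res$transversal)
  }
})

test_that("L1 sign is invariant under positive rescaling of the kernel rays", {
  # scaling both rays by positive integers reparameterises the cross-section
  # but cannot change any sign decision
  ht <- hopf_track()
  set.seed(9)
  for (rep in ht$hopf_reps[sample(length(ht$hopf_reps), 6)]) {
    ctx <- crnbif:::as_ctx(rep)
    a <- hopf_classify_cpp_safe(ctx, 1, 1)
    b <- hopf_classify_cpp_safe(ctx, 3, 2)
    if (is.null(a) || is.null(b)) next
    expect_equal(a$classification, b$classification)
  }
})


test_that("the five-reaction combustion network is supercritical at exact Hopf points", {
  # 2X>3X; X+Y>2Y; Y>0; 0>Y plus X>2X: kernel vectors h = (a, a+c, a+b+c, b, c)
  net <- parse_network("2X > 3X; X+Y > 2Y; Y > 0; 0 > Y; X > 2X")
  ctx <- list(gamma = matrix(as.integer(net$gamma), 2),
              A = matrix(as.integer(net$A), ncol = 2))
  n_checked <- 0
  for (a in 1:3) for (b in 1:3) for (c in 1:2) {
    h <- c(a, a + c, a + b + c, b, c)
    expect_equal(unname(net$gamma %*% h), matrix(0, 2, 1))
    res <- try(crnbif:::hopf_classify_cpp(ctx$gamma, ctx$A, h, h, TRUE),
               silent = TRUE)
    if (inherits(res, "try-error") || !isTRUE(res$feasible)) next
    expect_equal(res$classification, "supercritical")
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})
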