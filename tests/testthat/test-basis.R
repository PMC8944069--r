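# CRBF basis construction, evaluation and the excitation transform.

test_that("default basis geometry matches the published layout", {
  b <- crbf_basis()
  expect_equal(b$n_nodes, 10L)
  expect_equal(b$centers[1L], -0.05)
  expect_equal(b$centers[10L], 0.55)
  expect_equal(unique(round(diff(b$centers), 10)), round(0.6 / 9, 10))
  expect_equal(b$width, 2 * 0.6 / 9)
})

test_that("a single CRBF matches its closed form and compact support", {
  b <- crbf_basis()
  expect_equal(eval_crbf(0.2, 0.2, b$width, 3.7), 3.7)       # peak equals A
  expect_identical(eval_crbf(0.2 + b$width, 0.2, b$width, 5), 0)
  expect_identical(eval_crbf(0.9, 0.2, b$width, 5), 0)
  # (t - c)/w = 1/2 gives exp(-1/3)
  expect_equal(eval_crbf(b$width / 2, 0, b$width, 1), exp(-1 / 3),
               tolerance = 1e-12)
  expect_error(eval_crbf(NaN, 0, 0.1, 1), class = "musclebayes_invalid_error")
  expect_error(eval_crbf(0, 0, -0.1, 1), class = "musclebayes_invalid_error")
  expect_error(eval_crbf(0, Inf, 0.1, 1), class = "musclebayes_invalid_error")
})

test_that("sum_basis is the term-by-term sum of its bumps", {
  b <- crbf_basis()
  t <- seq(0, 0.5, by = 0.01)
  expect_equal(sum_basis(b, rep(0, 10), t), rep(0, length(t)))
  # single active node: peak A at its center, zero outside its support
  A <- rep(0, 10); A[4L] <- 2.5
  f <- sum_basis(b, A, t)
  expect_equal(f[which.min(abs(t - b$centers[4L]))], 2.5, tolerance = 1e-9)
  outside <- abs(t - b$centers[4L]) >= b$width
  expect_identical(f[outside], rep(0, sum(outside)))
  # overlapping nodes at a midpoint: oracle is the explicit two-term sum
  A2 <- rep(0, 10); A2[4L] <- 1.2; A2[5L] <- -0.7
  tm <- (b$centers[4L] + b$centers[5L]) / 2
  expect_equal(sum_basis(b, A2, tm),
               eval_crbf(tm, b$centers[4L], b$width, 1.2) +
                 eval_crbf(tm, b$centers[5L], b$width, -0.7),
               tolerance = 1e-12)
  expect_error(sum_basis(b, rep(0, 9), t),
               class = "musclebayes_shape_error")
})

test_that("stable inverse logit is exact, bounded and overflow-free", {
  expect_equal(inverse_logit_stable(0), 0.5)
  expect_equal(inverse_logit_stable(-30), exp(-30) / (1 + exp(-30)),
               tolerance = 1e-12)
  expect_equal(inverse_logit_stable(-30), 9.357623e-14, tolerance = 1e-6)
  big <- inverse_logit_stable(c(-1e4, -1000, 1000, 1e4))
  expect_true(all(is.finite(big)))
  expect_true(all(big >= 0 & big <= 1))
  expect_error(inverse_logit_stable(NaN),
               class = "musclebayes_invalid_error")
  # the two branches are exact complements over the amplitude range
  F <- seq(-30, 30, by = 0.25)
  expect_equal(inverse_logit_stable(F) + inverse_logit_stable(-F),
               rep(1, length(F)), tolerance = 1e-15)
  # round trip through the logit (above ~ +15 the information needed to
  # invert is no longer representable in the value itself)
  Fr <- seq(-30, 15, by = 0.25)
  expect_equal(stats::qlogis(inverse_logit_stable(Fr)), Fr,
               tolerance = 1e-10)
})

test_that("excitations map amplitudes through sum + inverse logit", {
  b <- crbf_basis()
  t <- seq(0, 0.5, by = 0.01)
  e0 <- excitations_from_amplitudes(b, matrix(0, 6, 10), t)
  expect_equal(e0$u, matrix(0.5, length(t), 6))
  # the -30 bound maps to effectively silent muscles everywhere
  elo <- excitations_from_amplitudes(b, matrix(-30, 6, 10), t)
  expect_true(all(elo$u <= 1e-13))
  expect_true(all(elo$u > 0))
  # flat 60-vector fills muscle-major
  A <- matrix(rnorm(60), 6, 10)
  ev <- excitations_from_amplitudes(b, as.vector(t(A)), t)
  expect_equal(ev$u, excitations_from_amplitudes(b, A, t)$u)
  expect_error(
    excitations_from_amplitudes(b, matrix(c(31, rep(0, 59)), 6, 10), t),
    class = "musclebayes_bounds_error")
})

test_that("perturbing one amplitude only acts inside that node's support", {
  b <- crbf_basis()
  t <- seq(0, 0.5, by = 0.002)
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(runif(60, -5, 5), 6, 10)
    m <- sample(6, 1); i <- sample(10, 1)
    A2 <- A; A2[m, i] <- A2[m, i] + runif(1, 0.5, 3)
    u1 <- excitations_from_amplitudes(b, A, t)$u
    u2 <- excitations_from_amplitudes(b, A2, t)$u
    outside <- abs(t - b$centers[i]) >= b$width
    expect_identical(u1[outside, ], u2[outside, ])  # bit-identical
    # other muscles untouched everywhere
    expect_identical(u1[, -m], u2[, -m])
    # non-decreasing across the whole support, strictly increasing where
    # the bump carries representable weight
    inside <- abs(t - b$centers[i]) < b$width
    core <- abs(t - b$centers[i]) <= b$width / 2
    expect_true(all(u2[inside, m] >= u1[inside, m]))
    expect_true(all(u2[core, m] > u1[core, m]))
  }
})
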