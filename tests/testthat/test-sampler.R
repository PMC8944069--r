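# DRAM sampler: proposal mechanics, acceptance rules, bookkeeping and
# stationary behavior on known targets.

test_that("initial proposals are uniform in [-15,-5] and near-silent", {
  cfg <- sampler_config(seed = 4)
  set.seed(1)
  x <- initial_proposal(60, cfg)
  expect_true(all(x >= -15 & x <= -5))
  set.seed(1)
  expect_identical(initial_proposal(60, cfg), x)
  u <- excitations_from_amplitudes(crbf_basis(), x, seq(0, 0.5, 0.01))
  expect_true(all(u$u < 0.01))
})

test_that("Metropolis rule accepts uphill always, downhill by the ratio", {
  for (i in 1:20) expect_true(mh_accept(-1, -2))
  expect_true(mh_accept(0, -Inf))
  set.seed(2)
  p80 <- mean(replicate(1e5, mh_accept(log(0.8), 0)))
  p10 <- mean(replicate(1e5, mh_accept(log(0.1), 0)))
  expect_equal(p80, 0.8, tolerance = 0.025)
  expect_equal(p10, 0.1, tolerance = 0.2)   # relative; +/- 2% absolute
  expect_lt(abs(p10 - 0.1), 0.02)
})

test_that("covariance adaptation scales history with a stabilizing ridge", {
  cfg <- sampler_config()
  const <- matrix(5, 50, 3)
  sc <- 2.4^2 / 3
  expect_equal(adapt_covariance(const, cfg), sc * cfg$am_epsilon * diag(3))
  set.seed(8)
  h <- matrix(rnorm(2e4), 1e4, 2)
  C <- adapt_covariance(h, cfg)
  expect_equal(C, t(C))
  expect_true(all(eigen(C, symmetric = TRUE)$values > 0))
  expect_equal(diag(C), rep(2.4^2 / 2, 2), tolerance = 0.05)
  expect_lt(max(abs(C[1, 2])), 0.1)
})

test_that("second-stage acceptance matches the delayed-rejection ratio", {
  # independent oracle: the textbook two-stage ratio written out with dnorm
  oracle <- function(x, y1, y2, sd1) {
    a1 <- function(from, to) min(1, exp(lp(to) - lp(from)))
    num <- exp(lp(y2)) * dnorm(y1, y2, sd1) * (1 - a1(y2, y1))
    den <- exp(lp(x)) * dnorm(y1, x, sd1) * (1 - a1(x, y1))
    min(1, num / den)
  }
  lp <- function(z) dnorm(z, 0, 1, log = TRUE)
  set.seed(14)
  for (i in 1:50) {
    x <- rnorm(1); sd1 <- runif(1, 0.5, 2)
    y1 <- x + rnorm(1, 0, sd1)
    y2 <- x + 0.2 * rnorm(1, 0, sd1)
    if (lp(y1) >= lp(x)) next  # stage 2 only runs after a rejection
    R1 <- matrix(sd1, 1, 1)
    la2 <- musclebayes:::dr_log_accept2(
      lp(x), lp(y1), lp(y2),
      -0.5 * ((y1 - y2) / sd1)^2, -0.5 * ((y1 - x) / sd1)^2)
    expect_equal(exp(la2), oracle(x, y1, y2, sd1), tolerance = 1e-12)
  }
  # proposing the current point back is always accepted
  expect_equal(musclebayes:::dr_log_accept2(-1, -5, -1, -0.3, -0.3), 0)
  # zero-density second stage can never be accepted
  expect_identical(musclebayes:::dr_log_accept2(-1, -5, -Inf, -0.3, -0.3),
                   -Inf)
})

test_that("chains are reproducible and account for every iteration", {
  lp <- function(x) -0.5 * sum(x^2)
  cfg <- sampler_config(n_iter = 2000L, n_chains = 2L, seed = 42)
  ch1 <- run_chain(lp, 2, cfg, chain_id = 1)
  ch2 <- run_chain(lp, 2, cfg, chain_id = 1)
  expect_identical(ch1$samples, ch2$samples)
  # stage accounting: accepts at both stages plus rejections cover n - 1
  n_rej <- sum(!ch1$accepted[-1L])
  expect_equal(ch1$n_accept_stage1 + ch1$n_accept_stage2 + n_rej,
               cfg$n_iter - 1L)
  expect_equal(sum(ch1$stage[-1L] == 1L), ch1$n_accept_stage1)
  expect_equal(sum(ch1$stage[-1L] == 2L), ch1$n_accept_stage2)
  # every rejection copies the previous sample exactly
  rej <- which(!ch1$accepted)
  for (i in rej) expect_identical(ch1$samples[i, ], ch1$samples[i - 1L, ])
})

test_that("an all-rejecting target leaves the chain at its start", {
  x0 <- c(0.3, -0.4)
  lp <- function(x) if (isTRUE(all.equal(x, x0, tolerance = 1e-12))) 0 else -Inf
  cfg <- sampler_config(n_iter = 500L, seed = 7)
  ch <- run_chain(lp, 2, cfg, init = x0)
  expect_true(all(ch$samples[, 1] == x0[1] & ch$samples[, 2] == x0[2]))
  expect_equal(ch$acc_rate, 0)
})

test_that("the sampler reproduces a 1-D standard normal target", {
  lp <- function(x) -0.5 * x^2
  cfg <- sampler_config(n_iter = 20000L, seed = 11, init_low = -2,
                        init_high = 2)
  ch <- run_chain(lp, 1, cfg)
  draws <- ch$samples[seq(10001, 20000, by = 50), 1]
  ks <- suppressWarnings(stats::ks.test(draws, pnorm))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(ch$samples[10001:20000, 1]), 0, tolerance = 0.15)
  expect_equal(sd(ch$samples[10001:20000, 1]), 1, tolerance = 0.15)
})

test_that("ensembles give distinct starts, identical reruns, stable order", {
  lp <- function(x) -0.5 * sum(x^2)
  cfg <- sampler_config(n_iter = 300L, n_chains = 3L, seed = 5)
  ens <- run_chains(lp, 2, cfg)
  expect_length(ens, 3L)
  starts <- t(sapply(ens, function(ch) ch$samples[1L, ]))
  expect_equal(nrow(unique(starts)), 3L)
  ens2 <- run_chains(lp, 2, cfg)
  for (k in 1:3) expect_identical(ens[[k]]$samples, ens2[[k]]$samples)
  solo <- run_chain(lp, 2, cfg, chain_id = 1)
  expect_identical(ens[[1L]]$samples, solo$samples)
})

test_that("a failing chain surfaces the error with partial results", {
  n_calls <- 0
  lp <- function(x) {
    n_calls <<- n_calls + 1
    if (n_calls > 150) stop("boom")
    -0.5 * sum(x^2)
  }
  cfg <- sampler_config(n_iter = 100L, n_chains = 3L, seed = 9)
  expect_error(run_chains(lp, 2, cfg), class = "musclebayes_chain_error")
})
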