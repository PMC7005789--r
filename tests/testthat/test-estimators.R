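test_that("exponential averaging handles degenerate and Gaussian work", {
  expect_equal(exp_estimator(rep(0, 5)), 0)
  expect_equal(exp_estimator(2.5), 2.5) # single sample is the identity
  expect_error(exp_estimator(numeric(0)), class = "fepddg_input_error")
  # Gaussian work w ~ N(mu, sigma^2): Delta f = mu - sigma^2/2 = 0 here
  set.seed(101)
  w <- rnorm(1e5, mean = 1, sd = sqrt(2))
  expect_lt(abs(exp_estimator(w)), 0.05)
})

test_that("BAR solves the two-state problem and matches the analytic answer", {
  d <- make_harmonic_dataset(c(1, 4), n_per_state = 2000, seed = 42)
  wp <- work_pair(d$rps)
  b <- bar_estimate(wp$fwd, wp$rev)
  expect_true(b$converged)
  expect_lt(abs(b$delta_f - log(2)), 3 * b$stderr)
  expect_gt(b$stderr, 0)
  # trivial symmetric case
  expect_equal(bar_estimate(rep(0, 10), rep(0, 10))$delta_f, 0,
               tolerance = 1e-9)
  expect_error(bar_estimate(numeric(0), 1), class = "fepddg_input_error")
})

test_that("MBAR recovers analytic harmonic free energies within 3 SE", {
  # 2 states, spring constants 1 and 4: Delta f = 0.5 ln 4 = ln 2
  d <- make_harmonic_dataset(c(1, 4), n_per_state = 2000, seed = 42)
  est <- mbar_solve(d$rps)
  expect_true(est$converged)
  expect_equal(est$f_k[1], 0)
  expect_lt(abs(est$delta_f - log(2)), 3 * est$stderr_delta_f)
  # 8-state evenly interpolated path, end-to-end against analytic + BAR chain
  springs <- exp(seq(0, log(16), length.out = 8))
  d8 <- make_harmonic_dataset(springs, n_per_state = 400, seed = 7)
  est8 <- mbar_solve(d8$rps)
  expect_true(est8$converged)
  expect_lt(abs(est8$delta_f - d8$analytic_f[8]), 3 * est8$stderr_delta_f)
  bar_sum <- 0
  bar_var <- 0
  for (k in 1:7) {
    rows_f <- d8$rps$origin == k
    rows_r <- d8$rps$origin == k + 1
    b <- bar_estimate(d8$rps$u[rows_f, k + 1] - d8$rps$u[rows_f, k],
                      d8$rps$u[rows_r, k] - d8$rps$u[rows_r, k + 1])
    bar_sum <- bar_sum + b$delta_f
    bar_var <- bar_var + b$stderr^2
  }
  joint <- sqrt(bar_var + est8$stderr_delta_f^2)
  expect_lt(abs(bar_sum - est8$delta_f), 3 * joint)
})

test_that("identically sampled states give Delta f = 0", {
  set.seed(3)
  x <- rnorm(400)
  u <- cbind(x^2 / 2, x^2 / 2)
  rps <- reduced_potential_set(u, rep(1:2, each = 200))
  est <- mbar_solve(rps)
  expect_equal(est$delta_f, 0, tolerance = 1e-10)
})

test_that("MBAR(K=2) equals BAR on identical samples to solver tolerance", {
  tol <- 1e-8
  for (seed in 1:20) {
    d <- make_harmonic_dataset(c(1, 2.5), n_per_state = 200, seed = seed)
    est <- mbar_solve(d$rps, tolerance = tol)
    wp <- work_pair(d$rps)
    b <- bar_estimate(wp$fwd, wp$rev)
    expect_lt(abs(est$delta_f - b$delta_f), 10 * tol)
  }
})

test_that("MBAR is invariant under per-column shifts of u", {
  d <- make_harmonic_dataset(c(1, 2, 4), n_per_state = 300, seed = 13)
  est <- mbar_solve(d$rps)
  shift <- 2.75
  u2 <- d$rps$u
  u2[, 2] <- u2[, 2] + shift
  rps2 <- reduced_potential_set(u2, d$rps$origin, times = d$rps$times)
  est2 <- mbar_solve(rps2)
  expect_equal(est2$f_k[2], est$f_k[2] + shift, tolerance = 1e-7)
  expect_equal(est2$f_k[3], est$f_k[3], tolerance = 1e-7)
})

test_that("MBAR estimates unsampled states and errors when under-determined", {
  # state 2 has no samples of its own but is cross-evaluated everywhere
  d <- make_harmonic_dataset(c(1, 2, 4), n_per_state = 500, seed = 21)
  keep <- d$rps$origin != 2L
  rps <- reduced_potential_set(d$rps$u[keep, ], d$rps$origin[keep],
                               times = d$rps$times[keep])
  est <- mbar_solve(rps)
  expect_true(est$converged)
  expect_lt(abs(est$f_k[2] - d$analytic_f[2]), 3 * est$stderr[1, 2] + 0.05)
  # only one state sampled -> under-determined
  only1 <- d$rps$origin == 1L
  rps1 <- reduced_potential_set(d$rps$u[only1, ], d$rps$origin[only1])
  expect_error(mbar_solve(rps1), class = "fepddg_underdetermined_error")
  # NaN/non-finite input refused at construction
  expect_error(reduced_potential_set(matrix(c(1, NaN, 0, 1), 2, 2), c(1, 2)),
               class = "fepddg_input_error")
})

test_that("non-convergence is reported as a flag, never an exception", {
  d <- make_harmonic_dataset(c(1, 4), n_per_state = 100, seed = 5)
  est <- expect_no_error(mbar_solve(d$rps, tolerance = 1e-15, max_iter = 2L))
  expect_false(est$converged)
  expect_equal(est$n_iterations, 2L)
  expect_true(is.finite(est$delta_f))
})

test_that("bias of Delta f shrinks as sampling grows", {
  err_at <- function(n) {
    mean(vapply(1:5, function(s) {
      d <- make_harmonic_dataset(c(1, 4), n_per_state = n, seed = 100 + s)
      abs(mbar_solve(d$rps)$delta_f - log(2))
    }, numeric(1)))
  }
  expect_lt(err_at(2000), err_at(100))
})

test_that("reported SE tracks the empirical spread across replications", {
  res <- vapply(1:50, function(s) {
    d <- make_harmonic_dataset(c(1, 4), n_per_state = 200, seed = 1000 + s)
    est <- mbar_solve(d$rps)
    c(est$delta_f, est$stderr_delta_f)
  }, numeric(2))
  emp_sd <- sd(res[1, ])
  mean_se <- mean(res[2, ])
  expect_gt(mean_se, emp_sd / 2)
  expect_lt(mean_se, emp_sd * 2)
})

test_that("statistical inefficiency and subsampling behave as expected", {
  set.seed(8)
  white <- rnorm(1e4)
  g <- statistical_inefficiency(white)
  expect_gte(g, 1)
  expect_lte(g, 1.2)
  # block-replicated series: every value repeated 10x -> g ~ 10
  blocks <- rep(rnorm(100), each = 10)
  gb <- statistical_inefficiency(blocks)
  expect_lt(abs(gb - 10) / 10, 0.2)
  expect_equal(statistical_inefficiency(rep(1, 50)), 1) # constant convention
  d <- make_harmonic_dataset(c(1, 4), n_per_state = 100, seed = 2)
  expect_identical(subsample(d$rps, 1), d$rps)
  thin <- subsample(d$rps, 2.5)
  expect_equal(thin$N_k, c(34, 34)) # every 3rd of 100 per state
})
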