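test_that("overlap matrix rows sum to one and identical states share weight", {
  # all states identical with equal N: O[i, j] = N_j / sum(N)
  set.seed(4)
  x <- rnorm(300)
  u <- cbind(x^2 / 2, x^2 / 2, x^2 / 2)
  rps <- reduced_potential_set(u, rep(1:3, each = 100))
  est <- mbar_solve(rps)
  ov <- overlap_matrix(rps, est)
  expect_equal(max(abs(rowSums(ov$O) - 1)), 0, tolerance = 1e-10)
  expect_equal(ov$O, matrix(1 / 3, 3, 3), tolerance = 1e-6)
  expect_true(all(ov$O >= 0 & ov$O <= 1))
  # a generic non-uniform dataset still has exact row sums
  d <- make_harmonic_dataset(c(1, 3, 9), n_per_state = c(100, 200, 150),
                             seed = 6)
  ov2 <- overlap_matrix(d$rps, mbar_solve(d$rps))
  expect_equal(max(abs(rowSums(ov2$O) - 1)), 0, tolerance = 1e-10)
})

test_that("far-separated states fail the 0.03 neighbor-overlap criterion", {
  d <- make_harmonic_dataset(c(1, 1), centers = c(0, 100),
                             n_per_state = 200, seed = 12)
  est <- mbar_solve(d$rps)
  ov <- overlap_matrix(d$rps, est)
  expect_lt(ov$min_neighbor_overlap, 0.03)
  expect_false(ov$passes_criterion)
})

test_that("overlap diagnostic is refused for a non-converged estimate", {
  d <- make_harmonic_dataset(c(1, 4), n_per_state = 100, seed = 5)
  bad <- mbar_solve(d$rps, tolerance = 1e-15, max_iter = 2L)
  expect_error(overlap_matrix(d$rps, bad), class = "fepddg_convergence_error")
})

test_that("overlap is reversal-invariant and weakly decreases with fewer states", {
  path_overlap <- function(K) {
    d <- make_harmonic_dataset(rep(1, K), centers = seq(0, 30, length.out = K),
                               n_per_state = 100, seed = 31)
    overlap_matrix(d$rps, mbar_solve(d$rps))
  }
  ov27 <- path_overlap(27)
  ov14 <- path_overlap(14)
  ov8 <- path_overlap(8)
  expect_lte(ov8$min_neighbor_overlap, ov14$min_neighbor_overlap)
  expect_lte(ov14$min_neighbor_overlap, ov27$min_neighbor_overlap)
  # reversing the lambda ordering permutes/transposes O, min is invariant
  d <- make_harmonic_dataset(c(1, 2, 4, 8), n_per_state = 150, seed = 17)
  ov <- overlap_matrix(d$rps, mbar_solve(d$rps))
  K <- 4
  rev_rps <- reduced_potential_set(d$rps$u[, K:1], (K + 1L) - d$rps$origin,
                                   times = d$rps$times)
  ov_rev <- overlap_matrix(rev_rps, mbar_solve(rev_rps))
  expect_equal(ov_rev$O, t(ov$O)[K:1, K:1], tolerance = 1e-8)
  expect_equal(ov_rev$min_neighbor_overlap, ov$min_neighbor_overlap,
               tolerance = 1e-8)
})

test_that("equilibration discard keeps exactly the samples at or after the cut", {
  # 3-ns series at 10-ps spacing: 300 rows, discard 2 ns -> 100 remain
  d <- make_harmonic_dataset(c(1, 4), n_per_state = 300, seed = 9)
  expect_identical(discard_equilibration(d$rps, 0), d$rps)
  cut <- discard_equilibration(d$rps, 2)
  expect_equal(nrow(cut$u), 200) # 100 per state
  expect_true(all(cut$times >= 2000))
  expect_equal(sum(d$rps$times >= 2000 & d$rps$origin == 1L), 100)
  # idempotence: discard(discard(x, a), b) = discard(x, max(a, b))
  a <- discard_equilibration(discard_equilibration(d$rps, 0.5), 2)
  expect_equal(a$u, cut$u)
  expect_error(discard_equilibration(d$rps, 10), class = "fepddg_input_error")
})

test_that("convergence series is stable for stationary data and ends at the full estimate", {
  d <- make_harmonic_dataset(c(1, 4), n_per_state = 300, seed = 19)
  conv <- convergence_series(d$rps, n_windows = 5, discard_ns = 0.5)
  expect_true(all(diff(conv$series$window_end_ns) > 0))
  # every window within 3 SE of the analytic value
  analytic_kcal <- kT_to_kcal(log(2))
  expect_true(all(abs(conv$series$delta_G_kcal - analytic_kcal) <=
                    3 * conv$series$stderr_kcal))
  full <- mbar_solve(discard_equilibration(d$rps, 0.5))
  n <- nrow(conv$series)
  expect_identical(conv$series$delta_G_kcal[n], full$delta_G_kcal)
  expect_identical(conv$series$stderr_kcal[n], full$stderr_delta_G_kcal)
})
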