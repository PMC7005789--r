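test_that("replicate aggregation computes mean and sample SD with exclusions", {
  leg <- aggregate_leg(c(-10, -10, -10), "mutation_free")
  expect_equal(leg$mean_dG, -10)
  expect_equal(leg$sigma, 0)
  leg2 <- aggregate_leg(c(1, 2, 3), "mutation_bound")
  expect_equal(leg2$mean_dG, 2)
  expect_equal(leg2$sigma, 1) # sample (n-1) convention
  # six replicates, one non-converged: five used, exclusion recorded
  ests <- c(lapply(c(-8.1, -7.9, -8.0, -8.2, -7.8), fake_estimate),
            list(fake_estimate(-3.0, converged = FALSE)))
  leg6 <- aggregate_leg(ests, "bind_mut")
  expect_equal(leg6$n_replicates_used, 5)
  expect_equal(nrow(leg6$excluded_replicates), 1)
  expect_equal(leg6$excluded_replicates$index, 6)
  expect_equal(leg6$mean_dG, -8.0)
  expect_error(aggregate_leg(ests, "bind_mut", policy = "strict"),
               class = "fepddg_convergence_error")
  expect_error(aggregate_leg(list(fake_estimate(1, FALSE)), "bind_wt"),
               class = "fepddg_convergence_error")
})

test_that("mutation-cycle assembly differences legs and adds errors in quadrature", {
  free <- aggregate_leg(c(-5, -2, 1), "mutation_free") # sd = 3
  bound <- aggregate_leg(c(-6, -2, 2), "mutation_bound") # sd = 4
  dd <- ddg_mutation(free, bound, system = "sys", mutation = "X1Y")
  expect_equal(dd$ddG, bound$mean_dG - free$mean_dG)
  expect_equal(dd$sigma, 5) # sqrt(3^2 + 4^2)
  expect_gte(dd$sigma, max(free$sigma, bound$sigma))
  # identical legs close the cycle
  same <- aggregate_leg(c(1, 2, 3), "mutation_free")
  same2 <- aggregate_leg(c(1, 2, 3), "mutation_bound")
  expect_equal(ddg_mutation(same, same2)$ddG, 0)
  # leg-label mismatch is an error
  expect_error(ddg_mutation(bound, free), class = "fepddg_input_error")
})

test_that("annihilation-cycle sigma follows the mutant-leg-only convention", {
  wt <- aggregate_leg(c(-10, -8, -12), "bind_wt") # spread 2
  mut <- aggregate_leg(c(-7, -7, -7), "bind_mut") # spread 0
  dd <- ddg_annihilation(wt, mut)
  expect_equal(dd$sigma, 0) # wild-type spread ignored by convention
  expect_equal(dd$ddG, mut$mean_dG - wt$mean_dG)
  dd_full <- ddg_annihilation(wt, mut, full_error_propagation = TRUE)
  expect_equal(dd_full$sigma, wt$sigma)
  expect_equal(ddg_annihilation(wt, aggregate_leg(c(-10, -8, -12), "bind_mut"))$ddG, 0)
})

test_that("swapping leg roles negates the assembled ddG", {
  a <- c(-3.2, -2.8, -3.0)
  b <- c(-1.1, -0.9, -1.0)
  fwd <- ddg_mutation(aggregate_leg(a, "mutation_free"),
                      aggregate_leg(b, "mutation_bound"))
  rev <- ddg_mutation(aggregate_leg(b, "mutation_free"),
                      aggregate_leg(a, "mutation_bound"))
  expect_equal(fwd$ddG, -rev$ddG)
  expect_equal(fwd$sigma, rev$sigma)
})

test_that("planted-truth cycles are recovered through the full pipeline", {
  sc <- make_cycle_scenario(-2.0, -0.5, seed = 5)
  l1 <- aggregate_leg(lapply(sc$leg1, mbar_solve), "mutation_free")
  l2 <- aggregate_leg(lapply(sc$leg2, mbar_solve), "mutation_bound")
  dd <- ddg_mutation(l1, l2)
  expect_equal(sc$truth$ddG_kcal, 1.5)
  expect_lt(abs(dd$ddG - 1.5), 3 * dd$sigma)
  # a mutation that changes nothing closes the cycle within uncertainty
  sc0 <- make_cycle_scenario(-1.0, -1.0, seed = 23)
  d0 <- ddg_mutation(aggregate_leg(lapply(sc0$leg1, mbar_solve), "mutation_free"),
                     aggregate_leg(lapply(sc0$leg2, mbar_solve), "mutation_bound"))
  expect_lt(abs(d0$ddG), 3 * max(d0$sigma, 0.05))
  # annihilation assembly of the same planted truth, mutant-leg SD error
  sca <- make_cycle_scenario(-2.0, -0.5, cycle = "annihilation", seed = 29)
  lw <- aggregate_leg(lapply(sca$leg1, mbar_solve), "bind_wt")
  lm <- aggregate_leg(lapply(sca$leg2, mbar_solve), "bind_mut")
  dda <- ddg_annihilation(lw, lm)
  expect_equal(dda$sigma, lm$sigma)
  expect_lt(abs(dda$ddG - 1.5), 3 * max(dda$sigma, 0.05))
})

test_that("annihilation sub-legs compose per replicate or against a shared solvent", {
  cx <- c(-12, -11, -13)
  sv <- c(-4, -3, -5)
  expect_equal(combine_sublegs(cx, sv), cx - sv)
  expect_equal(combine_sublegs(cx, sv, shared_solvent = TRUE), cx - mean(sv))
  expect_error(combine_sublegs(cx, sv[1:2]), class = "fepddg_input_error")
})
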