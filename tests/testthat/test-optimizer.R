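test_that("two-step chain optimum matches the closed-form allocation", {
  m <- chain_model()  # k1 = 10, Km_S = 1, k2 = 1, Km_A = 0.5, single pool
  res <- optimize_growth(m, c(S = 1))
  # f_T = 1/2 at S = 1; optimal A sits at the concentration ceiling
  k1fT <- 10 * 0.5
  f2 <- 1e3 / (1e3 + 0.5)
  expect_equal(res$objective, k1fT * f2 / (k1fT + f2), tolerance = 1e-6)
  # enzymes split so both steps carry the same flux
  e <- res$enzyme_profile
  expect_equal(e[["uptake"]] * 10 * 0.5, e[["growth"]] * 1 * f2, tolerance = 1e-6)
  expect_equal(sum(e), 1, tolerance = 1e-9)
  expect_equal(res$active_constraints, "total")
  # enzyme profile reproduces the optimal fluxes through the rate law
  v_up <- reaction_rate(m$kinetics$uptake, e[["uptake"]], res$x_state)
  expect_equal(v_up, res$objective, tolerance = 1e-9)
})

test_that("a uniform pool shrink rescales the optimum exactly", {
  m <- chain_model()
  base <- optimize_growth(m, c(S = 1))
  for (gamma in c(0.9, 0.5, 0.2)) {
    shrunk <- optimize_growth(perturb_pool_bounds(m, gamma), c(S = 1))
    expect_equal(shrunk$objective, gamma * base$objective, tolerance = 1e-9)
    expect_equal(shrunk$x_internal, base$x_internal, tolerance = 1e-6)
  }
})

test_that("optimization rejects models without usable objective EFMs", {
  # cost-free objective route: objective unbounded
  net <- chain_network()
  kin <- list(uptake = reaction_kinetics(1), growth = reaction_kinetics(1))
  w <- matrix(c(1, 0), 1, 2)  # growth enzyme in no pool; uptake pooled
  m <- kinetic_model(net, kin, constraint_set(w, 1))
  expect_s3_class(optimize_growth(m, c(S = 1)), "optimization_result")  # uptake still costs
  # no external concentration supplied
  m2 <- chain_model()
  expect_error(optimize_growth(m2, c()), "external")
})

test_that("steady-state integration matches the analytic chain fixed point", {
  m <- chain_model()
  # e1 k1 f_T = 0.5; e2 k2 = 0.9: x_A solves 0.5 = 0.9 x/(0.5 + x) -> 0.625
  ss <- steady_state_for_enzymes(m, c(0.1, 0.9), c(S = 1))
  expect_true(ss$converged)
  expect_false(ss$diverged)
  expect_equal(unname(ss$state["A"]), 0.625, tolerance = 1e-6)
  expect_equal(unname(ss$fluxes[1]), unname(ss$fluxes[2]), tolerance = 1e-6)
  # demand exceeding capacity: no finite fixed point
  ss2 <- steady_state_for_enzymes(m, c(0.3, 0.8), c(S = 1))
  expect_false(ss2$converged)
  # zero enzymes: immediately steady with zero fluxes
  ss0 <- steady_state_for_enzymes(m, c(0, 0), c(S = 1))
  expect_true(ss0$converged)
  expect_equal(max(abs(ss0$fluxes)), 0)
  expect_error(steady_state_for_enzymes(m, c(-1, 1), c(S = 1)), "nonnegative")
})

test_that("brute-force search approaches the chain optimum from below", {
  m <- chain_model()
  res <- optimize_growth(m, c(S = 1))
  bf <- brute_force_optimize(m, c(S = 1), list(seed = 1))
  expect_lt(abs(res$objective - bf$objective) / res$objective, 0.02)
  expect_lte(bf$objective, res$objective * (1 + 1e-3))
  # single-EFM optimum: allocation proportional to the EFM's enzyme demands
  dem <- enzyme_demand(objective_efms(m)[[1]], res$x_state, m)
  expect_equal(bf$enzyme_profile / sum(bf$enzyme_profile),
               dem / sum(dem), tolerance = 0.05)
})

test_that("active-set analysis counts weights, tight pools and equivalence", {
  m <- build_overflow_model()
  post <- optimize_growth(m, c(glc_ext = 5), options = list(n_starts = 4))
  sets <- analyze_active_sets(post)
  expect_equal(sets$n_active_efms, 2L)
  expect_equal(sets$n_active_constraints, 2L)
  expect_equal(sets$n_nonequivalent_efms, 2L)
  v <- verify_extremum_principle(post)
  expect_true(v$ok)

  pre <- optimize_growth(m, c(glc_ext = 0.5), options = list(n_starts = 4))
  sets_pre <- analyze_active_sets(pre)
  expect_equal(sets_pre$n_active_efms, 1L)
  expect_equal(sets_pre$active_constraints, "membrane")
  expect_true(verify_extremum_principle(pre)$ok)
})

test_that("equivalent active EFMs collapse to one in the principle's count", {
  # both diamond routes identical and only the shared drain pooled: the
  # optimum may use both routes, but they count as one strategy
  net <- diamond_network()
  kin <- list(route1 = reaction_kinetics(2), route2 = reaction_kinetics(2),
              growth = reaction_kinetics(1, saturation_spec("michaelis_menten", "A", c(A = 1))))
  m <- kinetic_model(net, kin,
                     constraint_set(matrix(c(1, 1, 1), 1, 3), 1))
  res <- optimize_growth(m, c(S = 1))
  sets <- analyze_active_sets(res)
  expect_lte(sets$n_nonequivalent_efms, sets$n_active_constraints)
  expect_true(verify_extremum_principle(res)$ok)
})

test_that("objective is monotone in pool bounds and substrate availability", {
  m <- build_overflow_model()
  lo <- optimize_growth(m, c(glc_ext = 1), options = list(n_starts = 4))
  hi <- optimize_growth(m, c(glc_ext = 4), options = list(n_starts = 4))
  expect_gt(hi$objective, lo$objective)
  bigger <- perturb_pool_bounds(m, c(1.5, 1))
  expect_gt(optimize_growth(bigger, c(glc_ext = 1), options = list(n_starts = 4))$objective,
            lo$objective * (1 - 1e-8))
})
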