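test_that("overflow model has the documented structure", {
  m <- build_overflow_model()
  efms <- objective_efms(m)
  expect_length(efms, 2L)
  expect_equal(unname(m$constraints$bounds["membrane"]), 0.3)
  expect_equal(unname(m$constraints$bounds["cytosol"]), 1)
  # respiration route: one uptake per unit biomass; overflow route: two
  uptake <- vapply(efms, function(e) e$values[["transport"]], numeric(1))
  expect_equal(sort(uptake), c(1, 2))
})

test_that("overflow sweep reproduces the respirofermentative switch", {
  m <- build_overflow_model()
  grid <- c(0.5, 1, 1.5, 2.5, 4, 6, 9)
  sw <- sweep_external_substrate(m, grid, options = list(n_starts = 4))
  expect_s3_class(sw, "sweep_table")
  expect_equal(nrow(sw), length(grid))
  # growth nondecreasing along the grid
  expect_true(all(diff(sw$mu) > -1e-9))
  crit <- detect_critical_point(sw)
  expect_false(is.null(crit))
  below <- sw$substrate < crit
  above <- sw$substrate >= crit
  # below: pure respiration, membrane-limited
  expect_true(all(sw$lambda_efm2[below] <= 1e-6 * sw$lambda_efm1[below]))
  expect_true(all(sw$active_constraints[below] == "membrane"))
  # above: both EFMs and both pools active, respiration declining
  expect_true(all(sw$lambda_efm2[above] > 0))
  expect_true(all(grepl("cytosol", sw$active_constraints[above]) &
                    grepl("membrane", sw$active_constraints[above])))
  resp_above <- sw$lambda_efm1[above]
  expect_true(all(diff(resp_above) < 0))
  # overflow (acetate-producing) uptake grows with substrate
  expect_true(all(diff(sw$uptake_efm2[above]) > 0))
})

test_that("the respiration cost vector crosses the diagonal at the switch", {
  m <- build_overflow_model()
  efms <- objective_efms(m)
  # states as optimized at a low and a high substrate level
  low <- optimize_growth(m, c(glc_ext = 0.5), options = list(n_starts = 4))
  high <- optimize_growth(m, c(glc_ext = 6), options = list(n_starts = 4))
  d_low <- compute_cost_matrix(efms, low$x_state, m)$D
  d_high <- compute_cost_matrix(efms, high$x_state, m)$D
  # pools rescaled to unit bounds: row 1 cytosol, row 2 membrane
  expect_gt(d_low["membrane", 1], d_low["cytosol", 1])    # above diagonal
  expect_lt(d_high["membrane", 1], d_high["cytosol", 1])  # below diagonal
})

test_that("critical-point detection reads the lambda columns", {
  tab <- data.frame(substrate = 1:6, mu = 1:6,
                    lambda_efm1 = c(1, 1, 1, 1, 1, 1),
                    lambda_efm2 = c(0, 0, 0, 0, 0.2, 0.5))
  expect_equal(detect_critical_point(tab), 5)
  tab$lambda_efm2 <- 0
  expect_null(detect_critical_point(tab))
  expect_error(detect_critical_point(data.frame(substrate = 1)), "lambda_")
})

test_that("lactis sweep crosses fermentation modes at near-constant enzymes", {
  m <- build_lactis_model()
  grid <- c(0.5, 1, 2, 4, 8, 16)
  sw <- sweep_external_substrate(m, grid, options = list(n_starts = 6))
  frac_h <- sw$lambda_efm2 / (sw$lambda_efm1 + sw$lambda_efm2)
  expect_lt(frac_h[1], 0.5)                   # mixed-acid dominates when scarce
  expect_gt(frac_h[length(frac_h)], 0.5)      # homolactic dominates when rich
  expect_true(all(diff(frac_h) > 0))
  # both pathways expressed at every point (a genuine mixture, not a jump)
  expect_true(all(sw$lambda_efm1 > 0) && all(sw$lambda_efm2 > 0))
  # enzyme concentrations move by less than 20% while the fluxes cross over
  for (col in c("e_mixed_acid", "e_homolactic", "e_biomass")) {
    v <- sw[[col]]
    expect_lt((max(v) - min(v)) / max(v), 0.2)
  }
})

test_that("pool-bound perturbations rescale and reshape optima as predicted", {
  m <- build_overflow_model()
  expect_error(perturb_pool_bounds(m, c(1, 0)), "positive")
  expect_equal(perturb_pool_bounds(m, c(1, 1)), m)
  base <- optimize_growth(m, c(glc_ext = 5), options = list(n_starts = 4))
  # symmetric shrink: exact proportional decrease
  gam <- optimize_growth(perturb_pool_bounds(m, c(0.6, 0.6)), c(glc_ext = 5),
                         options = list(n_starts = 4))
  expect_equal(gam$objective, 0.6 * base$objective, tolerance = 1e-9)
  # shrinking the respiration-dominated pool (cytosol): the overflow EFM's
  # flux first rises, then falls at strong limitation
  lam2 <- vapply(c(1, 0.8, 0.6, 0.4, 0.3, 0.25, 0.2, 0.15), function(g) {
    res <- optimize_growth(perturb_pool_bounds(m, c(g, 1)), c(glc_ext = 5),
                           options = list(n_starts = 4))
    unname(res$inner$lambdas[2])
  }, numeric(1))
  peak <- which.max(lam2)
  expect_gt(peak, 1)            # initial rise
  expect_lt(peak, length(lam2)) # eventual fall
  expect_gt(lam2[peak], lam2[1])
  expect_gt(lam2[peak], lam2[length(lam2)])
})

test_that("catalytic-rate perturbations lengthen demands reciprocally", {
  m <- build_overflow_model()
  expect_equal(perturb_catalytic_rates(m, c(respiration = 1)), m)
  expect_error(perturb_catalytic_rates(m, c(nope = 0.5)), "unknown")
  expect_error(perturb_catalytic_rates(m, c(respiration = 0)), "positive")
  half <- perturb_catalytic_rates(m, c(respiration = 0.5))
  efms <- objective_efms(m)
  x <- c(glc_ext = 2, intermediate = 50, ac_ext = 1, precursor = 1)
  d0 <- enzyme_demand(efms[[1]], x, m)
  d1 <- enzyme_demand(efms[[1]], x, half)
  expect_equal(d1[["respiration"]], 2 * d0[["respiration"]])
  expect_equal(d1[["transport"]], d0[["transport"]])
  # uniform kcat scaling is equivalent to a uniform pool shrink
  fac <- 0.55
  all_scaled <- perturb_catalytic_rates(
    m, stats::setNames(rep(fac, 4), m$network$reaction_ids))
  pool_scaled <- perturb_pool_bounds(m, c(fac, fac))
  o1 <- optimize_growth(all_scaled, c(glc_ext = 5), options = list(n_starts = 4))
  o2 <- optimize_growth(pool_scaled, c(glc_ext = 5), options = list(n_starts = 4))
  expect_equal(o1$objective, o2$objective, tolerance = 1e-8)
})

test_that("proportionality diagnostic finds breakpoints only when present", {
  mu <- seq(0.1, 1, by = 0.1)
  fit0 <- fit_proportional_breakpoint(mu, 2 * mu)
  expect_equal(fit0$slope, 2)
  expect_true(is.na(fit0$critical_rate))

  mu2 <- c(seq(0.1, 0.55, by = 0.05), seq(0.65, 1, by = 0.05))
  q2 <- ifelse(mu2 <= 0.6, 2 * mu2, 1.2 + 5 * (mu2 - 0.6))
  fit2 <- fit_proportional_breakpoint(mu2, q2)
  expect_equal(fit2$critical_rate, 0.6)
  expect_equal(fit2$slope, 2, tolerance = 1e-8)
  expect_equal(fit2$slope_post, 5, tolerance = 1e-8)

  expect_error(fit_proportional_breakpoint(c(0.1, 0.2, 0.3), c(1, 2, 3)), "4")
  expect_error(fit_proportional_breakpoint(mu, -2 * mu), "nonnegative")
})

test_that("single active EFM implies constant flux ratios along the sweep", {
  m <- build_overflow_model()
  sw <- sweep_external_substrate(m, c(0.4, 0.7, 1, 1.4), options = list(n_starts = 4))
  expect_true(all(sw$lambda_efm2 <= 1e-6 * sw$lambda_efm1))
  # uptake proportional to growth below the switch
  ratio <- sw$uptake_efm1 / sw$mu
  expect_lt(max(ratio) - min(ratio), 1e-6 * max(ratio))
})
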