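test_that("cost matrix columns equal pool-rescaled enzyme demands", {
  m <- build_overflow_model()
  efms <- objective_efms(m)
  x <- c(glc_ext = 2, intermediate = 100, ac_ext = 1, precursor = 1)
  cm <- compute_cost_matrix(efms, x, m)
  expect_equal(dim(cm$D), c(2L, 2L))
  expect_true(all(cm$D >= 0))
  # independent reaction-by-reaction arithmetic for the respiration column:
  # d_cyto = V_resp / (kcat_resp f_resp); d_membrane = V_transport /
  # (kcat_transport f_transport) / 0.3
  f_tr <- 2 / (1 + 2)
  f_resp <- 100 / (0.5 + 100)
  expect_equal(cm$D["cytosol", 1], 1 / (2 * f_resp), tolerance = 1e-12)
  expect_equal(cm$D["membrane", 1], 1 / (10 * f_tr) / 0.3, tolerance = 1e-12)
  # overflow column: two units of uptake, one overflow reaction event
  expect_equal(cm$D["cytosol", 2], 1 / (6 * f_resp), tolerance = 1e-12)
  expect_equal(cm$D["membrane", 2], 2 / (10 * f_tr) / 0.3, tolerance = 1e-12)
})

test_that("halving every saturation doubles every cost entry", {
  m <- chain_model(Km_S = 1, Km_A = 1)
  efms <- objective_efms(m)
  cm_half <- compute_cost_matrix(efms, c(S = 1, A = 1), m)    # f = 0.5, 0.5
  cm_third <- compute_cost_matrix(efms, c(S = 0.5, A = 0.5), m)  # f = 1/3
  expect_equal(cm_third$D, 1.5 * cm_half$D, tolerance = 1e-12)
})

test_that("equivalence holds exactly for cost-identical EFMs and fails otherwise", {
  # diamond with identical kinetics on both routes and zero weight on them:
  # the two EFMs have equal cost vectors at every state
  net <- diamond_network()
  kin <- list(route1 = reaction_kinetics(2), route2 = reaction_kinetics(2),
              growth = reaction_kinetics(1, saturation_spec("michaelis_menten", "A", c(A = 1))))
  w0 <- matrix(c(0, 0, 1), 1, 3)  # only the shared drain is pooled
  m0 <- kinetic_model(net, kin, constraint_set(w0, 1))
  efms <- objective_efms(m0)
  expect_length(efms, 2L)
  expect_true(are_equivalent(efms[[1]], efms[[1]], m0))
  expect_true(are_equivalent(efms[[1]], efms[[2]], m0))
  # same support, different kcat on a pooled reaction: not equivalent
  kin2 <- kin
  kin2$route1 <- reaction_kinetics(4)
  m1 <- kinetic_model(net, kin2, constraint_set(matrix(c(1, 1, 1), 1, 3), 1))
  efms1 <- objective_efms(m1)
  expect_false(are_equivalent(efms1[[1]], efms1[[2]], m1))
  expect_error(are_equivalent(efms[[1]], efms[[2]], m0, x_samples = list()),
               "at least one")
})

test_that("diagonal ranking reproduces the two-constraint geometry", {
  fake_cost <- function(D) structure(list(D = D, efm_ids = colnames(D), state = NULL),
                                     class = "cost_matrix")
  # pure strategy: dot at the larger cost component
  D1 <- matrix(c(0.5, 1.0), 2, 1, dimnames = list(NULL, "efm1"))
  r1 <- rank_on_diagonal_2d(fake_cost(D1))
  expect_equal(unname(r1$dots["efm1"]), 1.0)
  expect_equal(unname(r1$objectives["efm1"]), 1.0)
  # opposite-side mixture: segment-diagonal intersection at 0.6
  D2 <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(NULL, c("efm1", "efm2")))
  r2 <- rank_on_diagonal_2d(fake_cost(D2))
  expect_equal(unname(r2$dots[["efm1+efm2"]]), 0.6)
  expect_equal(r2$best, "efm1+efm2")
  expect_equal(unname(r2$objectives[["efm1+efm2"]]), 5 / 3)
  # same-side vectors: no mixture ranked, best pure wins
  D3 <- matrix(c(0.4, 0.9, 0.3, 0.8), 2, 2, dimnames = list(NULL, c("efm1", "efm2")))
  r3 <- rank_on_diagonal_2d(fake_cost(D3))
  expect_false(any(grepl("\\+", names(r3$dots))))
  expect_equal(r3$best, "efm2")
  expect_equal(unname(r3$dots["efm2"]), 0.8)
  expect_error(rank_on_diagonal_2d(fake_cost(matrix(1, 3, 2))), "2 constraints")
})

test_that("best 2d strategy agrees with the inner LP on random cost matrices", {
  fake_cost <- function(D) structure(list(D = D, efm_ids = colnames(D), state = NULL),
                                     class = "cost_matrix")
  # spec'd example first: both-pools-tight mixture
  D <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(NULL, c("efm1", "efm2")))
  bs <- best_strategy_2d(fake_cost(D))
  expect_equal(bs$support, c(1L, 2L))
  expect_equal(unname(bs$lambdas), c(5 / 6, 5 / 6), tolerance = 1e-12)
  single <- best_strategy_2d(fake_cost(matrix(c(0.5, 0.8), 2, 1,
                                              dimnames = list(NULL, "efm1"))))
  expect_equal(unname(single$lambdas), 1 / 0.8)
  set.seed(17)
  for (rep in 1:50) {
    M <- sample(1:6, 1)
    Dr <- matrix(10^stats::runif(2 * M, -1, 1), 2, M,
                 dimnames = list(NULL, paste0("efm", seq_len(M))))
    bs <- best_strategy_2d(fake_cost(Dr))
    lp <- solve_inner_lp(Dr)
    expect_equal(bs$objective, lp$objective, tolerance = 1e-9)
    # 1/dot equals the LP optimum restricted to that strategy's columns
    rk <- rank_on_diagonal_2d(fake_cost(Dr))
    for (nm in names(rk$dots)) {
      cols <- match(strsplit(nm, "+", fixed = TRUE)[[1]], colnames(Dr))
      sub <- solve_inner_lp(Dr[, cols, drop = FALSE])
      expect_gte(sub$objective + 1e-9, rk$objectives[[nm]])
    }
  }
})

test_that("equivalent EFMs receive identical cost columns at every state", {
  net <- diamond_network()
  kin <- list(route1 = reaction_kinetics(2), route2 = reaction_kinetics(2),
              growth = reaction_kinetics(1, saturation_spec("michaelis_menten", "A", c(A = 1))))
  m <- kinetic_model(net, kin, constraint_set(rbind(c(0, 0, 1), c(0, 0, 2)), c(1, 3)))
  efms <- objective_efms(m)
  set.seed(23)
  for (rep in 1:20) {
    x <- stats::setNames(10^stats::runif(2, -3, 3), c("S", "A"))
    cm <- compute_cost_matrix(efms, x, m)
    expect_equal(cm$D[, 1], cm$D[, 2], tolerance = 1e-12)
  }
})
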