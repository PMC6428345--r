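test_that("enumeration finds the unique route of a linear chain", {
  efms <- enumerate_efms(chain_network())
  expect_length(efms, 1L)
  expect_equal(unname(efms[[1]]$values), c(1, 1))
  expect_true(efms[[1]]$has_objective)
})

test_that("enumeration separates parallel routes of the diamond", {
  net <- diamond_network()
  efms <- enumerate_efms(net)
  expect_length(efms, 2L)
  expect_equal(lapply(efms, `[[`, "support"), list(c(1L, 3L), c(2L, 3L)))
  # exhaustive subset oracle agrees
  expect_equal(support_keys(efms), support_keys(enumerate_efms_bruteforce(net)))
})

test_that("enumeration handles degenerate cones and size limits", {
  # single irreversible reaction consuming an internal metabolite: cone = {0}
  s <- matrix(c(-1), 1, 1, dimnames = list("A", "r1"))
  net <- metabolic_network(s, is_external = c(A = FALSE), objective = "r1")
  expect_length(enumerate_efms(net), 0L)
  big <- matrix(0, 2, 30)
  big[1, ] <- -1; big[2, ] <- 1
  net_big <- metabolic_network(big, metabolite_ids = c("S", "P"),
                               reaction_ids = paste0("r", 1:30),
                               is_external = c(S = TRUE, P = FALSE), objective = 1)
  expect_error(enumerate_efms(net_big), "size_limit")
  expect_error(enumerate_efms_bruteforce(net_big), "12")
})

test_that("every enumerated EFM is a support-minimal steady-state mode", {
  set.seed(13)
  for (seed in 1:10) {
    m <- generate_instance(generator_config(seed, n_internal = 3, n_reactions = 7))
    efms <- enumerate_efms(m$network)
    expect_gt(length(efms), 0L)
    keys <- support_keys(efms)
    expect_equal(anyDuplicated(keys), 0L)
    ni <- internal_stoichiometry(m$network)
    for (e in efms) {
      expect_true(check_steady_state(m$network, e$values,
                                     tol = 1e-8 * (1 + max(e$values))))
      expect_true(all(e$values >= 0))
      # support-minimality via the kernel rank test on the support columns
      expect_equal(qr(ni[, e$support, drop = FALSE])$rank, length(e$support) - 1L)
    }
    # no enumerated support strictly contains another
    supports <- lapply(efms, `[[`, "support")
    for (i in seq_along(supports)) {
      for (j in seq_along(supports)) {
        if (i != j) expect_false(all(supports[[j]] %in% supports[[i]]) &&
                                   length(supports[[j]]) < length(supports[[i]]))
      }
    }
  }
})

test_that("double description and subset oracle agree on random instances", {
  for (seed in 1:25) {
    cfg <- generator_config(seed, n_internal = 2 + seed %% 2,
                            n_reactions = 5 + seed %% 4)
    m <- generate_instance(cfg)
    a <- enumerate_efms(m$network)
    b <- enumerate_efms_bruteforce(m$network)
    expect_equal(support_keys(a), support_keys(b), label = paste("seed", seed))
    # values agree up to the shared normalization
    ka <- order(vapply(a, function(e) paste(e$support, collapse = "-"), character(1)))
    kb <- order(vapply(b, function(e) paste(e$support, collapse = "-"), character(1)))
    expect_equal(efm_matrix(a[ka]), efm_matrix(b[kb]), tolerance = 1e-7)
  }
})

test_that("objective normalization rescales and is idempotent", {
  net <- chain_network()
  e <- enumerate_efms(net)[[1]]
  e2 <- e
  e2$values <- e$values * 2
  norm <- normalize_to_objective(e2, net)
  expect_equal(unname(norm$values), c(1, 1))
  expect_equal(normalize_to_objective(norm, net), norm)
  e3 <- structure(list(values = c(uptake = 1, growth = 0), support = 1L,
                       has_objective = FALSE), class = "efm")
  expect_error(normalize_to_objective(e3, net), "no objective flux")
})

test_that("flux decomposition recovers construction weights", {
  m <- build_overflow_model()
  efms <- enumerate_efms(m$network)
  E <- efm_matrix(efms)
  v <- drop(E %*% c(2, 3))
  d <- decompose_flux(m$network, v, efms)
  expect_equal(d$lambdas, c(2, 3), tolerance = 1e-9)
  expect_lt(d$residual, 1e-9)
  expect_true(d$certified)

  one <- drop(E %*% c(1, 0))
  d1 <- decompose_flux(m$network, one, efms)
  expect_equal(d1$lambdas, c(1, 0), tolerance = 1e-9)

  bad <- v + c(0, 1, 0, 0)  # unbalances the intermediate
  expect_error(decompose_flux(m$network, bad, efms), "steady-state")
})

test_that("decomposition reproduces random conical combinations", {
  set.seed(5)
  m <- generate_instance(generator_config(3, n_internal = 3, n_reactions = 7))
  efms <- enumerate_efms(m$network)
  E <- efm_matrix(efms)
  for (rep in 1:100) {
    w <- stats::rexp(ncol(E))
    v <- drop(E %*% w)
    d <- decompose_flux(m$network, v, efms, tol = 1e-7)
    expect_true(d$certified)
    expect_equal(drop(E %*% d$lambdas), v, tolerance = 1e-6)
  }
})
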