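# Shared fixtures, built in code.

# Two-step chain: external substrate -> A -> exported objective.
# kcat and Km chosen so closed-form optima are easy to state in tests.
chain_network <- function() {
  s <- matrix(c(-1, 1, 0, -1), 2, 2,
              dimnames = list(c("S", "A"), c("uptake", "growth")))
  metabolic_network(s, is_external = c(S = TRUE, A = FALSE), objective = "growth")
}

chain_model <- function(k1 = 10, k2 = 1, Km_S = 1, Km_A = 0.5) {
  kin <- list(
    uptake = reaction_kinetics(k1, saturation_spec("michaelis_menten", "S", c(S = Km_S))),
    growth = reaction_kinetics(k2, saturation_spec("michaelis_menten", "A", c(A = Km_A))))
  kinetic_model(chain_network(), kin,
                constraint_set(matrix(1, 1, 2, dimnames = list("total", NULL)), 1))
}

# Diamond: two parallel routes from S to A, then the objective drain.
diamond_network <- function() {
  s <- matrix(0, 2, 3, dimnames = list(c("S", "A"), c("route1", "route2", "growth")))
  s["S", "route1"] <- -1; s["A", "route1"] <- 1
  s["S", "route2"] <- -1; s["A", "route2"] <- 1
  s["A", "growth"] <- -1
  metabolic_network(s, is_external = c(S = TRUE, A = FALSE), objective = "growth")
}

support_keys <- function(efms) {
  sort(vapply(efms, function(e) paste(e$support, collapse = "-"), character(1)))
}

# Exhaustive vertex enumeration for max sum(lambda) s.t. D lambda <= 1:
# solves every square subsystem of active constraints and keeps the feasible
# basic solutions. Independent of the simplex implementation.
lp_vertex_oracle <- function(D, tol = 1e-9) {
  K <- nrow(D); M <- ncol(D)
  best <- 0
  for (size in seq_len(min(K, M))) {
    for (S in utils::combn(M, size, simplify = FALSE)) {
      for (Tt in utils::combn(K, size, simplify = FALSE)) {
        lam <- tryCatch(solve(D[Tt, S, drop = FALSE], rep(1, size)),
                        error = function(e) NULL)
        if (is.null(lam) || any(lam < -1e-12)) next
        full <- numeric(M)
        full[S] <- pmax(lam, 0)
        if (all(D %*% full <= 1 + tol)) best <- max(best, sum(full))
      }
    }
  }
  best
}

# TRUE when every internal metabolite saturates at least one of its consuming
# reactions, so that mass-action feedback can stabilize the dynamics; a
# precondition for the ODE-based brute-force oracle.
ode_stabilizable <- function(m) {
  ni <- internal_stoichiometry(m$network)
  all(vapply(rownames(ni), function(id) {
    consumers <- which(ni[id, ] < 0)
    any(vapply(consumers, function(j)
      id %in% m$kinetics[[j]]$saturation$substrate_ids, logical(1)))
  }, logical(1)))
}
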