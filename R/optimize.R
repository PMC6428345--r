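#' @keywords internal
#' Internal metabolites whose concentration enters any saturation function;
#' only these are tuned by the outer search, the rest are inert placeholders.
.free_internal_ids <- function(model) {
  refs <- unique(unlist(lapply(model$kinetics, function(rk) {
    c(rk$saturation$substrate_ids, rk$saturation$inhibitor_id)
  })))
  intersect(model$network$metabolite_ids[!model$network$is_external], refs)
}

.external_refs <- function(model) {
  refs <- unique(unlist(lapply(model$kinetics, function(rk) {
    c(rk$saturation$substrate_ids, rk$saturation$inhibitor_id)
  })))
  intersect(model$network$metabolite_ids[model$network$is_external], refs)
}

#' @keywords internal
#' Assemble the full concentration vector from external values and the free
#' internal block; inert metabolites sit at 1 (their value never enters).
.full_state <- function(model, x_external, x_free) {
  mids <- model$network$metabolite_ids
  x <- stats::setNames(rep(1, length(mids)), mids)
  x[names(x_external)] <- x_external
  if (length(x_free) > 0L) x[names(x_free)] <- x_free
  x
}

#' @keywords internal
#' Structural cost check: an EFM is cost-free when no reaction of its support
#' carries weight in any pool. Such EFMs void the optimization's assumptions.
.structurally_costfree <- function(efm, model) {
  w <- model$constraints$weights
  all(colSums(w[, efm$support, drop = FALSE]) == 0)
}

#' Maximize objective flux over enzyme allocation and internal concentrations
#'
#' Solves the growth-maximization problem in two nested stages. For fixed
#' metabolite concentrations the problem over EFM weights is the inner linear
#' program of [solve_inner_lp()] on the cost matrix; the outer stage searches
#' over the internal metabolite concentrations that enter any saturation
#' function, by seeded multistart Nelder-Mead in log10-concentration space
#' within configured bounds. The optimal enzyme profile is recovered from the
#' EFM weights and per-EFM enzyme demands and reproduces the optimal fluxes
#' through the rate law exactly.
#'
#' @param model a `kinetic_model`.
#' @param x_external named vector of external metabolite concentrations; must
#'   cover every external metabolite referenced by a saturation function.
#' @param options list of search options: `n_starts` (default 16), `maxit`
#'   per start (default 200), `conc_bounds` (default `c(1e-3, 1e3)` model
#'   units), `seed` (default 1), `warm_starts` (list of named internal
#'   concentration vectors added to the start set), `reltol` (default 1e-10).
#' @return object of class `optimization_result`: `objective`, `x_internal`
#'   (free internal concentrations at the optimum), `x_state` (full
#'   concentration vector), `inner` (the `inner_lp_result`),
#'   `enzyme_profile`, `active_efms` / `active_constraints` (ids at default
#'   tolerances), `efms` (the objective EFMs), `model`, `starts` (per-start
#'   log of converged objectives).
#' @export
optimize_growth <- function(model, x_external, options = list()) {
  opts <- utils::modifyList(
    list(n_starts = 16L, maxit = 200L, conc_bounds = c(1e-3, 1e3), seed = 1L,
         warm_starts = list(), reltol = 1e-10),
    options)
  all_efms <- enumerate_efms(model$network)
  efms <- Filter(function(e) e$has_objective, all_efms)
  if (length(efms) == 0L) stop("model has no objective-producing EFM; nothing to optimize")
  efms <- lapply(efms, normalize_to_objective, network = model$network)
  costfree <- vapply(efms, .structurally_costfree, logical(1), model = model)
  if (any(costfree)) {
    stop("objective-producing EFM(s) without enzyme cost detected; the ",
         "objective is unbounded under the model's constraint set")
  }
  idle <- Filter(function(e) !e$has_objective && .structurally_costfree(e, model), all_efms)
  if (length(idle) > 0L) {
    warning("network contains ", length(idle), " EFM(s) that neither produce ",
            "objective flux nor draw on any constrained pool; they are ",
            "ignored by the optimization but make the flux solution non-unique")
  }
  missing_ext <- setdiff(.external_refs(model), names(x_external))
  if (length(missing_ext) > 0L) {
    stop("external concentration(s) required: ", paste(missing_ext, collapse = ", "))
  }
  free_ids <- .free_internal_ids(model)
  lb <- log10(opts$conc_bounds[1]); ub <- log10(opts$conc_bounds[2])

  # vectorized objective for the outer search: shared saturation vector,
  # demands as one matrix division, then the inner LP
  mids <- model$network$metabolite_ids
  x_template <- stats::setNames(rep(1, length(mids)), mids)
  x_template[names(x_external)] <- x_external
  free_pos <- match(free_ids, mids)
  f_at <- .compile_saturation(model)
  vmat <- efm_matrix(efms)
  kcatv <- vapply(model$kinetics, `[[`, numeric(1), "kcat")
  w_scaled <- model$constraints$weights / model$constraints$bounds
  zero_mask <- vmat == 0

  eval_state <- function(z) {
    z <- pmin(pmax(z, lb), ub)
    x <- x_template
    if (length(free_pos) > 0L) x[free_pos] <- 10^z
    demands <- vmat / (kcatv * f_at(x))
    demands[zero_mask] <- 0
    demands[!is.finite(demands)] <- 1e12  # f = 0 on a support: prohibitive cost
    solve_inner_lp(w_scaled %*% demands, canonical = FALSE)$objective
  }

  starts_log <- list()
  if (length(free_ids) == 0L) {
    best_z <- numeric(0)
    best_obj <- eval_state(best_z)
    starts_log <- list(list(start = numeric(0), objective = best_obj, convergence = 0L))
  } else {
    n_dim <- length(free_ids)
    starts <- with_local_seed(opts$seed, {
      s <- lapply(seq_len(max(opts$n_starts - 1L, 1L)),
                  function(i) stats::runif(n_dim, lb, ub))
      c(list(rep((lb + ub) / 2, n_dim)), s)
    })
    if (n_dim <= 4L) {
      # coarse log-grid prescan: cheap insurance against kinks and far-off
      # basins that multistart simplex alone can miss
      axis <- seq(lb, ub, length.out = if (n_dim <= 2L) 7L else 5L)
      grid <- as.matrix(expand.grid(rep(list(axis), n_dim)))
      grid_obj <- apply(grid, 1, eval_state)
      top <- order(grid_obj, decreasing = TRUE)[seq_len(min(3L, nrow(grid)))]
      starts <- c(lapply(top, function(i) unname(grid[i, ])), starts)
    }
    for (w in opts$warm_starts) {
      starts <- c(list(pmin(pmax(log10(as.numeric(w[free_ids])), lb), ub)), starts)
    }
    best_obj <- -Inf; best_z <- starts[[1]]
    if (n_dim == 1L) {
      # golden-section over the whole interval, plus a bracketed search
      # around the best prescan point in case the profile is multimodal
      fine <- seq(lb, ub, length.out = 25L)
      fine_obj <- vapply(fine, eval_state, numeric(1))
      i_best <- which.max(fine_obj)
      brackets <- list(c(lb, ub),
                       c(fine[max(1L, i_best - 1L)], fine[min(25L, i_best + 1L)]))
      for (b in brackets) {
        fit <- stats::optimize(function(z) eval_state(z), lower = b[1], upper = b[2],
                               maximum = TRUE, tol = 1e-8)
        starts_log[[length(starts_log) + 1L]] <-
          list(start = b, objective = fit$objective, convergence = 0L)
        if (fit$objective > best_obj) {
          best_obj <- fit$objective
          best_z <- fit$maximum
        }
      }
      if (fine_obj[i_best] > best_obj) {
        best_obj <- fine_obj[i_best]
        best_z <- fine[i_best]
      }
    } else {
      for (s in starts) {
        res <- stats::optim(s, eval_state, method = "Nelder-Mead",
                            control = list(fnscale = -1, maxit = opts$maxit,
                                           reltol = opts$reltol))
        starts_log[[length(starts_log) + 1L]] <-
          list(start = s, objective = res$value, convergence = res$convergence)
        if (res$value > best_obj) {
          best_obj <- res$value
          best_z <- res$par
        }
      }
    }
    if (!is.finite(best_obj)) stop("no optimization start converged; check model feasibility")
  }

  best_z <- pmin(pmax(best_z, lb), ub)
  x_free <- stats::setNames(10^best_z, free_ids)
  x_star <- .full_state(model, x_external, x_free)
  cm <- compute_cost_matrix(efms, x_star, model)
  inner <- solve_inner_lp(cm, canonical = TRUE)
  demands <- vapply(efms, enzyme_demand, numeric(length(model$network$reaction_ids)),
                    x = x_star, model = model)
  e <- drop(demands %*% inner$lambdas)
  usage <- constraint_usage(e, model$constraints)
  lam_max <- max(inner$lambdas, 0)
  active_efms <- which(inner$lambdas > 1e-6 * lam_max)
  active_constraints <- which(usage >= model$constraints$bounds * (1 - 1e-6))
  structure(
    list(objective = inner$objective,
         x_internal = x_free,
         x_state = x_star,
         inner = inner,
         enzyme_profile = stats::setNames(e, model$network$reaction_ids),
         constraint_usage = usage,
         active_efms = active_efms,
         active_constraints = model$constraints$pool_ids[active_constraints],
         efms = efms,
         model = model,
         x_external = x_external,
         starts = starts_log),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> objective %.6g; %d active EFM(s); active constraint(s): %s\n",
              x$objective, length(x$active_efms),
              paste(x$active_constraints, collapse = ", ")))
  invisible(x)
}

#' Count active EFMs and active constraints at an optimum
#'
#' An EFM is active when its weight exceeds `tol_lambda` times the largest
#' weight; a constraint is active when its pool usage is within
#' `tol_constraint` (relative) of the bound. Active EFMs that are equivalent
#' (equal cost vectors at the optimal state) are collapsed to a single
#' representative, since they are interchangeable in the optimal mixture.
#'
#' @param result an `optimization_result`.
#' @param tol_lambda relative weight threshold (default 1e-6).
#' @param tol_constraint relative constraint slack threshold (default 1e-6).
#' @return list with `n_active_efms`, `n_active_constraints`,
#'   `n_nonequivalent_efms`, and the index/id sets.
#' @export
analyze_active_sets <- function(result, tol_lambda = 1e-6, tol_constraint = 1e-6) {
  lam <- result$inner$lambdas
  usage <- result$constraint_usage
  bounds <- result$model$constraints$bounds
  active_efms <- which(lam > tol_lambda * max(lam, 0))
  active_constraints <- which(usage >= bounds * (1 - tol_constraint))
  n_collapsed <- length(active_efms)
  if (length(active_efms) > 1L) {
    reps <- list()
    for (i in active_efms) {
      dup <- any(vapply(reps, function(j) {
        are_equivalent(result$efms[[i]], result$efms[[j]], result$model,
                       x_samples = list(result$x_state))
      }, logical(1)))
      if (!dup) reps[[length(reps) + 1L]] <- i
    }
    n_collapsed <- length(reps)
  }
  list(n_active_efms = length(active_efms),
       n_active_constraints = length(active_constraints),
       n_nonequivalent_efms = n_collapsed,
       active_efms = active_efms,
       active_constraints = result$model$constraints$pool_ids[active_constraints])
}

#' Check the extremum principle on an optimization result
#'
#' At a growth-rate optimum the number of non-equivalent flux-carrying EFMs
#' can be at most the number of active enzyme-expression constraints.
#'
#' @param result an `optimization_result`.
#' @param ... passed to [analyze_active_sets()].
#' @return list with `ok` (logical), and the counts from
#'   [analyze_active_sets()].
#' @export
verify_extremum_principle <- function(result, ...) {
  sets <- analyze_active_sets(result, ...)
  c(list(ok = sets$n_nonequivalent_efms <= sets$n_active_constraints), sets)
}

#' Steady-state internal concentrations for a fixed enzyme profile
#'
#' Integrates `dx_internal/dt = N_internal %*% v(e, x)` with a stiff solver
#' until the right-hand side falls below `1e-9 * (1 + max|x|)` (converged),
#' any internal concentration exceeds 1e9 (diverged), or the time budget of
#' 1e6 model time units is exhausted (non-converged). Supports the
#' brute-force optimization oracle.
#'
#' @param model a `kinetic_model`.
#' @param e nonnegative enzyme vector, length r.
#' @param x_external named external concentrations.
#' @param x0 optional named initial internal concentrations (default all 1).
#' @return list with `state` (named internal concentrations), `fluxes`,
#'   `converged`, `diverged`, `time` reached.
#' @export
steady_state_for_enzymes <- function(model, e, x_external, x0 = NULL) {
  net <- model$network
  ni <- internal_stoichiometry(net)
  internal_ids <- rownames(ni)
  e <- stats::setNames(as.numeric(e), net$reaction_ids)
  if (any(e < 0)) stop("enzyme concentrations must be nonnegative")
  if (is.null(x0)) x0 <- stats::setNames(rep(1, length(internal_ids)), internal_ids)
  # precompiled evaluation tables: integer indices into the full state vector
  # keep the inner loop free of name lookups and S3 dispatch
  mids <- net$metabolite_ids
  x_template <- stats::setNames(rep(1, length(mids)), mids)
  x_template[names(x_external)] <- x_external
  internal_pos <- match(internal_ids, mids)
  r_n <- length(net$reaction_ids)
  ekcat <- numeric(r_n)
  sub_idx <- vector("list", r_n); km_list <- vector("list", r_n)
  inh_idx <- integer(r_n); ki_vec <- numeric(r_n); custom <- vector("list", r_n)
  for (j in seq_len(r_n)) {
    rk <- model$kinetics[[j]]
    ekcat[j] <- e[j] * rk$kcat
    sat <- rk$saturation
    if (sat$kind %in% c("michaelis_menten", "mm_product_inhibition")) {
      sub_idx[[j]] <- match(sat$substrate_ids, mids)
      km_list[[j]] <- unname(sat$Km)
    }
    if (sat$kind == "mm_product_inhibition") {
      inh_idx[j] <- match(sat$inhibitor_id, mids)
      ki_vec[j] <- sat$Ki
    }
    if (!sat$kind %in% c("constant", "michaelis_menten", "mm_product_inhibition")) {
      custom[[j]] <- sat
    }
  }
  fluxes_at <- function(xi) {
    x <- x_template
    if (length(internal_pos) > 0L) x[internal_pos] <- pmax(xi, 0)
    v <- ekcat
    for (j in seq_len(r_n)) {
      if (!is.null(sub_idx[[j]])) {
        xs <- x[sub_idx[[j]]]
        f <- prod(xs / (km_list[[j]] + xs))
        if (inh_idx[j] > 0L) f <- f / (1 + x[inh_idx[j]] / ki_vec[j])
        v[j] <- v[j] * f
      } else if (!is.null(custom[[j]])) {
        v[j] <- v[j] * saturation_value(custom[[j]], x)
      }
    }
    v
  }
  deriv <- function(t, xi, parms) {
    list(drop(ni %*% fluxes_at(xi)))
  }
  if (length(internal_ids) == 0L) {
    v <- fluxes_at(numeric(0))
    return(list(state = x0, fluxes = stats::setNames(v, net$reaction_ids),
                residual = 0, converged = TRUE, diverged = FALSE, time = 0))
  }
  rhs <- function(xi) drop(ni %*% fluxes_at(xi))
  n_int <- length(internal_ids)
  jac_at <- function(xi) {
    J <- matrix(0, n_int, n_int)
    for (k in seq_len(n_int)) {
      h <- max(1e-6, 1e-6 * xi[k])
      xp <- xi; xp[k] <- xi[k] + h
      xm <- xi; xm[k] <- max(xi[k] - h, 0)
      J[, k] <- (rhs(xp) - rhs(xm)) / (xp[k] - xm[k])
    }
    J
  }
  # Newton polish: from the current trajectory point, jump to the nearby
  # fixed point and accept it when it is nonnegative, locally stable, and in
  # the same region of state space as the trajectory
  newton_polish <- function(xi) {
    x <- xi
    for (it in seq_len(30L)) {
      f <- rhs(x)
      if (max(abs(f)) < 1e-12 * (1 + max(abs(x)))) break
      step <- try(solve(jac_at(x), -f), silent = TRUE)
      if (inherits(step, "try-error")) return(NULL)
      x <- pmax(x + step, 0)
      if (any(!is.finite(x))) return(NULL)
    }
    if (max(abs(rhs(x))) > 1e-10 * (1 + max(abs(x)))) return(NULL)
    near <- all(x <= 1e3 * xi + 1e-3) && all(x >= xi / 1e3 - 1e-3)
    if (!near) return(NULL)
    ev <- eigen(jac_at(x), only.values = TRUE)$values
    if (any(Re(ev) > 1e-6)) return(NULL)
    x
  }
  t_now <- 0
  xi <- as.numeric(x0[internal_ids])
  converged <- FALSE; diverged <- FALSE
  rate_prev <- Inf
  # often the fixed point is reachable directly; integration is the fallback
  polished <- newton_polish(xi)
  if (!is.null(polished)) { xi <- polished; converged <- TRUE }
  if (!converged) for (t_next in 10^(0:6)) {
    sol <- NULL
    utils::capture.output(
      sol <- try(deSolve::ode(y = xi, times = c(t_now, t_next), func = deriv,
                              parms = NULL, method = "lsoda", rtol = 1e-7,
                              atol = 1e-9, maxsteps = 10000), silent = TRUE))
    if (inherits(sol, "try-error") || nrow(sol) < 2L) break
    xi <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    t_now <- t_next
    if (any(xi > 1e9)) { diverged <- TRUE; break }
    rate_now <- max(abs(rhs(xi)))
    if (rate_now < 1e-9 * (1 + max(abs(xi)))) { converged <- TRUE; break }
    if (t_now >= 1) {
      polished <- newton_polish(xi)
      if (!is.null(polished)) { xi <- polished; converged <- TRUE; break }
      # Newton found no nearby stable fixed point and the residual is not
      # decaying: drifting or cycling, the budget cannot converge
      if (t_now >= 1e3 && rate_now > 0.8 * rate_prev) break
    }
    rate_prev <- rate_now
  }
  v <- fluxes_at(xi)
  list(state = stats::setNames(xi, internal_ids),
       fluxes = stats::setNames(v, net$reaction_ids),
       residual = if (length(xi)) max(abs(rhs(xi))) else 0,
       converged = converged, diverged = diverged, time = t_now)
}

#' Brute-force growth maximization over sampled enzyme allocations
#'
#' Independent lower-bound oracle for [optimize_growth()]: samples enzyme
#' allocations on the boundary of the constraint polytope (seeded random
#' directions scaled until one pool is exhausted), computes the steady state
#' each allocation supports via [steady_state_for_enzymes()], evaluates the
#' objective flux there, and refines the best allocations by Nelder-Mead in
#' log-allocation space. Divergent or non-converging allocations are
#' infeasible. Concentrations are not box-bounded here, so agreement with the
#' bounded outer search is expected only up to the (tiny) saturation headroom
#' beyond the search box. No optimality guarantee.
#'
#' @param model a `kinetic_model` with at most 6 reactions.
#' @param x_external named external concentrations.
#' @param grid_options list: `n_random` samples (default 48), `refine_maxit`
#'   (default 120), `seed` (default 1).
#' @return list with `objective`, `enzyme_profile`, `state` (internal
#'   concentrations at the best steady state), `n_evaluated`.
#' @export
brute_force_optimize <- function(model, x_external, grid_options = list()) {
  opts <- utils::modifyList(
    list(n_random = 48L, refine_maxit = 200L, seed = 1L),
    grid_options)
  r <- length(model$network$reaction_ids)
  if (r > 6L) stop("brute-force optimization is limited to 6 reactions")
  cs <- model$constraints
  obj_idx <- model$network$objective_index
  scale_to_boundary <- function(e) {
    usage <- drop(cs$weights %*% e)
    f <- min(cs$bounds[usage > 0] / usage[usage > 0])
    e * f
  }
  internal_ids <- rownames(internal_stoichiometry(model$network))
  x0_set <- list(stats::setNames(rep(1, length(internal_ids)), internal_ids),
                 stats::setNames(rep(1e4, length(internal_ids)), internal_ids))
  evaluate_from <- function(e, x0) {
    ss <- steady_state_for_enzymes(model, e, x_external, x0 = x0)
    if (ss$diverged) return(list(value = -Inf, ss = ss))
    # slow-manifold trajectories count as steady when the residual imbalance
    # is negligible on the scale of the fluxes themselves
    near_steady <- ss$converged ||
      ss$residual <= 1e-4 * (1 + max(abs(ss$fluxes)))
    if (!near_steady) return(list(value = -Inf, ss = ss))
    list(value = ss$fluxes[obj_idx], ss = ss)
  }
  # multistable dynamics: a growth-maximizing cell settles in the best of
  # its locally stable states, so evaluate from both a low and a high
  # initial condition and keep the better one
  evaluate <- function(e) {
    best_ev <- list(value = -Inf, ss = NULL)
    for (x0 in x0_set) {
      ev <- evaluate_from(e, x0)
      if (ev$value > best_ev$value) best_ev <- ev
    }
    best_ev
  }
  samples <- with_local_seed(opts$seed, {
    lapply(seq_len(opts$n_random), function(i) {
      e <- stats::rexp(r)
      if (i %% 2L == 0L) {
        # sparse direction: optima sit on low-support faces of the polytope
        drop_mask <- stats::runif(r) < 0.4
        drop_mask[obj_idx] <- FALSE
        e[drop_mask] <- 0
      }
      e
    })
  })
  # pathway-directed samples: allocations proportional to each minimal
  # pathway's enzyme demand at random metabolite states (and pairwise
  # mixtures thereof); a structural prior from stoichiometry and kinetics
  # only, not from any solved optimum
  efms <- tryCatch(objective_efms(model), error = function(e) list())
  if (length(efms) > 0L) {
    mids <- model$network$metabolite_ids
    f_at <- .compile_saturation(model)
    kcatv <- vapply(model$kinetics, `[[`, numeric(1), "kcat")
    x_base <- stats::setNames(rep(1, length(mids)), mids)
    x_base[names(x_external)] <- x_external
    internal <- !model$network$is_external
    demand_at <- function(efm, x) {
      d <- efm$values / (kcatv * f_at(x))
      d[efm$values == 0] <- 0
      if (all(is.finite(d)) && max(d) > 0) d else NULL
    }
    directed <- with_local_seed(opts$seed + 1L, {
      out <- Filter(Negate(is.null), lapply(efms, demand_at, x = x_base))
      for (rep in seq_len(6L)) {
        x <- x_base
        x[internal] <- 10^stats::runif(sum(internal), -4, 4)
        dems <- Filter(Negate(is.null), lapply(efms, demand_at, x = x))
        out <- c(out, dems)
        if (length(dems) >= 2L) {
          pair <- sample(length(dems), 2L)
          t_mix <- stats::runif(1)
          out[[length(out) + 1L]] <-
            t_mix * dems[[pair[1]]] / max(dems[[pair[1]]]) +
            (1 - t_mix) * dems[[pair[2]]] / max(dems[[pair[2]]])
        }
      }
      out
    })
    samples <- c(directed, samples)
  }
  cand <- list()
  n_eval <- 0L
  for (s in samples) {
    e <- scale_to_boundary(s)
    ev <- evaluate(e)
    n_eval <- n_eval + 1L
    if (is.finite(ev$value)) cand[[length(cand) + 1L]] <- list(value = ev$value, e = e, ss = ev$ss)
  }
  if (length(cand) == 0L) stop("no sampled allocation reached a feasible steady state")
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "value"), decreasing = TRUE)]
  best <- cand[[1]]
  refine_from <- function(e0) {
    refine <- stats::optim(log(e0 + 1e-12), function(u) {
      ev <- evaluate(scale_to_boundary(exp(u)))
      if (is.finite(ev$value)) return(ev$value)
      # graded infeasibility: keep a slope toward less-divergent dynamics so
      # the simplex can approach optima that sit near a stability edge
      -1e3 - min(log10(1 + max(ev$ss$residual, 0)), 100)
    }, method = "Nelder-Mead",
    control = list(fnscale = -1, maxit = opts$refine_maxit, reltol = 1e-10))
    n_eval <<- n_eval + opts$refine_maxit
    e_ref <- scale_to_boundary(exp(refine$par))
    list(ev = evaluate(e_ref), e = e_ref)
  }
  for (start in cand[seq_len(min(2L, length(cand)))]) {
    out <- refine_from(start$e)
    if (out$ev$value > best$value) best <- list(value = out$ev$value, e = out$e, ss = out$ev$ss)
  }
  # restart the simplex on the incumbent until it stops improving
  for (round in seq_len(4L)) {
    prev <- best$value
    out <- refine_from(best$e)
    if (out$ev$value > best$value) {
      best <- list(value = out$ev$value, e = out$e, ss = out$ev$ss)
    }
    if (best$value < prev * (1 + 1e-3)) break
  }
  list(objective = unname(best$value),
       enzyme_profile = stats::setNames(best$e, model$network$reaction_ids),
       state = best$ss$state,
       n_evaluated = n_eval)
}

#' Realizability of an optimum under expression noise
#'
#' Perturbs the optimal enzyme concentrations with multiplicative log-normal
#' noise, rescales each perturbed profile onto the constraint polytope
#' boundary, computes the steady state each profile reaches (from a low and
#' a high initial condition), and returns the largest objective fraction
#' realized. At a well-behaved optimum, allocations in a small neighbourhood
#' realize almost the full objective; when every neighbour diverges or falls
#' into a poor basin, the optimum sits on a stability edge of the
#' fixed-enzyme dynamics and steady-state sampling oracles such as
#' [brute_force_optimize()] cannot be expected to reach it.
#'
#' @param result an `optimization_result` from [optimize_growth()].
#' @param n number of noise draws (default 8).
#' @param noise log-normal standard deviation (default 0.02, i.e. ~2%).
#' @param seed seed for the noise draws.
#' @return largest fraction of the optimal objective realized by any
#'   perturbed profile (0 when none reaches a steady state).
#' @export
optimum_noise_robustness <- function(result, n = 8L, noise = 0.02, seed = 1L) {
  model <- result$model
  e0 <- result$enzyme_profile
  x_ext <- result$x_external
  cs <- model$constraints
  internal_ids <- rownames(internal_stoichiometry(model$network))
  obj_idx <- model$network$objective_index
  with_local_seed(seed, {
    best <- 0
    for (rep in seq_len(n)) {
      e <- e0 * exp(stats::rnorm(length(e0), 0, noise))
      usage <- drop(cs$weights %*% e)
      e <- e * min(cs$bounds[usage > 0] / usage[usage > 0])
      for (x0v in c(1, 1e4)) {
        x0 <- stats::setNames(rep(x0v, length(internal_ids)), internal_ids)
        ss <- steady_state_for_enzymes(model, e, x_ext, x0 = x0)
        near <- ss$converged ||
          (!ss$diverged && ss$residual <= 1e-4 * (1 + max(abs(ss$fluxes))))
        if (near) best <- max(best, unname(ss$fluxes[obj_idx]) / result$objective)
      }
    }
    best
  })
}
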