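#' @keywords internal
#' Run code with a private RNG stream, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Objective-producing EFMs of a kinetic model
#'
#' Enumerates all EFMs of the model's network and keeps those carrying
#' objective flux, normalized to a unit objective entry.
#'
#' @param model a `kinetic_model`.
#' @return list of normalized `efm` objects (possibly empty).
#' @export
objective_efms <- function(model) {
  efms <- enumerate_efms(model$network)
  efms <- Filter(function(e) e$has_objective, efms)
  lapply(efms, normalize_to_objective, network = model$network)
}

#' Cost matrix of a set of EFMs at a metabolite state
#'
#' Entry `(k, i)` is the fraction of constrained pool k that EFM i consumes
#' to generate one unit of objective flux at metabolite state `x`:
#' `d_k^i(x) = sum_j w_j^(k) V_j^i / (kcat_j f_j(x)) / bound_k`. Weights are
#' rescaled by the pool bounds so that feasibility of a weight vector
#' `lambda` reads `D %*% lambda <= 1` elementwise.
#'
#' @param efms list of normalized objective-producing `efm` objects.
#' @param x named concentration vector (external and internal metabolites).
#' @param model a `kinetic_model`.
#' @return object of class `cost_matrix`: list with `D` (K x M matrix, pools
#'   in rows), `efm_ids`, and `state` (the `x` used).
#' @export
compute_cost_matrix <- function(efms, x, model) {
  stopifnot(length(efms) > 0L)
  if (!all(vapply(efms, `[[`, logical(1), "has_objective"))) {
    stop("cost matrix is defined for objective-producing EFMs only")
  }
  cs <- model$constraints
  w_scaled <- cs$weights / cs$bounds
  D <- vapply(efms, function(e) drop(w_scaled %*% enzyme_demand(e, x, model)),
              numeric(nrow(cs$weights)))
  D <- matrix(D, nrow = nrow(cs$weights),
              dimnames = list(cs$pool_ids, paste0("efm", seq_along(efms))))
  structure(list(D = D, efm_ids = colnames(D), state = x), class = "cost_matrix")
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix> %d pool(s) x %d EFM(s)\n", nrow(x$D), ncol(x$D)))
  print(x$D)
  invisible(x)
}

#' Test whether two EFMs are equivalent with respect to the constraints
#'
#' Two EFMs are equivalent when their cost vectors are equal; equivalent EFMs
#' are interchangeable in an optimal mixture, so only non-equivalent EFMs are
#' counted by the extremum principle. Equality of cost vectors is checked at
#' each supplied metabolite state (or, by default, at 20 seeded quasi-random
#' states drawn log-uniformly per metabolite, a decidable surrogate for
#' "for all x").
#'
#' @param efm_a,efm_b normalized objective-producing `efm` objects.
#' @param model a `kinetic_model`.
#' @param x_samples list of named concentration vectors; defaults to 20
#'   seeded log-uniform draws in `[1e-3, 1e3]` per metabolite.
#' @param tol maximum absolute cost difference tolerated (default 1e-8).
#' @param seed seed for the default sampling.
#' @return `TRUE` iff the cost vectors agree within `tol` at every sample.
#' @export
are_equivalent <- function(efm_a, efm_b, model, x_samples = NULL, tol = 1e-8,
                           seed = 20190311L) {
  if (is.null(x_samples)) {
    mids <- model$network$metabolite_ids
    x_samples <- with_local_seed(seed, {
      lapply(seq_len(20L), function(i) {
        stats::setNames(10^stats::runif(length(mids), -3, 3), mids)
      })
    })
  }
  if (length(x_samples) == 0L) stop("at least one metabolite state sample is required")
  for (x in x_samples) {
    da <- drop((model$constraints$weights / model$constraints$bounds) %*%
                 enzyme_demand(efm_a, x, model))
    db <- drop((model$constraints$weights / model$constraints$bounds) %*%
                 enzyme_demand(efm_b, x, model))
    if (max(abs(da - db)) > tol) return(FALSE)
  }
  TRUE
}

#' Rank EFMs and two-EFM mixtures on the constraint-box diagonal (K = 2)
#'
#' With two constraints, every strategy (pure EFM or a mixture of an
#' above-diagonal and a below-diagonal EFM) can be ranked by a single dot on
#' the diagonal of the unit constraint box: the average cost per unit
#' objective flux. A pure strategy with cost vector `d` projects to
#' `max(d1, d2)`; a mixture of two cost vectors on opposite sides of the
#' diagonal is ranked by the diagonal coordinate of the intersection between
#' the diagonal and the segment joining them. The strategy with the dot
#' closest to the origin yields the largest objective flux, `1 / dot`.
#' Cost vectors exactly on the diagonal saturate both pools on their own and
#' rank as pure strategies.
#'
#' @param cost a `cost_matrix` with exactly two pools; all entries must be
#'   positive.
#' @param tol numeric tolerance for classifying a vector as diagonal.
#' @return object of class `diagonal_ranking`: list with `dots` (named
#'   vector, diagonal positions), `objectives` (`1/dots`), `best` (strategy
#'   id), `sides` (per-EFM classification `above`/`below`/`diagonal`).
#' @export
rank_on_diagonal_2d <- function(cost, tol = 1e-12) {
  D <- cost$D
  if (nrow(D) != 2L) stop("diagonal ranking requires exactly 2 constraints")
  if (any(D <= 0)) stop("diagonal ranking requires strictly positive costs")
  M <- ncol(D)
  g <- D[2, ] - D[1, ]  # > 0: above diagonal (pool 2 costlier), < 0: below
  sides <- ifelse(abs(g) <= tol, "diagonal", ifelse(g > 0, "above", "below"))
  dots <- stats::setNames(pmax(D[1, ], D[2, ]), colnames(D))
  if (M > 1L) {
    for (a in seq_len(M - 1L)) {
      for (b in (a + 1L):M) {
        opposite <- (sides[a] == "above" && sides[b] == "below") ||
          (sides[a] == "below" && sides[b] == "above")
        if (!opposite) next
        t <- g[a] / (g[a] - g[b])
        p <- (1 - t) * D[1, a] + t * D[1, b]
        dots[paste0(colnames(D)[a], "+", colnames(D)[b])] <- p
      }
    }
  }
  structure(list(dots = dots, objectives = 1 / dots,
                 best = names(dots)[which.min(dots)], sides = sides),
            class = "diagonal_ranking")
}

#' @export
print.diagonal_ranking <- function(x, ...) {
  cat("<diagonal_ranking>\n")
  print(data.frame(dot = x$dots, objective = x$objectives))
  cat("best:", x$best, "\n")
  invisible(x)
}

#' Best pure-or-mixture strategy for two constraints, by exact enumeration
#'
#' Enumerates all pure strategies and all opposite-side pairs via
#' [rank_on_diagonal_2d()] and returns the support and weights attaining the
#' maximal objective `sum(lambda)` subject to `D %*% lambda <= 1`. The
#' support has at most two elements and the objective agrees with the inner
#' linear program.
#'
#' @param cost a `cost_matrix` with exactly two pools and positive entries.
#' @return list with `support` (EFM indices), `lambdas` (full-length weight
#'   vector), `objective`.
#' @export
best_strategy_2d <- function(cost) {
  rk <- rank_on_diagonal_2d(cost)
  D <- cost$D
  M <- ncol(D)
  best <- rk$best
  lambdas <- stats::setNames(numeric(M), colnames(D))
  if (grepl("+", best, fixed = TRUE)) {
    pair <- match(strsplit(best, "+", fixed = TRUE)[[1]], colnames(D))
    lam <- solve(D[, pair], c(1, 1))
    lambdas[pair] <- lam
    support <- pair
  } else {
    i <- match(best, colnames(D))
    lambdas[i] <- 1 / max(D[, i])
    support <- i
  }
  list(support = sort(support), lambdas = lambdas, objective = sum(lambdas))
}
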