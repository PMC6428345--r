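#' @keywords internal
#' Dense primal simplex with Bland's rule for max c'x s.t. Ax <= b, x >= 0.
#' Requires b >= 0 so the slack basis is feasible; deterministic; returns a
#' basic feasible solution (vertex). Errors on unboundedness.
simplex_max <- function(A, b, c, tol = 1e-11) {
  K <- nrow(A); M <- ncol(A)
  if (any(b < 0)) stop("simplex_max requires a nonnegative right-hand side")
  Tb <- cbind(A, diag(K), b)
  z <- c(-c, numeric(K), 0)
  basis <- M + seq_len(K)
  repeat {
    enter <- which(z[seq_len(M + K)] < -tol)
    if (length(enter) == 0L) break
    enter <- enter[1L]  # Bland: smallest eligible index
    col <- Tb[, enter]
    rows <- which(col > tol)
    if (length(rows) == 0L) stop("linear program is unbounded")
    ratios <- Tb[rows, M + K + 1L] / col[rows]
    cand <- rows[ratios <= min(ratios) + tol]
    leave <- cand[which.min(basis[cand])]  # Bland: smallest leaving variable
    Tb[leave, ] <- Tb[leave, ] / Tb[leave, enter]
    for (i in seq_len(K)) {
      if (i != leave && abs(Tb[i, enter]) > 0) Tb[i, ] <- Tb[i, ] - Tb[i, enter] * Tb[leave, ]
    }
    z <- z - z[enter] * Tb[leave, ]
    basis[leave] <- enter
  }
  x <- numeric(M + K)
  x[basis] <- Tb[, M + K + 1L]
  list(x = x[seq_len(M)], objective = sum(c * x[seq_len(M)]), basis = basis)
}

#' Solve the inner linear program over EFM weights
#'
#' Given the cost matrix `D` at a fixed metabolite state, maximizes the
#' objective flux `sum(lambda)` subject to `D %*% lambda <= 1`, `lambda >= 0`.
#' The solution returned is a vertex (basic feasible solution) of the
#' feasible polytope, so its support has at most K elements whenever no two
#' used cost columns coincide. With `canonical = TRUE`, ties between optimal
#' vertices are broken deterministically in favour of the lexicographically
#' smallest support.
#'
#' @param cost a `cost_matrix`, or a bare K x M numeric matrix of
#'   pool-rescaled costs.
#' @param canonical break optimal-vertex ties by scanning supports in
#'   (size, lexicographic) order; skip for speed inside search loops.
#' @param tol numerical tolerance.
#' @return object of class `inner_lp_result`: `lambdas`, `objective`
#'   (`sum(lambdas)`), `basis_support` (indices with positive weight),
#'   `lp_matrix` (list with the stacked constraint matrix `A = rbind(-I, D)`
#'   and right-hand side `z`).
#' @export
solve_inner_lp <- function(cost, canonical = TRUE, tol = 1e-9) {
  D <- if (inherits(cost, "cost_matrix")) cost$D else as.matrix(cost)
  if (any(D < 0)) stop("cost matrix entries must be nonnegative")
  K <- nrow(D); M <- ncol(D)
  zero_col <- which(apply(D, 2, max) == 0)
  if (length(zero_col) > 0L) {
    stop("cost-free EFM (column ", paste(zero_col, collapse = ", "),
         "): the objective is unbounded; the framework assumes every EFM ",
         "draws on at least one limited enzyme pool")
  }
  sol <- simplex_max(D, rep(1, K), rep(1, M))
  lambdas <- pmax(sol$x, 0)
  objective <- sum(lambdas)
  if (canonical && M <= 20L) {
    res <- .lex_min_support(D, objective, tol)
    if (!is.null(res)) lambdas <- res
  }
  support <- which(lambdas > tol * max(lambdas, 1))
  structure(
    list(lambdas = stats::setNames(lambdas, colnames(D)),
         objective = sum(lambdas),
         basis_support = support,
         lp_matrix = list(A = rbind(-diag(M), D), z = c(numeric(M), rep(1, K)))),
    class = "inner_lp_result")
}

#' @keywords internal
#' Scan supports in (size, lexicographic) order for one achieving the known
#' optimum; returns the restricted vertex solution, or NULL if none matches
#' (which only happens through numerical disagreement; caller keeps the
#' simplex vertex then).
.lex_min_support <- function(D, objective, tol) {
  K <- nrow(D); M <- ncol(D)
  if (objective <= tol) return(numeric(M))
  for (size in seq_len(min(K, M))) {
    subsets <- utils::combn(M, size, simplify = FALSE)
    for (s in subsets) {
      sub <- simplex_max(D[, s, drop = FALSE], rep(1, K), rep(1, size))
      if (sub$objective >= objective - tol * (1 + objective)) {
        lambdas <- numeric(M)
        lambdas[s] <- pmax(sub$x, 0)
        return(lambdas)
      }
    }
  }
  NULL
}

#' @export
print.inner_lp_result <- function(x, ...) {
  cat(sprintf("<inner_lp_result> objective %.6g, support {%s}\n",
              x$objective, paste(x$basis_support, collapse = ", ")))
  invisible(x)
}
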