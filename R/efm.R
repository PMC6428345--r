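#' @keywords internal
#' Orthonormal nullspace basis via SVD; columns span {x : A x = 0}.
nullspace_basis <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  keep <- sv$d <= tol * max(sv$d[1], 1)
  n_zero <- ncol(A) - sum(sv$d > tol * max(sv$d[1], 1))
  if (n_zero == 0L) return(matrix(0, ncol(A), 0))
  sv$v[, (ncol(A) - n_zero + 1L):ncol(A), drop = FALSE]
}

matrix_rank <- function(A, tol = 1e-8) {
  if (length(A) == 0L) return(0L)
  qr(A, tol = tol)$rank
}

flux_support <- function(v, tol = 1e-10) which(abs(v) > tol)

#' @keywords internal
#' Scale rays to unit max-abs and clamp arithmetic noise to exact zero.
.clean_rays <- function(R, tol = 1e-10) {
  if (ncol(R) == 0L) return(R)
  R <- sweep(R, 2, apply(abs(R), 2, max), "/")
  R[abs(R) < tol] <- 0
  R
}

.dedupe_rays <- function(R, digits = 9L) {
  if (ncol(R) == 0L) return(R)
  key <- apply(round(R, digits), 2, paste, collapse = ",")
  R[, !duplicated(key), drop = FALSE]
}

.support_key <- function(support) paste(sprintf("%03d", support), collapse = "-")

.make_efm <- function(v, network, support_tol = 1e-10) {
  obj <- network$objective_index
  has_obj <- abs(v[obj]) > support_tol
  v <- if (has_obj) v / v[obj] else v / max(v)
  v[abs(v) < support_tol] <- 0
  if (has_obj) v[obj] <- 1
  structure(
    list(values = stats::setNames(v, network$reaction_ids),
         support = flux_support(v, support_tol),
         has_objective = has_obj),
    class = "efm")
}

#' @export
print.efm <- function(x, ...) {
  cat(sprintf("<efm> support {%s}%s\n",
              paste(names(x$values)[x$support], collapse = ", "),
              if (x$has_objective) ", objective-producing" else ""))
  invisible(x)
}

#' Collect EFMs into a reactions-by-modes matrix
#' @param efms list of `efm` objects.
#' @return numeric matrix, reactions in rows, one column per EFM.
#' @export
efm_matrix <- function(efms) {
  stopifnot(length(efms) > 0L)
  m <- do.call(cbind, lapply(efms, `[[`, "values"))
  colnames(m) <- paste0("efm", seq_along(efms))
  m
}

#' Enumerate Elementary Flux Modes of a small irreversible network
#'
#' EFMs are the support-minimal nonzero elements of the steady-state flux cone
#' `{v : N_internal v = 0, v >= 0}`; for fully irreversible networks they
#' coincide with the extreme rays of that pointed cone. The implementation is
#' a nullspace double-description method: it starts from generators of the
#' nullspace of the internal stoichiometry and processes the nonnegativity
#' constraint of one reaction at a time, combining positive/negative ray pairs.
#' Once the intermediate cone is pointed, rays whose tight constraint set is
#' strictly contained in another ray's are discarded; a final algebraic
#' elementarity test (`rank(N_internal[, support]) == |support| - 1`) keeps
#' exactly the extreme rays.
#'
#' @param network a `metabolic_network`; intended for desk-scale models.
#' @param size_limit refuse networks with more reactions than this (default 25).
#' @param tol numeric zero threshold for support membership after
#'   normalization (default 1e-10).
#' @return list of `efm` objects, each normalized so the objective entry is 1
#'   (when the mode produces objective flux) or the maximum entry is 1
#'   (otherwise), ordered lexicographically by support. Includes EFMs without
#'   objective flux, e.g. futile cycles; downstream optimization filters on
#'   `has_objective`.
#' @seealso [enumerate_efms_bruteforce()] for an exhaustive oracle.
#' @export
enumerate_efms <- function(network, size_limit = 25L, tol = 1e-10) {
  r <- length(network$reaction_ids)
  if (r > size_limit) {
    stop(sprintf("network has %d reactions; enumeration is limited to %d (raise size_limit deliberately for larger desk-scale models)",
                 r, size_limit))
  }
  ni <- internal_stoichiometry(network)
  kb <- nullspace_basis(ni)
  n_free <- ncol(kb)
  if (n_free == 0L) return(list())
  # pick pivot rows so the kernel basis carries an identity block there: the
  # initial cone {v in ker : v_pivots >= 0} is then pointed and generated by
  # the basis columns, so extreme-ray pruning is valid from the first step
  piv <- qr(t(kb))$pivot[seq_len(n_free)]
  rays <- .clean_rays(kb %*% solve(kb[piv, , drop = FALSE]), tol)
  processed <- sort(piv)
  prune_nonextreme <- function(rays, processed) {
    n <- ncol(rays)
    if (n <= 1L) return(rays)
    tight <- t(abs(rays[processed, , drop = FALSE]) <= tol)  # rays x constraints
    sizes <- rowSums(tight)
    keep <- rep(TRUE, n)
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a != b && sizes[b] > sizes[a] && all(tight[b, ] | !tight[a, ])) {
          keep[a] <- FALSE
          break
        }
      }
    }
    rays[, keep, drop = FALSE]
  }
  for (j in setdiff(seq_len(r), piv)) {
    vals <- rays[j, ]
    pos <- rays[, vals > tol, drop = FALSE]
    zero <- rays[, abs(vals) <= tol, drop = FALSE]
    neg <- rays[, vals < -tol, drop = FALSE]
    combos <- NULL
    if (ncol(pos) > 0L && ncol(neg) > 0L) {
      combos <- matrix(0, r, ncol(pos) * ncol(neg))
      idx <- 0L
      for (a in seq_len(ncol(pos))) {
        for (b in seq_len(ncol(neg))) {
          idx <- idx + 1L
          w <- pos[, a] * abs(neg[j, b]) + neg[, b] * pos[j, a]
          w[j] <- 0
          combos[, idx] <- w
        }
      }
    }
    rays <- .dedupe_rays(.clean_rays(cbind(pos, zero, combos), tol))
    processed <- sort(c(processed, j))
    rays <- prune_nonextreme(rays, processed)
  }
  if (ncol(rays) == 0L) return(list())
  # elementarity: extreme rays of the irreversible cone satisfy the rank test
  is_efm <- vapply(seq_len(ncol(rays)), function(i) {
    s <- flux_support(rays[, i], tol)
    length(s) > 0L && min(rays[s, i]) > 0 &&
      matrix_rank(ni[, s, drop = FALSE]) == length(s) - 1L
  }, logical(1))
  rays <- .dedupe_rays(rays[, is_efm, drop = FALSE])
  efms <- lapply(seq_len(ncol(rays)), function(i) .make_efm(rays[, i], network, tol))
  efms[order(vapply(efms, function(e) .support_key(e$support), character(1)))]
}

#' Exhaustive EFM enumeration by support subsets (independent oracle)
#'
#' Tests, for every subset of reactions, whether the internal stoichiometry
#' restricted to that support has a one-dimensional kernel spanned by a
#' strictly positive vector with full support. This is exponential in the
#' number of reactions and is meant as an independent cross-check of
#' [enumerate_efms()] on tiny networks.
#'
#' @inheritParams enumerate_efms
#' @return list of `efm` objects, same normalization and ordering as
#'   [enumerate_efms()].
#' @export
enumerate_efms_bruteforce <- function(network, tol = 1e-10) {
  r <- length(network$reaction_ids)
  if (r > 12L) stop("brute-force enumeration is exponential; limited to 12 reactions")
  ni <- internal_stoichiometry(network)
  found <- list()
  for (mask in seq_len(2^r - 1L)) {
    s <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(r) - 1L)) != 0L)
    kb <- nullspace_basis(ni[, s, drop = FALSE])
    if (ncol(kb) != 1L) next
    k <- kb[, 1]
    if (min(abs(k)) <= 1e-8 * max(abs(k))) next  # kernel vector must have full support
    if (max(k) * min(k) < 0) next                # entries must share one sign
    v <- numeric(r)
    v[s] <- abs(k)
    found[[length(found) + 1L]] <- v
  }
  if (length(found) == 0L) return(list())
  supports <- lapply(found, flux_support, tol = tol)
  minimal <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      j != i && length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]])
    }, logical(1)))
  }, logical(1))
  efms <- lapply(found[minimal], .make_efm, network = network, support_tol = tol)
  efms[order(vapply(efms, function(e) .support_key(e$support), character(1)))]
}

#' Rescale an EFM to unit objective flux
#'
#' @param efm an `efm` object with nonzero objective entry.
#' @param network the `metabolic_network` the EFM belongs to.
#' @return the EFM scaled so the objective entry equals 1; support unchanged.
#' @export
normalize_to_objective <- function(efm, network) {
  obj <- network$objective_index
  if (abs(efm$values[obj]) <= 1e-300 || !efm$has_objective) {
    stop(sprintf("EFM with support {%s} carries no objective flux and cannot be normalized to it",
                 paste(names(efm$values)[efm$support], collapse = ", ")))
  }
  efm$values <- efm$values / efm$values[obj]
  efm$has_objective <- TRUE
  efm
}

#' Decompose a steady-state flux vector into EFM weights
#'
#' Solves the nonnegative least-squares problem `min || E lambda - v ||_2`
#' over `lambda >= 0`, where `E` stacks the EFMs column-wise. When the number
#' of EFMs exceeds the rank of `E`, the weight vector is not unique; the
#' deterministic active-set solution of the nonnegative least-squares solver
#' is returned.
#'
#' @param network a `metabolic_network`.
#' @param v steady-state flux vector (checked; error when it is not in the
#'   flux cone).
#' @param efms list of `efm` objects, typically from [enumerate_efms()].
#' @param tol residual certification tolerance (default [steady_state_tol()]).
#' @return list with `lambdas` (nonnegative, length `length(efms)`),
#'   `residual` (Euclidean norm), and `certified` (`TRUE` when the residual is
#'   below `tol * (1 + ||v||)`, certifying membership of the EFM cone).
#' @export
decompose_flux <- function(network, v, efms, tol = steady_state_tol(v)) {
  v <- as.numeric(v)
  if (!check_steady_state(network, v)) {
    stop("flux vector is not a steady-state cone element; cannot decompose")
  }
  E <- efm_matrix(efms)
  fit <- pracma::lsqnonneg(E, v)
  residual <- sqrt(sum((E %*% fit$x - v)^2))
  list(lambdas = as.numeric(fit$x),
       residual = residual,
       certified = residual <= tol * (1 + sqrt(sum(v^2))))
}
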