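#' Construct a metabolic network
#'
#' A metabolic network is a stoichiometric matrix over irreversible reactions
#' together with a partition of metabolites into external (environment-supplied,
#' not balanced) and internal (balanced at steady state), and one designated
#' objective reaction whose flux is maximized downstream.
#'
#' @param stoichiometry numeric matrix, metabolites in rows, reactions in
#'   columns. Dimensionless stoichiometric coefficients (mol/mol).
#' @param metabolite_ids character vector of row identifiers.
#' @param reaction_ids character vector of column identifiers.
#' @param is_external logical vector (or named logical) marking external
#'   metabolites; external rows are treated as unconstrained sources/sinks.
#' @param objective id or index of the objective reaction.
#' @return object of class `metabolic_network` with elements `stoichiometry`,
#'   `metabolite_ids`, `reaction_ids`, `is_external`, `objective_index`.
#' @examples
#' net <- metabolic_network(
#'   stoichiometry = matrix(c(-1, 1, 0, -1), 2, 2,
#'     dimnames = list(c("S", "A"), c("uptake", "growth"))),
#'   metabolite_ids = c("S", "A"),
#'   reaction_ids = c("uptake", "growth"),
#'   is_external = c(TRUE, FALSE),
#'   objective = "growth")
#' check_steady_state(net, c(1, 1))
#' @export
metabolic_network <- function(stoichiometry, metabolite_ids = rownames(stoichiometry),
                              reaction_ids = colnames(stoichiometry),
                              is_external, objective) {
  stoichiometry <- as.matrix(stoichiometry)
  storage.mode(stoichiometry) <- "double"
  m <- nrow(stoichiometry)
  r <- ncol(stoichiometry)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("m", seq_len(m))
  if (is.null(reaction_ids)) reaction_ids <- paste0("r", seq_len(r))
  if (length(metabolite_ids) != m) stop("metabolite_ids length does not match row count")
  if (length(reaction_ids) != r) stop("reaction_ids length does not match column count")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (!is.null(names(is_external))) is_external <- is_external[metabolite_ids]
  is_external <- as.logical(is_external)
  if (length(is_external) != m || anyNA(is_external)) {
    stop("is_external must cover every metabolite")
  }
  obj <- if (is.character(objective)) match(objective, reaction_ids) else as.integer(objective)
  if (is.na(obj) || obj < 1L || obj > r) stop("objective reaction not found in network")
  zero_col <- apply(abs(stoichiometry), 2, max) == 0
  if (any(zero_col)) {
    stop("reaction(s) with all-zero stoichiometry: ",
         paste(reaction_ids[zero_col], collapse = ", "))
  }
  if (r > 1L && !any(!is_external)) {
    stop("network with more than one reaction must have at least one internal metabolite")
  }
  dimnames(stoichiometry) <- list(metabolite_ids, reaction_ids)
  structure(
    list(stoichiometry = stoichiometry,
         metabolite_ids = metabolite_ids,
         reaction_ids = reaction_ids,
         is_external = stats::setNames(is_external, metabolite_ids),
         objective_index = obj),
    class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites (%d internal), %d reactions, objective '%s'\n",
              length(x$metabolite_ids), sum(!x$is_external),
              length(x$reaction_ids), x$reaction_ids[x$objective_index]))
  invisible(x)
}

#' Stoichiometric matrix restricted to internal metabolites
#'
#' @param network a `metabolic_network`.
#' @return numeric matrix with only the balanced (internal) rows. May have zero
#'   rows when every metabolite is external.
#' @export
internal_stoichiometry <- function(network) {
  network$stoichiometry[!network$is_external, , drop = FALSE]
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Replaces each reversible column by a forward copy and a negated backward
#' copy so that all reactions of the returned network are irreversible and the
#' flux cone is pointed. Any steady-state flux of the original network maps to
#' a nonnegative steady-state flux of the split network by assigning the
#' positive part to the forward and the negative part to the backward column.
#'
#' @param stoichiometry numeric matrix of the raw network.
#' @param reversible logical vector, one flag per reaction.
#' @param metabolite_ids,reaction_ids,is_external,objective as in
#'   [metabolic_network()].
#' @return a `metabolic_network` with `r_irrev + 2 * r_rev` columns; split
#'   columns are suffixed `_fwd` / `_bwd`.
#' @export
split_reversible <- function(stoichiometry, reversible,
                             metabolite_ids = rownames(stoichiometry),
                             reaction_ids = colnames(stoichiometry),
                             is_external, objective) {
  stoichiometry <- as.matrix(stoichiometry)
  r <- ncol(stoichiometry)
  if (is.null(reaction_ids)) reaction_ids <- paste0("r", seq_len(r))
  reversible <- as.logical(reversible)
  if (length(reversible) != r) stop("one reversibility flag per reaction required")
  obj <- if (is.character(objective)) match(objective, reaction_ids) else as.integer(objective)
  if (is.na(obj) || obj < 1L || obj > r) stop("objective reaction not found in network")
  if (reversible[obj]) {
    stop("objective reaction must be a single irreversible flux; split it upstream of model building")
  }
  cols <- vector("list", r)
  ids <- vector("list", r)
  for (j in seq_len(r)) {
    if (reversible[j]) {
      cols[[j]] <- cbind(stoichiometry[, j], -stoichiometry[, j])
      ids[[j]] <- paste0(reaction_ids[j], c("_fwd", "_bwd"))
    } else {
      cols[[j]] <- stoichiometry[, j, drop = FALSE]
      ids[[j]] <- reaction_ids[j]
    }
  }
  new_s <- do.call(cbind, cols)
  new_ids <- unlist(ids)
  new_obj <- which(new_ids == reaction_ids[obj])
  metabolic_network(new_s, metabolite_ids = metabolite_ids, reaction_ids = new_ids,
                    is_external = is_external, objective = new_obj)
}

#' Default steady-state tolerance, relative to the flux scale
#' @param v numeric flux vector.
#' @return scalar tolerance `1e-9 * (1 + max(abs(v)))`.
#' @export
steady_state_tol <- function(v) 1e-9 * (1 + max(abs(v), 0))

#' Test whether a flux vector lies in the steady-state flux cone
#'
#' Balance is enforced over internal metabolite rows only; external rows are
#' unconstrained sources and sinks. Fluxes must be nonnegative up to `tol`
#' because all reactions are irreversible by convention.
#'
#' @param network a `metabolic_network`.
#' @param v numeric flux vector of length `r`.
#' @param tol nonnegative tolerance; defaults to [steady_state_tol()].
#' @return `TRUE` iff `max |N_internal %*% v| <= tol` and `min(v) >= -tol`.
#' @export
check_steady_state <- function(network, v, tol = steady_state_tol(v)) {
  v <- as.numeric(v)
  if (length(v) != length(network$reaction_ids)) {
    stop("flux vector length does not match the number of reactions")
  }
  if (tol <= 0) stop("tol must be positive")
  ni <- internal_stoichiometry(network)
  balance_ok <- nrow(ni) == 0L || max(abs(ni %*% v)) <= tol
  balance_ok && min(v) >= -tol
}
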