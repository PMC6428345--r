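#' Saturation function specifications
#'
#' The saturation function `f(x)` of an enzyme scales its rate below the
#' `kcat` maximum and takes values in `[0, 1]` for nonnegative metabolite
#' concentrations. Three kinds are supported:
#' \describe{
#'   \item{`constant`}{`f == 1` (fully saturated enzyme).}
#'   \item{`michaelis_menten`}{product over substrates of `x_s / (Km_s + x_s)`.}
#'   \item{`mm_product_inhibition`}{Michaelis-Menten multiplied by a
#'     non-competitive inhibition factor `1 / (1 + x_inh / Ki)`.}
#' }
#' A `custom` kind can be registered with [register_saturation_kind()] for
#' extensions; unregistered kinds are rejected at validation.
#'
#' @param kind one of `"constant"`, `"michaelis_menten"`,
#'   `"mm_product_inhibition"`, or a registered custom kind.
#' @param substrate_ids metabolite ids the function saturates in.
#' @param Km named numeric vector of Michaelis constants (> 0, concentration
#'   units), one per substrate.
#' @param inhibitor_id optional metabolite id of the inhibitor.
#' @param Ki optional inhibition constant (> 0).
#' @return object of class `saturation_spec`.
#' @export
saturation_spec <- function(kind, substrate_ids = character(), Km = numeric(),
                            inhibitor_id = NULL, Ki = NULL) {
  kind <- match.arg(kind, c("constant", "michaelis_menten", "mm_product_inhibition",
                            names(.saturation_registry$kinds)))
  if (kind %in% c("michaelis_menten", "mm_product_inhibition")) {
    if (length(substrate_ids) == 0L) stop("saturating kinds need at least one substrate")
    if (is.null(names(Km))) names(Km) <- substrate_ids
    Km <- Km[substrate_ids]
    if (anyNA(Km) || any(Km <= 0)) stop("Km must be positive and cover every substrate")
  }
  if (kind == "mm_product_inhibition") {
    if (is.null(inhibitor_id) || is.null(Ki)) stop("mm_product_inhibition needs inhibitor_id and Ki")
    if (Ki <= 0) stop("Ki must be positive")
  }
  structure(list(kind = kind, substrate_ids = substrate_ids, Km = Km,
                 inhibitor_id = inhibitor_id, Ki = Ki),
            class = "saturation_spec")
}

.saturation_registry <- new.env(parent = emptyenv())
.saturation_registry$kinds <- list()

#' Register a custom saturation kind
#'
#' Extension hook: registers an evaluator `function(spec, x)` returning a
#' value in `[0, 1]`. Models using unregistered kinds fail validation.
#'
#' @param name kind name.
#' @param fn evaluator taking the `saturation_spec` and a named concentration
#'   vector.
#' @export
register_saturation_kind <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .saturation_registry$kinds[[name]] <- fn
  invisible(name)
}

#' Evaluate a saturation function
#'
#' @param spec a `saturation_spec`.
#' @param x named numeric vector of nonnegative metabolite concentrations;
#'   must contain every metabolite the spec references.
#' @return scalar in `[0, 1]`.
#' @export
saturation_value <- function(spec, x) {
  needed <- c(spec$substrate_ids, spec$inhibitor_id)
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    stop("metabolite concentration(s) missing from state: ", paste(missing, collapse = ", "))
  }
  f <- switch(spec$kind,
    constant = 1,
    michaelis_menten = prod(x[spec$substrate_ids] / (spec$Km + x[spec$substrate_ids])),
    mm_product_inhibition = {
      mm <- prod(x[spec$substrate_ids] / (spec$Km + x[spec$substrate_ids]))
      mm / (1 + x[spec$inhibitor_id] / spec$Ki)
    },
    {
      fn <- .saturation_registry$kinds[[spec$kind]]
      if (is.null(fn)) stop("unknown saturation kind: ", spec$kind)
      fn(spec, x)
    })
  unname(f)
}

#' Per-reaction kinetics: turnover number plus saturation function
#'
#' @param kcat maximal per-enzyme turnover (> 0, flux per enzyme
#'   concentration).
#' @param saturation a `saturation_spec`.
#' @return object of class `reaction_kinetics`.
#' @export
reaction_kinetics <- function(kcat, saturation = saturation_spec("constant")) {
  if (!is.numeric(kcat) || length(kcat) != 1L || kcat <= 0) stop("kcat must be a positive scalar")
  structure(list(kcat = kcat, saturation = saturation), class = "reaction_kinetics")
}

#' Weighted enzyme-pool constraints
#'
#' Each of the K constraints is a weighted sum of enzyme concentrations
#' bounded by a pool capacity: `sum_j w_j^(k) e_j <= bound_k`. One enzyme may
#' belong to one, several, or none of the pools. Internally all cost
#' computations rescale weights by the bounds so feasibility reads
#' `usage <= 1` per pool.
#'
#' @param weights K x r nonnegative matrix (pools in rows, reactions in
#'   columns); no all-zero row.
#' @param bounds length-K positive vector of pool capacities.
#' @param pool_ids optional pool identifiers (default `pool1..poolK`).
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(weights, bounds, pool_ids = NULL) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (any(weights < 0)) stop("constraint weights must be nonnegative")
  if (any(apply(weights, 1, max) == 0)) stop("constraint with all-zero weights is meaningless")
  bounds <- as.numeric(bounds)
  if (length(bounds) != nrow(weights)) stop("one bound per constraint required")
  if (any(bounds <= 0)) stop("pool bounds must be positive")
  if (is.null(pool_ids)) pool_ids <- rownames(weights)
  if (is.null(pool_ids)) pool_ids <- paste0("pool", seq_len(nrow(weights)))
  rownames(weights) <- pool_ids
  structure(list(weights = weights, bounds = stats::setNames(bounds, pool_ids),
                 pool_ids = pool_ids),
            class = "constraint_set")
}

#' Assemble a kinetic metabolic model
#'
#' @param network a `metabolic_network`.
#' @param kinetics named list of `reaction_kinetics`, one per reaction.
#' @param constraints a `constraint_set` whose columns align with the
#'   network's reaction order.
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(network, kinetics, constraints) {
  stopifnot(inherits(network, "metabolic_network"), inherits(constraints, "constraint_set"))
  rids <- network$reaction_ids
  missing <- setdiff(rids, names(kinetics))
  if (length(missing) > 0L) stop("kinetics missing for reaction(s): ", paste(missing, collapse = ", "))
  kinetics <- kinetics[rids]
  if (ncol(constraints$weights) != length(rids)) {
    stop("constraint weight columns do not align with the reaction order")
  }
  colnames(constraints$weights) <- rids
  mids <- network$metabolite_ids
  for (id in rids) {
    rk <- kinetics[[id]]
    if (!inherits(rk, "reaction_kinetics")) stop("kinetics for ", id, " is not a reaction_kinetics object")
    refs <- c(rk$saturation$substrate_ids, rk$saturation$inhibitor_id)
    unknown <- setdiff(refs, mids)
    if (length(unknown) > 0L) {
      stop("saturation of ", id, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    if (!rk$saturation$kind %in% c("constant", "michaelis_menten", "mm_product_inhibition") &&
        is.null(.saturation_registry$kinds[[rk$saturation$kind]])) {
      stop("unregistered saturation kind '", rk$saturation$kind, "' for reaction ", id)
    }
  }
  structure(list(network = network, kinetics = kinetics, constraints = constraints),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  print(x$network)
  cat(sprintf("  %d enzyme pool constraint(s): %s\n",
              length(x$constraints$bounds),
              paste(sprintf("%s<=%g", names(x$constraints$bounds), x$constraints$bounds),
                    collapse = ", ")))
  invisible(x)
}

#' Reaction rate under the linear-in-enzyme rate law
#'
#' `v = e * kcat * f(x)`: the rate is proportional to the enzyme
#' concentration at fixed metabolite concentrations, with the saturation
#' function capturing all concentration dependence.
#'
#' @param rk a `reaction_kinetics`.
#' @param e nonnegative enzyme concentration.
#' @param x named numeric concentration vector.
#' @return scalar flux.
#' @export
reaction_rate <- function(rk, e, x) {
  if (e < 0) stop("enzyme concentration must be nonnegative")
  e * rk$kcat * saturation_value(rk$saturation, x)
}

#' Enzyme concentrations needed by one EFM per unit objective flux
#'
#' For an EFM normalized to unit objective flux, the enzyme demand of
#' reaction j is `V_j / (kcat_j * f_j(x))` on the support and zero elsewhere.
#'
#' @param efm an `efm` normalized to unit objective flux.
#' @param x named numeric concentration vector covering all referenced
#'   metabolites.
#' @param model a `kinetic_model`.
#' @return named nonnegative vector of enzyme concentrations, length r.
#' @export
enzyme_demand <- function(efm, x, model) {
  rids <- model$network$reaction_ids
  e <- stats::setNames(numeric(length(rids)), rids)
  for (j in efm$support) {
    rk <- model$kinetics[[rids[j]]]
    f <- saturation_value(rk$saturation, x)
    if (f <= 0) {
      stop(sprintf("EFM infeasible at this state: saturation of reaction '%s' is zero", rids[j]))
    }
    e[j] <- efm$values[j] / (rk$kcat * f)
  }
  e
}

#' Usage of each constrained enzyme pool by an enzyme profile
#'
#' @param e nonnegative enzyme concentration vector, length r.
#' @param cs a `constraint_set`.
#' @return length-K vector `W %*% e` of raw pool usages; compare against
#'   `cs$bounds`.
#' @export
constraint_usage <- function(e, cs) {
  e <- as.numeric(e)
  if (length(e) != ncol(cs$weights)) stop("enzyme vector length does not match constraint columns")
  if (any(e < 0)) stop("enzyme concentrations must be nonnegative")
  drop(cs$weights %*% e)
}

#' @keywords internal
#' Compile the per-reaction saturation functions into one vector-valued
#' evaluator over the full concentration vector, avoiding repeated S3
#' dispatch in optimization inner loops. Returns function(x) -> f (length r).
.compile_saturation <- function(model) {
  mids <- model$network$metabolite_ids
  rids <- model$network$reaction_ids
  r_n <- length(rids)
  sub_idx <- vector("list", r_n); km_list <- vector("list", r_n)
  inh_idx <- integer(r_n); ki_vec <- numeric(r_n); custom <- vector("list", r_n)
  for (j in seq_len(r_n)) {
    sat <- model$kinetics[[j]]$saturation
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
  function(x) {
    f <- rep(1, r_n)
    for (j in seq_len(r_n)) {
      if (!is.null(sub_idx[[j]])) {
        xs <- x[sub_idx[[j]]]
        f[j] <- prod(xs / (km_list[[j]] + xs))
        if (inh_idx[j] > 0L) f[j] <- f[j] / (1 + x[inh_idx[j]] / ki_vec[j])
      } else if (!is.null(custom[[j]])) {
        f[j] <- saturation_value(custom[[j]], x)
      }
    }
    f
  }
}
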