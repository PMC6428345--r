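#' Coarse-grained overflow-metabolism model
#'
#' A four-reaction core model with two objective-producing EFMs: external
#' glucose is imported by a membrane transporter (Michaelis-Menten in
#' glucose) into an internal intermediate, which is converted to a biomass
#' precursor either by a high-yield respiration reaction (1 precursor per
#' intermediate) or by a low-yield overflow reaction with a higher catalytic
#' rate (1 precursor per 2 intermediates, excreting acetate). The objective
#' is the biomass drain. Two enzyme pools constrain expression: cytosolic
#' enzyme (respiration + overflow, bound 1) and membrane area (transporter,
#' bound 0.3). The kinetic parameters are package constants chosen so that a
#' respirofermentative switch falls inside the default substrate sweep range:
#' transporter kcat 10, Km 1; respiration kcat 2, Km 0.5; overflow kcat 6,
#' Km 0.5; biomass drain kcat 1.
#'
#' @return a `kinetic_model`.
#' @export
build_overflow_model <- function() {
  s <- matrix(0, nrow = 4, ncol = 4,
              dimnames = list(c("glc_ext", "intermediate", "ac_ext", "precursor"),
                              c("transport", "respiration", "overflow", "biomass")))
  s["glc_ext", "transport"] <- -1
  s["intermediate", "transport"] <- 1
  s["intermediate", "respiration"] <- -1
  s["precursor", "respiration"] <- 1
  s["intermediate", "overflow"] <- -2
  s["precursor", "overflow"] <- 1
  s["ac_ext", "overflow"] <- 1
  s["precursor", "biomass"] <- -1
  net <- metabolic_network(s,
                           is_external = c(glc_ext = TRUE, intermediate = FALSE,
                                           ac_ext = TRUE, precursor = FALSE),
                           objective = "biomass")
  kin <- list(
    transport = reaction_kinetics(10, saturation_spec("michaelis_menten", "glc_ext", c(glc_ext = 1))),
    respiration = reaction_kinetics(2, saturation_spec("michaelis_menten", "intermediate", c(intermediate = 0.5))),
    overflow = reaction_kinetics(6, saturation_spec("michaelis_menten", "intermediate", c(intermediate = 0.5))),
    biomass = reaction_kinetics(1))
  w <- rbind(cytosol = c(0, 1, 1, 0), membrane = c(1, 0, 0, 0))
  colnames(w) <- colnames(s)
  kinetic_model(net, kin, constraint_set(w, c(cytosol = 1, membrane = 0.3)))
}

#' Coarse-grained model of the L. lactis fermentation switch
#'
#' Glucose feeds ATP production through two pathways with different ATP
#' yields and different strengths of non-competitive product inhibition by
#' ATP: a mixed-acid pathway (yield 3 ATP per glucose, strong inhibition,
#' high glucose affinity) and a homolactic pathway (yield 2 ATP per glucose,
#' weak inhibition, low glucose affinity). ATP drives the biomass objective
#' (Michaelis-Menten in ATP). Enzyme expression is constrained by a total
#' cytosolic pool over all three enzymes (bound 1) and an uptake-machinery
#' pool over the two fermentation pathways with unequal weights (the
#' coarse-grained pathways embed different shares of transport machinery per
#' enzyme unit), bound 0.42. The parameters are package constants chosen so
#' that increasing external glucose moves the optimal flux fraction from
#' mixed-acid to homolactic fermentation while the optimal enzyme
#' concentrations stay nearly constant: the homolactic saturation rises
#' steeply with glucose while rising ATP increasingly inhibits the
#' mixed-acid pathway.
#'
#' @return a `kinetic_model`.
#' @export
build_lactis_model <- function() {
  s <- matrix(0, nrow = 2, ncol = 3,
              dimnames = list(c("glc_ext", "atp"),
                              c("mixed_acid", "homolactic", "biomass")))
  s["glc_ext", "mixed_acid"] <- -1
  s["atp", "mixed_acid"] <- 3
  s["glc_ext", "homolactic"] <- -1
  s["atp", "homolactic"] <- 2
  s["atp", "biomass"] <- -1
  net <- metabolic_network(s, is_external = c(glc_ext = TRUE, atp = FALSE),
                           objective = "biomass")
  kin <- list(
    mixed_acid = reaction_kinetics(
      2.7, saturation_spec("mm_product_inhibition", "glc_ext", c(glc_ext = 0.4),
                           inhibitor_id = "atp", Ki = 0.65)),
    homolactic = reaction_kinetics(
      2.5, saturation_spec("mm_product_inhibition", "glc_ext", c(glc_ext = 25),
                           inhibitor_id = "atp", Ki = 14)),
    biomass = reaction_kinetics(2.7, saturation_spec("michaelis_menten", "atp", c(atp = 0.3))))
  w <- rbind(total = c(1, 1, 1), uptake = c(6.5, 0.02, 0))
  colnames(w) <- colnames(s)
  kinetic_model(net, kin, constraint_set(w, c(total = 1, uptake = 0.42)))
}

#' Optimize growth along a grid of external substrate concentrations
#'
#' Runs [optimize_growth()] once per grid point, warm-starting each point
#' with the previous optimum, and tabulates the objective value, the weight
#' and substrate-uptake flux of every objective EFM, the optimal enzyme
#' profile, and the set of active constraints.
#'
#' @param model a `kinetic_model`.
#' @param substrate_grid strictly positive, ascending concentrations of the
#'   swept external substrate.
#' @param substrate_id id of the swept metabolite; defaults to the first
#'   external metabolite referenced by a saturation function.
#' @param x_external_base named vector of further external concentrations
#'   (default none).
#' @param options passed to [optimize_growth()]; defaults to 8 starts here
#'   since warm starting carries the previous optimum along the grid.
#' @return data.frame of class `sweep_table` with columns `substrate`, `mu`,
#'   `lambda_<efm>`, `uptake_<efm>`, `e_<reaction>`, `active_constraints`
#'   (semicolon-separated pool ids).
#' @export
sweep_external_substrate <- function(model, substrate_grid, substrate_id = NULL,
                                     x_external_base = NULL, options = list()) {
  if (any(substrate_grid <= 0) || is.unsorted(substrate_grid, strictly = TRUE)) {
    stop("substrate_grid must be positive and strictly ascending")
  }
  if (is.null(substrate_id)) {
    ext <- .external_refs(model)
    if (length(ext) == 0L) stop("model has no external metabolite in any saturation function")
    substrate_id <- ext[1]
  }
  opts <- utils::modifyList(list(n_starts = 8L), options)
  efms <- objective_efms(model)
  rids <- model$network$reaction_ids
  srow <- model$network$stoichiometry[substrate_id, ]
  uptake_per_unit <- vapply(efms, function(e) sum(pmax(-srow, 0) * e$values), numeric(1))
  rows <- vector("list", length(substrate_grid))
  warm <- list()
  for (i in seq_along(substrate_grid)) {
    x_ext <- c(stats::setNames(substrate_grid[i], substrate_id), x_external_base)
    res <- optimize_growth(model, x_ext,
                           utils::modifyList(opts, list(warm_starts = warm)))
    warm <- list(res$x_internal)
    lam <- res$inner$lambdas
    row <- c(list(substrate = substrate_grid[i], mu = res$objective),
             stats::setNames(as.list(lam), paste0("lambda_", names(lam))),
             stats::setNames(as.list(lam * uptake_per_unit),
                             paste0("uptake_", names(lam))),
             stats::setNames(as.list(res$enzyme_profile), paste0("e_", rids)),
             list(active_constraints = paste(res$active_constraints, collapse = ";")))
    rows[[i]] <- as.data.frame(row, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Detect the critical substrate concentration in a two-EFM sweep
#'
#' Scans the EFM-weight columns of a sweep table for the smallest substrate
#' value at which the EFM that is inactive at the start of the sweep carries
#' a weight above `tol` times the largest weight in that row — the onset of
#' the second pathway (e.g. overflow products).
#'
#' @param sweep a `sweep_table` (or any data.frame with `substrate` and
#'   `lambda_*` columns).
#' @param tol relative activation threshold (default 1e-6).
#' @return the critical substrate concentration, or `NULL` when no second
#'   EFM ever activates.
#' @export
detect_critical_point <- function(sweep, tol = 1e-6) {
  lam_cols <- grep("^lambda_", names(sweep), value = TRUE)
  if (length(lam_cols) == 0L) stop("sweep table has no lambda_ columns")
  lam <- as.matrix(sweep[, lam_cols, drop = FALSE])
  first_max <- max(lam[1, ])
  inactive <- which(lam[1, ] <= tol * max(first_max, .Machine$double.eps))
  if (length(inactive) == 0L) return(NULL)
  crossings <- c()
  for (j in inactive) {
    hit <- which(lam[, j] > tol * apply(lam, 1, max))
    if (length(hit) > 0L) crossings <- c(crossings, sweep$substrate[min(hit)])
  }
  if (length(crossings) == 0L) NULL else min(crossings)
}

#' Rescale the enzyme-pool bounds of a model
#'
#' Emulates perturbations that shrink (or relax) the limited enzyme pools,
#' e.g. the expression of a non-functional protein occupying part of a pool.
#'
#' @param model a `kinetic_model`.
#' @param factors positive factors, one per constraint.
#' @return the model with `bounds * factors`; everything else unchanged.
#' @export
perturb_pool_bounds <- function(model, factors) {
  factors <- as.numeric(factors)
  if (length(factors) != length(model$constraints$bounds)) {
    stop("one factor per constraint required")
  }
  if (any(factors <= 0)) stop("pool-bound factors must be positive")
  model$constraints$bounds <- model$constraints$bounds * factors
  model
}

#' Rescale catalytic rates of selected reactions
#'
#' Emulates enzyme inhibition: lowering a reaction's kcat raises that
#' reaction's enzyme demand in every EFM proportionally, lengthening the
#' cost vectors.
#'
#' @param model a `kinetic_model`.
#' @param reaction_factors named positive factors, names are reaction ids.
#' @return the model with the selected `kcat` values multiplied.
#' @export
perturb_catalytic_rates <- function(model, reaction_factors) {
  if (is.null(names(reaction_factors))) stop("reaction_factors must be named by reaction id")
  unknown <- setdiff(names(reaction_factors), model$network$reaction_ids)
  if (length(unknown) > 0L) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  if (any(reaction_factors <= 0)) stop("catalytic-rate factors must be positive")
  for (id in names(reaction_factors)) {
    model$kinetics[[id]]$kcat <- model$kinetics[[id]]$kcat * reaction_factors[[id]]
  }
  model
}

#' Fit a proportional-plus-breakpoint model to chemostat uptake data
#'
#' Below a critical growth rate, single-EFM usage makes uptake rates exactly
#' proportional to the growth rate; the onset of a second EFM bends the
#' relation. This fits a through-origin line up to a candidate breakpoint
#' continuing with a free-slope segment beyond it, choosing the breakpoint by
#' grid search over the midpoints of consecutive growth rates. When the
#' two-segment fit improves the total squared error of the single
#' through-origin line by less than 5%, no breakpoint is reported.
#'
#' @param growth_rates,uptake_rates nonnegative numeric vectors (>= 4
#'   points).
#' @return object of class `breakpoint_fit`: `slope` (uptake per growth rate
#'   on the proportional segment), `slope_post` (slope beyond the
#'   breakpoint, `NA` without one), `critical_rate` (breakpoint growth rate
#'   or `NA`), `sse`.
#' @export
fit_proportional_breakpoint <- function(growth_rates, uptake_rates) {
  if (length(growth_rates) < 4L) stop("at least 4 data points are required")
  if (length(growth_rates) != length(uptake_rates)) stop("input lengths differ")
  if (any(growth_rates < 0) || any(uptake_rates < 0)) {
    stop("growth and uptake rates must be nonnegative")
  }
  ord <- order(growth_rates)
  mu <- growth_rates[ord]; q <- uptake_rates[ord]
  fit1 <- stats::lm(q ~ mu - 1)
  sse1 <- sum(stats::residuals(fit1)^2)
  mids <- (mu[-1] + mu[-length(mu)]) / 2
  mids <- mids[mids > mu[2] & mids < mu[length(mu) - 1L]]  # both segments need support
  best <- list(sse = Inf)
  for (b in unique(mids)) {
    m1 <- pmin(mu, b)
    m2 <- pmax(mu - b, 0)
    fit2 <- stats::lm(q ~ m1 + m2 - 1)
    sse2 <- sum(stats::residuals(fit2)^2)
    if (sse2 < best$sse) {
      best <- list(sse = sse2, b = b, a = unname(stats::coef(fit2)[1]),
                   d = unname(stats::coef(fit2)[2]))
    }
  }
  proportional_exact <- sse1 <= 1e-12 * max(sum(q^2), .Machine$double.eps)
  if (proportional_exact || !is.finite(best$sse) || best$sse >= 0.95 * sse1) {
    out <- list(slope = unname(stats::coef(fit1)[1]), slope_post = NA_real_,
                critical_rate = NA_real_, sse = sse1)
  } else {
    out <- list(slope = best$a, slope_post = best$d,
                critical_rate = best$b, sse = best$sse)
  }
  structure(out, class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (is.na(x$critical_rate)) {
    cat(sprintf("<breakpoint_fit> proportional: slope %.4g (sse %.3g), no breakpoint\n",
                x$slope, x$sse))
  } else {
    cat(sprintf("<breakpoint_fit> slope %.4g up to critical rate %.4g, then %.4g (sse %.3g)\n",
                x$slope, x$critical_rate, x$slope_post, x$sse))
  }
  invisible(x)
}
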