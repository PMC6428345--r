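#' Configuration for the random model-instance generator
#'
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param n_internal number of internal metabolites (2-6).
#' @param n_reactions number of reactions (4-10, at least `n_internal + 1`).
#' @param n_constraints number of enzyme pools (1-3).
#' @param stoich_values candidate stoichiometric coefficients for extra
#'   reactions.
#' @param kcat_range,Km_range log-uniform sampling ranges for kinetic
#'   parameters.
#' @param weight_sparsity probability that a reaction joins a given pool.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed, n_internal = 3L, n_reactions = 6L,
                             n_constraints = 2L, stoich_values = c(-2, -1, 1, 2),
                             kcat_range = c(0.1, 10), Km_range = c(0.1, 10),
                             weight_sparsity = 0.7) {
  stopifnot(n_internal >= 2L, n_internal <= 6L,
            n_reactions >= 4L, n_reactions <= 10L,
            n_reactions >= n_internal + 1L,
            n_constraints >= 1L, n_constraints <= 3L,
            all(kcat_range > 0), all(Km_range > 0),
            weight_sparsity > 0, weight_sparsity <= 1)
  structure(list(seed = as.integer(seed), n_internal = as.integer(n_internal),
                 n_reactions = as.integer(n_reactions),
                 n_constraints = as.integer(n_constraints),
                 stoich_values = stoich_values, kcat_range = kcat_range,
                 Km_range = Km_range, weight_sparsity = weight_sparsity),
            class = "generator_config")
}

#' @keywords internal
#' One candidate instance under the current RNG stream; may violate the
#' standing assumptions, in which case generate_instance retries.
.draw_instance <- function(cfg) {
  n <- cfg$n_internal
  internal_ids <- paste0("I", seq_len(n))
  mids <- c("S_ext", internal_ids, "P_ext")
  r <- cfg$n_reactions
  s <- matrix(0, nrow = length(mids), ncol = r, dimnames = list(mids, NULL))
  rids <- character(r)
  # linear backbone guarantees at least one objective-producing route
  s["S_ext", 1] <- -1; s["I1", 1] <- 1; rids[1] <- "uptake"
  for (j in seq_len(n - 1L)) {
    s[internal_ids[j], j + 1L] <- -1
    s[internal_ids[j + 1L], j + 1L] <- 1
    rids[j + 1L] <- paste0("conv", j)
  }
  n_extra <- r - n - 1L
  for (k in seq_len(n_extra)) {
    col <- n + k
    kind <- sample(c("internal", "uptake", "export"), 1L, prob = c(0.6, 0.2, 0.2))
    coefs <- abs(cfg$stoich_values)
    if (kind == "internal") {
      ab <- sample(n, 2L)
      s[internal_ids[ab[1]], col] <- -sample(coefs, 1L)
      s[internal_ids[ab[2]], col] <- sample(coefs, 1L)
    } else if (kind == "uptake") {
      a <- sample(n, 1L)
      s["S_ext", col] <- -sample(coefs, 1L)
      s[internal_ids[a], col] <- sample(coefs, 1L)
    } else {
      a <- sample(n, 1L)
      s[internal_ids[a], col] <- -sample(coefs, 1L)
      s["P_ext", col] <- sample(coefs, 1L)
    }
    rids[col] <- paste0("aux", k)
  }
  s[internal_ids[n], r] <- -1; s["P_ext", r] <- 1; rids[r] <- "objective"
  net <- metabolic_network(s, metabolite_ids = mids, reaction_ids = rids,
                           is_external = stats::setNames(mids %in% c("S_ext", "P_ext"), mids),
                           objective = "objective")
  lrunif <- function(range, k = 1L) 10^stats::runif(k, log10(range[1]), log10(range[2]))
  kin <- stats::setNames(vector("list", r), rids)
  for (j in seq_len(r)) {
    kind <- sample(c("michaelis_menten", "constant", "mm_product_inhibition"),
                   1L, prob = c(0.7, 0.2, 0.1))
    substrates <- mids[s[, j] < 0]
    products <- setdiff(mids[s[, j] > 0], "P_ext")
    if (kind != "constant" && length(substrates) == 0L) kind <- "constant"
    if (kind == "mm_product_inhibition" && length(products) == 0L) kind <- "michaelis_menten"
    sat <- switch(kind,
      constant = saturation_spec("constant"),
      michaelis_menten = saturation_spec(
        "michaelis_menten", substrates,
        stats::setNames(lrunif(cfg$Km_range, length(substrates)), substrates)),
      mm_product_inhibition = saturation_spec(
        "mm_product_inhibition", substrates,
        stats::setNames(lrunif(cfg$Km_range, length(substrates)), substrates),
        inhibitor_id = sample(products, 1L), Ki = lrunif(cfg$Km_range)))
    kin[[j]] <- reaction_kinetics(lrunif(cfg$kcat_range), sat)
  }
  w <- matrix(0, cfg$n_constraints, r)
  for (k in seq_len(cfg$n_constraints)) {
    member <- stats::runif(r) < cfg$weight_sparsity
    if (!any(member)) member[sample(r, 1L)] <- TRUE
    w[k, member] <- round(stats::runif(sum(member), 0.5, 2), 3)
  }
  colnames(w) <- rids
  kinetic_model(net, kin, constraint_set(w, rep(1, cfg$n_constraints)))
}

#' Generate a random kinetic model instance
#'
#' Draws seeded random instances of the model class the theory assumes: an
#' irreversible network around a linear backbone from one external substrate
#' to the objective, linear-in-enzyme rate laws with sampled saturation
#' kinds (70% Michaelis-Menten, 20% constant, 10% with product inhibition),
#' and K weighted enzyme pools. Instances violating the standing assumptions
#' — no objective-producing EFM, a cost-free objective EFM, or equivalent
#' objective EFMs — are rejected and redrawn under an advanced sub-seed, up
#' to 100 attempts.
#'
#' @param config a `generator_config`.
#' @return a valid `kinetic_model`; deterministic given `config`.
#' @export
generate_instance <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  for (attempt in seq_len(100L)) {
    sub_seed <- (config$seed * 131L + attempt) %% .Machine$integer.max
    model <- with_local_seed(sub_seed, try(.draw_instance(config), silent = TRUE))
    if (inherits(model, "try-error")) next
    efms <- try(objective_efms(model), silent = TRUE)
    if (inherits(efms, "try-error") || length(efms) == 0L) next
    if (any(vapply(efms, .structurally_costfree, logical(1), model = model))) next
    if (length(efms) > 1L) {
      equivalent <- FALSE
      for (a in seq_len(length(efms) - 1L)) {
        for (b in (a + 1L):length(efms)) {
          if (are_equivalent(efms[[a]], efms[[b]], model, seed = sub_seed)) {
            equivalent <- TRUE; break
          }
        }
        if (equivalent) break
      }
      if (equivalent) next
    }
    return(model)
  }
  stop(sprintf("no valid instance in 100 attempts for seed %d (n_internal=%d, n_reactions=%d, n_constraints=%d)",
               config$seed, config$n_internal, config$n_reactions, config$n_constraints))
}
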