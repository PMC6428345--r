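MODEL_FORMAT_VERSION <- "1.0"

#' @keywords internal
#' Build the plain-list document form of a model (fixed key order, sorted
#' maps) so that equal models serialize byte-identically.
.model_document <- function(model) {
  net <- model$network
  metabolites <- lapply(net$metabolite_ids, function(id) {
    list(id = id, external = unname(net$is_external[id]))
  })
  reactions <- lapply(seq_along(net$reaction_ids), function(j) {
    id <- net$reaction_ids[j]
    col <- net$stoichiometry[, j]
    col <- col[col != 0]
    col <- col[order(names(col))]
    rk <- model$kinetics[[id]]
    sat <- list(kind = rk$saturation$kind)
    if (length(rk$saturation$substrate_ids) > 0L) {
      sat$substrate_ids <- as.list(rk$saturation$substrate_ids)
      km <- rk$saturation$Km[order(names(rk$saturation$Km))]
      sat$Km <- as.list(km)
    }
    if (!is.null(rk$saturation$inhibitor_id)) {
      sat$inhibitor_id <- rk$saturation$inhibitor_id
      sat$Ki <- rk$saturation$Ki
    }
    list(id = id, stoichiometry = as.list(col), kcat = rk$kcat, saturation = sat,
         objective = j == net$objective_index)
  })
  constraints <- lapply(seq_along(model$constraints$pool_ids), function(k) {
    wr <- model$constraints$weights[k, ]
    wr <- wr[wr != 0]
    wr <- wr[order(names(wr))]
    list(id = model$constraints$pool_ids[k], weights = as.list(wr),
         bound = unname(model$constraints$bounds[k]))
  })
  list(format_version = MODEL_FORMAT_VERSION, metabolites = metabolites,
       reactions = reactions, constraints = constraints)
}

#' Write a kinetic model as a canonical JSON document
#'
#' The document uses a fixed key order, alphabetically sorted stoichiometry
#' and weight maps, and full-precision floats, so that equal models produce
#' byte-identical files.
#'
#' @param model a `kinetic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- .model_document(model)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2)
  writeLines(json, path)
  invisible(path)
}

#' Read a kinetic model from a JSON document
#'
#' Validates the document field-by-field with specific error messages
#' (missing fields, unknown saturation kinds, nonpositive kcat/Km/bound,
#' zero or multiple objective reactions, references to unknown ids) and
#' returns a fully validated model.
#'
#' @param path path to a JSON model document.
#' @return a `kinetic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("format_version", "metabolites", "reactions", "constraints")) {
    if (is.null(doc[[field]])) stop("model document lacks required field '", field, "'")
  }
  mids <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$external)) stop("metabolite entry needs 'id' and 'external'")
    m$id
  }, character(1))
  is_external <- stats::setNames(
    vapply(doc$metabolites, function(m) isTRUE(m$external), logical(1)), mids)
  rids <- vapply(doc$reactions, function(rx) {
    if (is.null(rx$id)) stop("reaction entry lacks 'id'")
    rx$id
  }, character(1))
  objective_flags <- vapply(doc$reactions, function(rx) isTRUE(rx$objective), logical(1))
  if (sum(objective_flags) == 0L) stop("model document designates no objective reaction")
  if (sum(objective_flags) > 1L) {
    stop("model document designates multiple objective reactions: ",
         paste(rids[objective_flags], collapse = ", "))
  }
  s <- matrix(0, nrow = length(mids), ncol = length(rids), dimnames = list(mids, rids))
  kin <- stats::setNames(vector("list", length(rids)), rids)
  for (rx in doc$reactions) {
    st <- rx$stoichiometry
    if (is.null(st) || length(st) == 0L) stop("reaction '", rx$id, "' has empty stoichiometry")
    unknown <- setdiff(names(st), mids)
    if (length(unknown) > 0L) {
      stop("reaction '", rx$id, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    s[names(st), rx$id] <- unlist(st)
    if (is.null(rx$kcat) || rx$kcat <= 0) stop("reaction '", rx$id, "' needs a positive kcat")
    sat_doc <- rx$saturation
    if (is.null(sat_doc) || is.null(sat_doc$kind)) stop("reaction '", rx$id, "' lacks a saturation spec")
    known <- c("constant", "michaelis_menten", "mm_product_inhibition",
               names(.saturation_registry$kinds))
    if (!sat_doc$kind %in% known) {
      stop("reaction '", rx$id, "' has unknown saturation kind '", sat_doc$kind, "'")
    }
    km <- unlist(sat_doc$Km)
    if (!is.null(km) && any(km <= 0)) stop("reaction '", rx$id, "' has nonpositive Km")
    if (!is.null(sat_doc$Ki) && sat_doc$Ki <= 0) stop("reaction '", rx$id, "' has nonpositive Ki")
    sat <- saturation_spec(sat_doc$kind,
                           substrate_ids = as.character(unlist(sat_doc$substrate_ids)),
                           Km = if (is.null(km)) numeric() else km,
                           inhibitor_id = sat_doc$inhibitor_id,
                           Ki = sat_doc$Ki)
    kin[[rx$id]] <- reaction_kinetics(rx$kcat, sat)
  }
  net <- metabolic_network(s, metabolite_ids = mids, reaction_ids = rids,
                           is_external = is_external,
                           objective = rids[which(objective_flags)])
  pool_ids <- vapply(doc$constraints, function(cn) {
    if (is.null(cn$id)) stop("constraint entry lacks 'id'")
    cn$id
  }, character(1))
  w <- matrix(0, nrow = length(pool_ids), ncol = length(rids),
              dimnames = list(pool_ids, rids))
  bounds <- numeric(length(pool_ids))
  for (k in seq_along(doc$constraints)) {
    cn <- doc$constraints[[k]]
    unknown <- setdiff(names(cn$weights), rids)
    if (length(unknown) > 0L) {
      stop("constraint '", cn$id, "' references unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    }
    w[k, names(cn$weights)] <- unlist(cn$weights)
    if (is.null(cn$bound) || cn$bound <= 0) stop("constraint '", cn$id, "' needs a positive bound")
    bounds[k] <- cn$bound
  }
  kinetic_model(net, kin, constraint_set(w, bounds, pool_ids = pool_ids))
}

#' Write an EFM matrix, a cost matrix, or a sweep table to disk
#'
#' EFM matrices are written as TSV with reactions in rows and EFM ids in the
#' header; cost matrices as TSV with pools in rows; sweep tables as CSV with
#' their full header.
#'
#' @param x a list of `efm` objects, a `cost_matrix`, or a `sweep_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(x, path) {
  if (inherits(x, "cost_matrix")) {
    df <- data.frame(pool = rownames(x$D), x$D, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "sweep_table")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  } else if (is.list(x) && length(x) > 0L && inherits(x[[1]], "efm")) {
    m <- efm_matrix(x)
    df <- data.frame(reaction = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop("unsupported object; expected EFM list, cost_matrix, or sweep_table")
  }
  invisible(path)
}
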