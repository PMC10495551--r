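#' Regulatory-metabolic component maps
#'
#' The bridge between the two model layers: an explicit, reviewable table
#' naming, for each regulatory node that stands for a metabolic component,
#' the metabolic reactions it governs — the catalyzed reactions for an
#' enzyme, the producing reactions for a metabolite. The map is an input, not
#' inferred: nodes and reactions are matched by their curated identifiers
#' (BiGG ids in practice), because silent fuzzy matching is worse than an
#' explicit table.
#'
#' @param node Character vector of regulatory node identifiers (unique).
#' @param kind `"enzyme"` or `"metabolite"` per entry.
#' @param reactions List (or comma-separated character vector) of linked
#'   reaction ids per entry.
#' @param metabolite For `"metabolite"` entries, the metabolic-model species
#'   the node stands for (used to validate that linked reactions can produce
#'   it); `NA` for enzymes.
#' @return Object of class `component_map` (data.frame with a list column
#'   `reactions`).
#' @export
component_map <- function(node, kind, reactions, metabolite = NA_character_) {
  if (anyDuplicated(node)) {
    stop("regulatory node(s) mapped more than once: ",
         paste(unique(node[duplicated(node)]), collapse = ", "), call. = FALSE)
  }
  if (!all(kind %in% c("enzyme", "metabolite"))) {
    stop("kind must be 'enzyme' or 'metabolite'", call. = FALSE)
  }
  if (is.character(reactions)) {
    reactions <- strsplit(reactions, "\\s*,\\s*")
  }
  stopifnot(length(reactions) == length(node))
  out <- data.frame(node = node, kind = kind, stringsAsFactors = FALSE)
  out$reactions <- lapply(reactions, as.character)
  out$metabolite <- rep_len(metabolite, length(node))
  class(out) <- c("component_map", "data.frame")
  out
}

#' Validate a component map against a metabolic model
#'
#' Checks that all linked reactions exist and that metabolite entries link
#' only reactions able to produce the metabolite: positive stoichiometry, or
#' any stoichiometry in a reversible reaction (which can produce the species
#' when running backwards).
#'
#' @param map A [component_map()].
#' @param model A [metabolic_model()].
#' @return `map`, invisibly.
#' @export
validate_component_map <- function(map, model) {
  stopifnot(inherits(map, "component_map"), inherits(model, "metabolic_model"))
  all_rxns <- unique(unlist(map$reactions))
  bad <- setdiff(all_rxns, model$reactions$id)
  if (length(bad) > 0L) {
    stop("component map links unknown reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  st <- model$stoichiometry
  for (k in seq_len(nrow(map))) {
    if (map$kind[k] != "metabolite" || is.na(map$metabolite[k])) next
    met <- map$metabolite[k]
    for (rid in map$reactions[[k]]) {
      coef <- st$coefficient[st$reaction == rid & st$metabolite == met]
      lb <- model$reactions$lb[model$reactions$id == rid]
      producing <- length(coef) > 0L && (any(coef > 0) || (lb < 0 && any(coef < 0)))
      if (!producing) {
        stop("reaction '", rid, "' cannot produce metabolite '", met,
             "' (entry for node '", map$node[k], "')", call. = FALSE)
      }
    }
  }
  invisible(map)
}

#' Read/write a component map as TSV
#'
#' Columns: `node`, `kind`, `reactions` (comma-separated), `metabolite`.
#'
#' @param path TSV path.
#' @return [component_map()] (reading) or `path` invisibly (writing).
#' @export
read_component_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  met <- if ("metabolite" %in% names(df)) df$metabolite else NA_character_
  met[!is.na(met) & met == ""] <- NA_character_
  component_map(df$node, df$kind, df$reactions, met)
}

#' @rdname read_component_map_tsv
#' @param map A [component_map()].
#' @export
write_component_map_tsv <- function(map, path) {
  df <- data.frame(
    node = map$node, kind = map$kind,
    reactions = vapply(map$reactions, paste, character(1), collapse = ","),
    metabolite = ifelse(is.na(map$metabolite), "", map$metabolite),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Asymptotic maximal value of a node over trap spaces
#'
#' Returns 0 only when the node is fixed at 0 in every trap space; a node
#' that is free anywhere counts as potentially active and yields 1. Only the
#' definite-0 case licenses a metabolic constraint: activity would speak to
#' neither feasibility nor kinetics of the linked reactions.
#'
#' @param spaces Non-empty list of trap spaces.
#' @param node Node identifier.
#' @param net Optional [boolean_network()] for membership checking.
#' @return `0L` or `1L`.
#' @export
component_asymptotic_max <- function(spaces, node, net = NULL) {
  if (length(spaces) == 0L) stop("no trap spaces given", call. = FALSE)
  if (!is.null(net) && !(node %in% net$nodes)) {
    stop("node '", node, "' absent from the network", call. = FALSE)
  }
  for (sp in spaces) {
    if (!(node %in% names(sp))) return(1L) # free: potentially active
    if (sp[[node]] == 1L) return(1L)
  }
  0L
}

#' Derive zero-flux constraints from trap spaces
#'
#' For every mapped component whose asymptotic maximum over the trap spaces
#' is 0 — an enzyme that is never active, a metabolite that is never produced
#' under the regulatory dynamics — all linked reactions are constrained to
#' zero flux. Components with asymptotic maximum 1 contribute nothing.
#' Reactions reached through several components are listed once with the
#' combined justification.
#'
#' @param spaces Non-empty list of trap spaces.
#' @param map A [component_map()].
#' @param net Optional network (see [component_asymptotic_max()]).
#' @param model Optional [metabolic_model()]; when given the map is validated
#'   against it first.
#' @return Object of class `flux_constraints`: data.frame with `reaction`,
#'   `lb`, `ub` (all zero) and list column `justification` (regulatory nodes).
#' @export
derive_constraints <- function(spaces, map, net = NULL, model = NULL) {
  stopifnot(inherits(map, "component_map"))
  if (!is.null(model)) validate_component_map(map, model)
  rxn_just <- list()
  for (k in seq_len(nrow(map))) {
    nd <- map$node[k]
    if (component_asymptotic_max(spaces, nd, net) == 0L) {
      for (rid in map$reactions[[k]]) {
        rxn_just[[rid]] <- union(rxn_just[[rid]], nd)
      }
    }
  }
  rxns <- sort(names(rxn_just))
  out <- data.frame(reaction = rxns,
                    lb = rep(0, length(rxns)), ub = rep(0, length(rxns)),
                    stringsAsFactors = FALSE)
  out$justification <- unname(rxn_just[rxns])
  class(out) <- c("flux_constraints", "data.frame")
  out
}

#' Apply zero-flux constraints to a metabolic model
#'
#' Pure transformation: returns a copy of the model with the listed
#' reactions' bounds set to `[0, 0]` (both directions of reversible
#' reactions); all other bounds untouched. Constraints only ever tighten the
#' feasible set.
#'
#' @param model A [metabolic_model()].
#' @param constraints A `flux_constraints` from [derive_constraints()].
#' @return A new [metabolic_model()].
#' @export
apply_constraints <- function(model, constraints) {
  stopifnot(inherits(model, "metabolic_model"))
  if (nrow(constraints) == 0L) return(model)
  bad <- setdiff(constraints$reaction, model$reactions$id)
  if (length(bad) > 0L) {
    stop("constraint(s) on unknown reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rxns <- model$reactions
  idx <- match(constraints$reaction, rxns$id)
  rxns$lb[idx] <- 0
  rxns$ub[idx] <- 0
  metabolic_model(model$metabolites, rxns, model$stoichiometry,
                  model$compartments)
}

#' Read/write flux constraints as TSV
#'
#' Columns: `reaction`, `lb`, `ub`, `justification` (comma-separated nodes).
#'
#' @param path TSV path.
#' @return `flux_constraints` (reading) or `path` invisibly (writing).
#' @export
read_constraints_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(reaction = df$reaction, lb = df$lb, ub = df$ub,
                    stringsAsFactors = FALSE)
  out$justification <- strsplit(df$justification, "\\s*,\\s*")
  class(out) <- c("flux_constraints", "data.frame")
  out
}

#' @rdname read_constraints_tsv
#' @param constraints A `flux_constraints`.
#' @export
write_constraints_tsv <- function(constraints, path) {
  df <- data.frame(
    reaction = constraints$reaction, lb = constraints$lb, ub = constraints$ub,
    justification = vapply(constraints$justification, paste, character(1),
                           collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
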