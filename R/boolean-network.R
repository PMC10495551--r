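#' Construct a Boolean regulatory network
#'
#' A `boolean_network` holds an ordered set of node identifiers and, for each
#' node, a Boolean update expression over the nodes. Input nodes — nodes with
#' no regulators other than themselves — are modelled with the identity
#' update `X := X`, which makes them bistable (free) until clamped.
#'
#' @param functions Named list mapping node identifier to update rule. Each
#'   rule may be a string (parsed with [parse_bool_expr()]), an unevaluated
#'   expression, a logical constant, or `NULL` for an input node (identity
#'   update).
#' @param annotations Optional named list of per-node metadata lists; the
#'   conventional fields are `name` (display/gene symbol) and `class`
#'   (ontology class such as `"gene"`, `"protein"`, `"phenotype"`,
#'   `"simple molecule"`).
#' @return An object of class `boolean_network` with components `nodes`,
#'   `functions`, `inputs` and `annotations`.
#' @examples
#' net <- boolean_network(list(
#'   Hypoxia = NULL,            # input
#'   HIF1    = "Hypoxia",
#'   PDK1    = "HIF1",
#'   PDH     = "!PDK1"
#' ))
#' net$inputs
#' @export
boolean_network <- function(functions, annotations = list()) {
  if (is.null(names(functions)) || any(names(functions) == "") ||
      anyDuplicated(names(functions))) {
    stop("'functions' must be a named list with unique, non-empty names", call. = FALSE)
  }
  nodes <- names(functions)
  exprs <- vector("list", length(nodes))
  names(exprs) <- nodes
  for (nm in nodes) {
    f <- functions[[nm]]
    if (is.null(f)) {
      exprs[[nm]] <- as.symbol(nm) # input: identity update
    } else if (is.character(f)) {
      exprs[[nm]] <- parse_bool_expr(f)
    } else if (is.logical(f) && length(f) == 1L && !is.na(f)) {
      exprs[[nm]] <- f
    } else if (is.language(f)) {
      check_bool_expr(f)
      exprs[[nm]] <- canon_expr(f)
    } else {
      stop("unsupported update rule for node '", nm, "'", call. = FALSE)
    }
  }
  for (nm in nodes) {
    refs <- expr_vars(exprs[[nm]])
    unknown <- setdiff(refs, nodes)
    if (length(unknown) > 0L) {
      stop("update rule of '", nm, "' references undeclared node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  inputs <- nodes[vapply(nodes, function(nm) {
    identical(exprs[[nm]], as.symbol(nm))
  }, logical(1))]
  if (length(annotations) > 0L) {
    bad <- setdiff(names(annotations), nodes)
    if (length(bad) > 0L) {
      stop("annotations for unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(nodes = nodes, functions = exprs, inputs = inputs,
         annotations = annotations),
    class = "boolean_network"
  )
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", length(x$nodes), "nodes (",
      length(x$inputs), "inputs )\n")
  show <- utils::head(x$nodes, 10L)
  for (nm in show) {
    rule <- if (nm %in% x$inputs) "<input>" else expr_to_text(x$functions[[nm]])
    cat("  ", nm, " := ", rule, "\n", sep = "")
  }
  if (length(x$nodes) > length(show)) {
    cat("  ... and", length(x$nodes) - length(show), "more nodes\n")
  }
  invisible(x)
}

#' Regulators of each node
#' @param net A `boolean_network`.
#' @return Named list of character vectors (self-reference of inputs removed).
#' @export
network_regulators <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  out <- lapply(net$nodes, function(nm) {
    regs <- expr_vars(net$functions[[nm]])
    if (nm %in% net$inputs) regs <- setdiff(regs, nm)
    regs
  })
  names(out) <- net$nodes
  out
}

#' Gene-symbol aliases attached to network nodes
#'
#' Collects, per node, the node identifier itself plus any `name` annotation,
#' upper-cased for case-insensitive matching.
#'
#' @param net A `boolean_network`.
#' @return Named list of upper-case alias vectors.
#' @keywords internal
node_aliases <- function(net) {
  out <- lapply(net$nodes, function(nm) {
    al <- nm
    ann <- net$annotations[[nm]]
    if (!is.null(ann$name)) al <- c(al, ann$name)
    unique(toupper(al))
  })
  names(out) <- net$nodes
  out
}
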