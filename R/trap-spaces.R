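#' Trap spaces of Boolean networks
#'
#' A trap space is a partial 0/1 assignment (a subspace of the state space)
#' that no trajectory can leave under any update scheme: for every assigned
#' node, the update function restricted to the subspace can never evaluate to
#' the opposite value. Minimal trap spaces — those containing no strictly
#' smaller trap space — approximate the attractors of the asynchronous
#' dynamics and are the asymptotic summary used throughout this package.
#'
#' Trap spaces are represented as named integer vectors holding the fixed
#' nodes only; free nodes are implicit.
#'
#' @name trap-spaces
NULL

## ---- internal helpers -----------------------------------------------------

trap_space_key <- function(space, nodes) {
  v <- rep("-", length(nodes))
  names(v) <- nodes
  if (length(space) > 0L) v[names(space)] <- as.character(space)
  paste(v, collapse = "")
}

## Keep assignments whose (node,value) pair sets are maximal, i.e. the
## subspaces that are minimal as state sets.
keep_maximal_assignments <- function(spaces) {
  if (length(spaces) <= 1L) return(spaces)
  n_fixed <- lengths(spaces)
  keep <- rep(TRUE, length(spaces))
  for (i in seq_along(spaces)) {
    a <- spaces[[i]]
    for (j in seq_along(spaces)) {
      if (i == j || n_fixed[j] <= n_fixed[i]) next
      b <- spaces[[j]]
      if (all(names(a) %in% names(b)) &&
          (length(a) == 0L || all(b[names(a)] == a))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  spaces[keep]
}

## Canonical order: by number of fixed nodes, then lexicographically on the
## 0/1/"-" representation over the network's node order.
sort_trap_spaces <- function(spaces, nodes) {
  if (length(spaces) == 0L) return(spaces)
  spaces <- lapply(spaces, function(s) s[intersect(nodes, names(s))])
  keys <- vapply(spaces, trap_space_key, character(1), nodes = nodes)
  ord <- order(lengths(spaces), keys, method = "radix")
  spaces[ord]
}

#' Check the closure property of a candidate trap space
#'
#' Uses three-valued evaluation: every assigned node's update function must
#' evaluate definitely to its assigned value over the subspace.
#'
#' @param net A `boolean_network`.
#' @param space Named 0/1 vector (fixed nodes only).
#' @return `TRUE` or `FALSE`.
#' @export
is_trap_space <- function(net, space) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(space) == 0L) return(TRUE)
  bad <- setdiff(names(space), net$nodes)
  if (length(bad) > 0L) {
    stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(space)) {
    v <- tv_eval(net$functions[[nm]], space, nodes = net$nodes)
    if (!identical(v, as.integer(space[[nm]]))) return(FALSE)
  }
  TRUE
}

## ---- exact solver ----------------------------------------------------------

#' Compute all minimal trap spaces
#'
#' Exact constraint-based computation in two stages. First, constants are
#' percolated through the network (value propagation with an empty clamping),
#' which fixes every node that is forced by clamped/constant update rules;
#' every minimal trap space must contain these percolated values. Second, on
#' the residual free nodes, the smallest trap space containing each residual
#' state is computed by closure — iteratively freeing any assigned node whose
#' update function, restricted to the current subspace, can take the opposite
#' value (three-valued check on the node's reduced truth table). The set of
#' distinct closures, filtered to maximal fixed-node assignments, is exactly
#' the set of minimal trap spaces.
#'
#' @param net A `boolean_network`.
#' @param max_free_nodes Solver limit on the number of nodes left free after
#'   percolation (the search enumerates `2^k` residual states). Exceeding it
#'   raises an error rather than returning a partial answer.
#' @return List of trap spaces (named integer vectors) in canonical order:
#'   fewest fixed nodes first, ties broken lexicographically.
#' @examples
#' net <- boolean_network(list(A = "A")) # self-activating switch
#' compute_minimal_trap_spaces(net)      # {A=0} and {A=1}
#' @export
compute_minimal_trap_spaces <- function(net, max_free_nodes = 16L) {
  stopifnot(inherits(net, "boolean_network"))
  perc <- propagate_values(net, clamping())$values
  residual <- setdiff(net$nodes, names(perc))
  if (length(residual) == 0L) {
    return(sort_trap_spaces(list(perc), net$nodes))
  }
  if (length(residual) > max_free_nodes) {
    stop("trap-space solver limit exceeded: ", length(residual),
         " free nodes after percolation (max_free_nodes = ", max_free_nodes,
         "); raise the limit explicitly if this size is intended",
         call. = FALSE)
  }
  ttabs <- lapply(residual, function(nm) {
    expr_truth_table(simplify_expr(net$functions[[nm]], perc))
  })
  names(ttabs) <- residual
  r <- length(residual)
  n_states <- bitwShiftL(1L, r)
  found <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in 0:(n_states - 1L)) {
    m <- stats::setNames(bitwAnd(bitwShiftR(i, 0:(r - 1L)), 1L), residual)
    assigned <- rep(TRUE, r)
    names(assigned) <- residual
    repeat {
      changed <- FALSE
      for (j in seq_len(r)) {
        if (!assigned[j]) next
        nm <- residual[j]
        val <- tt_tv_eval(ttabs[[nm]], m[assigned])
        if (!identical(val, m[[nm]])) {
          assigned[j] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    sp <- m[assigned]
    key <- trap_space_key(sp, residual)
    if (is.null(found[[key]])) found[[key]] <- sp
  }
  candidates <- as.list(found)
  minimal <- keep_maximal_assignments(unname(candidates))
  full <- lapply(minimal, function(sp) {
    out <- c(perc, sp)
    out[intersect(net$nodes, names(out))]
  })
  sort_trap_spaces(full, net$nodes)
}

## ---- brute-force oracle ----------------------------------------------------

#' Brute-force reference computation of minimal trap spaces
#'
#' Testing oracle: enumerates all `3^n` subspaces, keeps those closed under
#' the exact state dynamics (every member state's update of every fixed node
#' reproduces the fixed value, checked on a precomputed full state-transition
#' image), and filters to minimal. Exponential by design; refuses networks
#' beyond `max_nodes`.
#'
#' @param net A `boolean_network`.
#' @param max_nodes Hard cap (default 10).
#' @return Same form and order as [compute_minimal_trap_spaces()].
#' @export
brute_force_trap_spaces <- function(net, max_nodes = 10L) {
  stopifnot(inherits(net, "boolean_network"))
  n <- length(net$nodes)
  if (n > max_nodes) {
    stop("brute-force oracle refuses networks with more than ", max_nodes,
         " nodes (got ", n, ")", call. = FALSE)
  }
  n_states <- bitwShiftL(1L, n)
  idx <- 0:(n_states - 1L)
  state_bits <- vapply(seq_len(n), function(j) bitwAnd(bitwShiftR(idx, j - 1L), 1L),
                       integer(n_states))
  state_bits <- matrix(state_bits, nrow = n_states)
  colnames(state_bits) <- net$nodes
  env <- new.env(parent = baseenv())
  for (j in seq_len(n)) assign(net$nodes[j], state_bits[, j] == 1L, envir = env)
  img <- vapply(net$nodes, function(nm) {
    v <- eval(net$functions[[nm]], envir = env)
    v <- as.integer(v)
    if (length(v) == 1L) v <- rep(v, n_states)
    v
  }, integer(n_states))
  img <- matrix(img, nrow = n_states, dimnames = list(NULL, net$nodes))

  spaces <- list()
  code <- integer(n) # 0,1 fixed; 2 free — ternary counter
  repeat {
    fixed_idx <- which(code < 2L)
    members <- rep(TRUE, n_states)
    for (j in fixed_idx) members <- members & (state_bits[, j] == code[j])
    closed <- TRUE
    for (j in fixed_idx) {
      if (!all(img[members, j] == code[j])) { closed <- FALSE; break }
    }
    if (closed) {
      sp <- stats::setNames(code[fixed_idx], net$nodes[fixed_idx])
      spaces[[length(spaces) + 1L]] <- sp
    }
    k <- 1L
    while (k <= n && code[k] == 2L) { code[k] <- 0L; k <- k + 1L }
    if (k > n) break
    code[k] <- code[k] + 1L
  }
  sort_trap_spaces(keep_maximal_assignments(spaces), net$nodes)
}

## ---- projection and serialization -----------------------------------------

#' Project trap spaces onto a subset of nodes
#'
#' Restricts each trap space to the given nodes and removes duplicate
#' projections (preserving first-occurrence order).
#'
#' @param spaces List of trap spaces.
#' @param nodes Character vector of nodes to project on (may be empty).
#' @return Deduplicated list of partial assignments over `nodes`.
#' @export
project_trap_spaces <- function(spaces, nodes) {
  proj <- lapply(spaces, function(sp) sp[intersect(nodes, names(sp))])
  keys <- vapply(proj, trap_space_key, character(1), nodes = nodes)
  proj[!duplicated(keys)]
}

#' Write trap spaces to TSV or JSON
#'
#' TSV: one row per trap space, one column per node, values `0`/`1`/`-`
#' (free). JSON: array of objects with fixed nodes only.
#'
#' @param spaces List of trap spaces.
#' @param nodes Full node order (column order of the TSV).
#' @param path Output path; format chosen by extension (`.json` vs TSV).
#' @return `path`, invisibly.
#' @export
write_trap_spaces <- function(spaces, nodes, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- lapply(spaces, function(sp) as.list(sp))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  rows <- vapply(spaces, function(sp) {
    v <- rep("-", length(nodes))
    names(v) <- nodes
    if (length(sp) > 0L) v[names(sp)] <- as.character(sp)
    paste(v, collapse = "\t")
  }, character(1))
  writeLines(c(paste(nodes, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read trap spaces written by [write_trap_spaces()] (TSV form)
#'
#' @param path TSV path.
#' @return List of trap spaces with attribute `nodes`.
#' @export
read_trap_spaces <- function(path) {
  lines <- readLines(path)
  nodes <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  spaces <- lapply(lines[-1L], function(ln) {
    v <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    fixed <- v != "-"
    stats::setNames(as.integer(v[fixed]), nodes[fixed])
  })
  attr(spaces, "nodes") <- nodes
  spaces
}
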