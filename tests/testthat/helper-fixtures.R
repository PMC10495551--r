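# Shared fixtures built in code.

# Minimal hypoxia->HIF->PDK->PDH regulatory core (no decoys).
toy_core_net <- function() {
  boolean_network(list(
    Hypoxia = NULL,
    HIF1 = "Hypoxia",
    PDK1 = "HIF1",
    PDH = "!PDK1"
  ))
}

# Canonical string keys for comparing trap-space sets.
space_keys <- function(spaces) {
  sort(vapply(spaces, function(x) {
    if (length(x) == 0L) return("<empty>")
    paste(names(x), x, sep = "=", collapse = ",")
  }, character(1)))
}

# Flip one node of an initial-condition set.
flip_condition <- function(conditions, node) {
  v <- conditions$values
  v[node] <- 1L - v[[node]]
  initial_conditions(v, conditions$provenance)
}

# Asynchronous attractors (terminal SCCs of the state-transition graph) of a
# small Boolean network, as a list of 0/1 state matrices. Independent oracle
# for propagation soundness, built on igraph's SCC condensation.
async_attractor_states <- function(net) {
  n <- length(net$nodes)
  stopifnot(n <= 10)
  n_states <- 2^n
  idx <- 0:(n_states - 1)
  bits <- sapply(seq_len(n), function(j) bitwAnd(bitwShiftR(idx, j - 1L), 1L))
  bits <- matrix(bits, nrow = n_states, dimnames = list(NULL, net$nodes))
  env <- new.env(parent = baseenv())
  for (j in seq_len(n)) assign(net$nodes[j], bits[, j] == 1L, envir = env)
  img <- sapply(net$nodes, function(nm) {
    v <- as.integer(eval(net$functions[[nm]], envir = env))
    if (length(v) == 1L) rep(v, n_states) else v
  })
  img <- matrix(img, nrow = n_states)
  edges <- integer(0)
  for (j in seq_len(n)) {
    flips <- which(img[, j] != bits[, j])
    if (length(flips) > 0L) {
      to <- idx[flips] + (img[flips, j] - bits[flips, j]) * 2^(j - 1)
      edges <- c(edges, rbind(flips, to + 1L))
    }
  }
  g <- igraph::make_empty_graph(n = n_states, directed = TRUE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g, mode = "strong")
  cond <- igraph::contract(g, comp$membership)
  cond <- igraph::simplify(cond)
  terminal <- which(igraph::degree(cond, mode = "out") == 0)
  lapply(terminal, function(cc) {
    bits[comp$membership == cc, , drop = FALSE]
  })
}
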