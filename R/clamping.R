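#' Clampings: partial 0/1 assignments with provenance
#'
#' A clamping fixes a subset of nodes to constants. It is the computational
#' face of an initial-condition set: following the contextualization strategy
#' used for the breast CAF model, every node with a fixed initial value
#' (inputs and internal nodes alike) is clamped as a constant before value
#' propagation and trap-space analysis.
#'
#' @param values Named 0/1 vector (or named list) of node values.
#' @param origin Per-node provenance tag, `"user"` or `"propagated"`;
#'   recycled if scalar.
#' @return Object of class `clamping` with fields `values` (named integer)
#'   and `origin` (named character).
#' @examples
#' clamping(c(Hypoxia = 1))
#' @export
clamping <- function(values = integer(), origin = "user") {
  values <- unlist(values)
  if (length(values) > 0L) {
    if (is.null(names(values)) || any(names(values) == "")) {
      stop("clamping values must be named", call. = FALSE)
    }
    if (anyDuplicated(names(values))) {
      dups <- unique(names(values)[duplicated(names(values))])
      stop("node(s) clamped more than once: ", paste(dups, collapse = ", "), call. = FALSE)
    }
    if (!all(values %in% c(0, 1))) {
      stop("clamping values must be 0 or 1", call. = FALSE)
    }
  }
  values <- stats::setNames(as.integer(values), names(values))
  origin <- rep_len(as.character(origin), length(values))
  names(origin) <- names(values)
  if (length(values) > 0L && !all(origin %in% c("user", "propagated"))) {
    stop("origin must be 'user' or 'propagated'", call. = FALSE)
  }
  structure(list(values = values, origin = origin), class = "clamping")
}

#' @export
print.clamping <- function(x, ...) {
  cat("Clamping of", length(x$values), "node(s)\n")
  if (length(x$values) > 0L) {
    df <- data.frame(node = names(x$values), value = unname(x$values),
                     origin = unname(x$origin))
    print(utils::head(df, 20L), row.names = FALSE)
    if (nrow(df) > 20L) cat("  ...\n")
  }
  invisible(x)
}

check_clamp_domain <- function(net, clamps) {
  stopifnot(inherits(net, "boolean_network"), inherits(clamps, "clamping"))
  bad <- setdiff(names(clamps$values), net$nodes)
  if (length(bad) > 0L) {
    stop("clamping refers to node(s) absent from the network: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Clamp nodes of a Boolean network to constants
#'
#' Replaces the update function of every clamped node by the constant value;
#' all other update functions are untouched. Knock-out corresponds to
#' clamping at 0 and knock-in to clamping at 1.
#'
#' @param net A `boolean_network`.
#' @param clamps A [clamping()].
#' @return A new `boolean_network`.
#' @export
apply_clamping <- function(net, clamps) {
  check_clamp_domain(net, clamps)
  if (length(clamps$values) == 0L) return(net)
  funs <- net$functions
  for (nm in names(clamps$values)) funs[[nm]] <- clamps$values[[nm]] == 1L
  boolean_network(funs, annotations = net$annotations)
}

#' Value propagation (percolation) of clamped values
#'
#' Computes the least fixpoint of the rule "fix node `v` at `b` whenever its
#' update function evaluates three-valued to `b` under the values fixed so
#' far", starting from the user clamping. Clamped nodes act as constants.
#' The result extends the input clamping, is idempotent, and is sound for the
#' clamped dynamics: every attractor state of the clamped network agrees with
#' every propagated value.
#'
#' @param net A `boolean_network`.
#' @param clamps A [clamping()]; its nodes are tagged `"user"`, all newly
#'   fixed nodes `"propagated"`.
#' @return A [clamping()] extending `clamps`.
#' @examples
#' net <- boolean_network(list(A = NULL, B = "A", C = "B"))
#' propagate_values(net, clamping(c(A = 1)))$values
#' @export
propagate_values <- function(net, clamps = clamping()) {
  check_clamp_domain(net, clamps)
  clamped <- apply_clamping(net, clamps)
  fixed <- clamps$values
  origin <- clamps$origin
  repeat {
    changed <- FALSE
    for (nm in clamped$nodes) {
      if (nm %in% names(fixed)) next
      v <- tv_eval(clamped$functions[[nm]], fixed, nodes = clamped$nodes)
      if (!is.na(v)) {
        fixed[nm] <- v
        origin[nm] <- "propagated"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  clamping(fixed, origin)
}
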