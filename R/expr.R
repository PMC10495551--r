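#' Boolean expression utilities
#'
#' Boolean update functions are stored as unevaluated R expressions built from
#' node symbols, the logical constants `TRUE`/`FALSE`, and the operators `&`
#' (AND), `|` (OR) and `!` (NOT). This gives parsing, deparsing and
#' substitution for free while keeping the update rules readable
#' (`HIF1 := Hypoxia`, `PDH := !PDK1`).
#'
#' @name bool-expr
#' @keywords internal
NULL

#' Parse a Boolean expression from text
#'
#' @param text A single string such as `"A & !B | C"`. The constants `0`/`1`
#'   and `TRUE`/`FALSE` are accepted.
#' @return An unevaluated R expression (symbol, logical or call).
#' @examples
#' parse_bool_expr("Hypoxia & !PDK1")
#' @export
parse_bool_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  expr <- tryCatch(
    str2lang(text),
    error = function(e) stop("cannot parse Boolean expression: ", conditionMessage(e), call. = FALSE)
  )
  check_bool_expr(expr)
  canon_expr(expr)
}

## Rewrite scalar && / || to vectorised & / | so expressions can be evaluated
## over whole truth-table columns at once.
canon_expr <- function(expr) {
  if (!is.call(expr)) return(expr)
  op <- as.character(expr[[1L]])
  if (op == "(") return(canon_expr(expr[[2L]]))
  if (op == "!") return(call("!", canon_expr(expr[[2L]])))
  if (op %in% c("&", "&&")) return(call("&", canon_expr(expr[[2L]]), canon_expr(expr[[3L]])))
  if (op %in% c("|", "||")) return(call("|", canon_expr(expr[[2L]]), canon_expr(expr[[3L]])))
  expr
}

## Accept only the Boolean fragment: symbols, TRUE/FALSE, 0/1, !, &, |, ( ).
check_bool_expr <- function(expr) {
  if (is.symbol(expr)) return(invisible(TRUE))
  if (is.logical(expr) && length(expr) == 1L && !is.na(expr)) return(invisible(TRUE))
  if (is.numeric(expr) && length(expr) == 1L && expr %in% c(0, 1)) return(invisible(TRUE))
  if (is.call(expr)) {
    op <- as.character(expr[[1L]])
    if (op == "(") return(check_bool_expr(expr[[2L]]))
    if (op == "!") return(check_bool_expr(expr[[2L]]))
    if (op %in% c("&", "|", "&&", "||")) {
      check_bool_expr(expr[[2L]])
      check_bool_expr(expr[[3L]])
      return(invisible(TRUE))
    }
    stop("unsupported operator in Boolean expression: '", op, "'", call. = FALSE)
  }
  stop("unsupported term in Boolean expression: ", deparse(expr), call. = FALSE)
}

#' Variables referenced by a Boolean expression
#' @param expr An expression as returned by [parse_bool_expr()].
#' @return Character vector of distinct node identifiers.
#' @export
expr_vars <- function(expr) {
  unique(all.vars(expr))
}

expr_to_text <- function(expr) {
  paste(deparse(expr, width.cutoff = 500L), collapse = " ")
}

#' Three-valued (Kleene) evaluation of a Boolean expression
#'
#' Evaluates `expr` under a partial assignment of node values. Unassigned
#' nodes are treated as unknown; the result is `0L` or `1L` only if the
#' expression takes that value for every completion of the unknowns reachable
#' by Kleene's rules (`1 OR unknown = 1`, `0 AND unknown = 0`), and
#' `NA_integer_` otherwise.
#'
#' Kleene evaluation is sound but not complete for constancy: a tautology over
#' unknowns (e.g. `A | !A`) still evaluates to unknown. That conservatism is
#' what the value-propagation and trap-space machinery require.
#'
#' @param expr Boolean expression.
#' @param values Named integer/numeric vector of 0/1 values; missing names are
#'   unknown. `NA` entries are also treated as unknown.
#' @param nodes Optional character vector of declared nodes; if supplied,
#'   referencing an undeclared node is an error.
#' @return `0L`, `1L` or `NA_integer_`.
#' @examples
#' tv_eval(parse_bool_expr("A | B"), c(A = 1))   # 1
#' tv_eval(parse_bool_expr("A & B"), c(A = 1))   # NA
#' @export
tv_eval <- function(expr, values = integer(), nodes = NULL) {
  if (is.symbol(expr)) {
    nm <- as.character(expr)
    if (!is.null(nodes) && !(nm %in% nodes)) {
      stop("expression references undeclared node '", nm, "'", call. = FALSE)
    }
    if (nm %in% names(values)) {
      v <- values[[nm]]
      if (is.na(v)) return(NA_integer_)
      return(as.integer(v))
    }
    return(NA_integer_)
  }
  if (is.logical(expr)) return(as.integer(expr))
  if (is.numeric(expr)) return(as.integer(expr))
  op <- as.character(expr[[1L]])
  if (op == "(") return(tv_eval(expr[[2L]], values, nodes))
  if (op == "!") {
    v <- tv_eval(expr[[2L]], values, nodes)
    return(if (is.na(v)) NA_integer_ else 1L - v)
  }
  a <- tv_eval(expr[[2L]], values, nodes)
  if (op %in% c("&", "&&")) {
    if (identical(a, 0L)) return(0L)
    b <- tv_eval(expr[[3L]], values, nodes)
    if (identical(b, 0L)) return(0L)
    if (is.na(a) || is.na(b)) return(NA_integer_)
    return(1L)
  }
  if (op %in% c("|", "||")) {
    if (identical(a, 1L)) return(1L)
    b <- tv_eval(expr[[3L]], values, nodes)
    if (identical(b, 1L)) return(1L)
    if (is.na(a) || is.na(b)) return(NA_integer_)
    return(0L)
  }
  stop("unsupported operator in Boolean expression: '", op, "'", call. = FALSE)
}

#' Partially evaluate a Boolean expression under fixed values
#'
#' Substitutes the given 0/1 values and folds constants, returning a
#' simplified expression over the remaining variables only.
#'
#' @inheritParams tv_eval
#' @return A simplified expression; possibly `TRUE` or `FALSE`.
#' @export
simplify_expr <- function(expr, values = integer()) {
  if (is.symbol(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(values) && !is.na(values[[nm]])) {
      return(values[[nm]] == 1)
    }
    return(expr)
  }
  if (is.logical(expr)) return(expr)
  if (is.numeric(expr)) return(expr == 1)
  op <- as.character(expr[[1L]])
  if (op == "(") return(simplify_expr(expr[[2L]], values))
  if (op == "!") {
    a <- simplify_expr(expr[[2L]], values)
    if (is.logical(a)) return(!a)
    if (is.call(a) && as.character(a[[1L]]) == "!") return(a[[2L]])
    return(call("!", a))
  }
  a <- simplify_expr(expr[[2L]], values)
  b <- simplify_expr(expr[[3L]], values)
  if (op %in% c("&", "&&")) {
    if (isFALSE(a) || isFALSE(b)) return(FALSE)
    if (isTRUE(a)) return(b)
    if (isTRUE(b)) return(a)
    return(call("&", a, b))
  }
  if (op %in% c("|", "||")) {
    if (isTRUE(a) || isTRUE(b)) return(TRUE)
    if (isFALSE(a)) return(b)
    if (isFALSE(b)) return(a)
    return(call("|", a, b))
  }
  stop("unsupported operator in Boolean expression: '", op, "'", call. = FALSE)
}

#' Exact Boolean evaluation at a complete state
#'
#' @param expr Boolean expression.
#' @param state Named 0/1 vector covering all referenced variables.
#' @return `0L` or `1L`.
#' @keywords internal
eval_expr_state <- function(expr, state) {
  v <- tv_eval(expr, state)
  if (is.na(v)) {
    stop("state does not cover all variables of ", expr_to_text(expr), call. = FALSE)
  }
  v
}

#' Truth table of a Boolean expression over its variables
#'
#' Rows enumerate regulator states in binary counting order with the first
#' variable as the least significant bit.
#'
#' @param expr Boolean expression.
#' @param vars Character vector of variables (defaults to [expr_vars()]).
#' @return List with `vars` and integer vector `tt` of length `2^length(vars)`.
#' @keywords internal
expr_truth_table <- function(expr, vars = expr_vars(expr)) {
  k <- length(vars)
  if (k > 20L) {
    stop("refusing to build a truth table over ", k, " regulators", call. = FALSE)
  }
  n_rows <- bitwShiftL(1L, k)
  tt <- integer(n_rows)
  if (k == 0L) {
    tt[1L] <- tv_eval(expr)
    if (is.na(tt[1L])) stop("expression with no variables must be constant", call. = FALSE)
    return(list(vars = vars, tt = tt))
  }
  idx <- 0:(n_rows - 1L)
  bits <- vapply(seq_len(k), function(j) bitwAnd(bitwShiftR(idx, j - 1L), 1L), integer(n_rows))
  bits <- matrix(bits, nrow = n_rows)
  env <- new.env(parent = baseenv())
  for (j in seq_len(k)) assign(vars[j], bits[, j] == 1L, envir = env)
  val <- eval(expr, envir = env)
  tt <- as.integer(val)
  if (length(tt) == 1L) tt <- rep(tt, n_rows)
  list(vars = vars, tt = tt)
}

## Three-valued evaluation from a truth table: value of the function over the
## face of the hypercube selected by `fixed` (named 0/1 vector; missing = free).
## Returns 0L/1L if constant on that face, NA otherwise.
tt_tv_eval <- function(ttab, fixed) {
  k <- length(ttab$vars)
  if (k == 0L) return(ttab$tt[1L])
  keep <- rep(TRUE, length(ttab$tt))
  idx <- 0:(length(ttab$tt) - 1L)
  for (j in seq_len(k)) {
    nm <- ttab$vars[j]
    if (nm %in% names(fixed) && !is.na(fixed[[nm]])) {
      keep <- keep & (bitwAnd(bitwShiftR(idx, j - 1L), 1L) == fixed[[nm]])
    }
  }
  vals <- ttab$tt[keep]
  if (all(vals == 1L)) return(1L)
  if (all(vals == 0L)) return(0L)
  NA_integer_
}
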