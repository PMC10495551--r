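#' Dense two-phase simplex for flux balance problems
#'
#' Solves `max/min c'v` subject to `A v = b` and `lb <= v <= ub`. Written for
#' the moderate, often degenerate linear programs that arise in flux balance
#' analysis of core metabolic models; uses Bland's pivoting rule throughout,
#' which guarantees termination on degenerate problems at the cost of speed.
#'
#' Variables with `lb == ub` are eliminated before solving; variables with an
#' infinite upper range simply get no upper-bound row.
#'
#' @param obj Objective coefficients (length n).
#' @param A Constraint matrix (m x n).
#' @param b Right-hand side (length m).
#' @param lb,ub Finite lower bounds and (possibly infinite) upper bounds.
#' @param maximize Maximize (default) or minimize.
#' @param tol Numerical tolerance for pivoting and feasibility.
#' @return List with `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `objective` and `solution` (length n; `NA` unless optimal).
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("lower bounds must be finite", call. = FALSE)
  if (any(ub < lb)) stop("upper bound below lower bound", call. = FALSE)

  fixed <- (ub - lb) <= tol
  free <- which(!fixed)
  v_out <- lb # fixed vars sit at their bound
  if (length(free) == 0L) {
    resid <- A %*% lb - b
    if (max(abs(resid)) > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_,
                  solution = rep(NA_real_, n)))
    }
    objv <- sum(obj * lb)
    return(list(status = "optimal", objective = objv, solution = lb))
  }
  Af <- A[, free, drop = FALSE]
  bshift <- as.vector(b - A %*% ifelse(fixed, lb, 0) - Af %*% lb[free])
  u <- (ub - lb)[free]
  nf <- length(free)
  cf <- obj[free]
  if (!maximize) cf <- -cf # internally always maximize

  bounded <- which(is.finite(u))
  m_eq <- nrow(Af)
  m_bd <- length(bounded)
  m_all <- m_eq + m_bd
  # columns: nf structural + m_bd slacks + m_eq artificials
  n_all <- nf + m_bd + m_eq
  Tab <- matrix(0, m_all, n_all + 1L)
  Tab[seq_len(m_eq), seq_len(nf)] <- Af
  Tab[seq_len(m_eq), n_all + 1L] <- bshift
  neg <- Tab[seq_len(m_eq), n_all + 1L] < 0
  if (any(neg)) {
    Tab[seq_len(m_eq)[neg], ] <- -Tab[seq_len(m_eq)[neg], , drop = FALSE]
  }
  for (k in seq_along(bounded)) {
    Tab[m_eq + k, bounded[k]] <- 1
    Tab[m_eq + k, nf + k] <- 1
    Tab[m_eq + k, n_all + 1L] <- u[bounded[k]]
  }
  art_cols <- nf + m_bd + seq_len(m_eq)
  for (i in seq_len(m_eq)) Tab[i, art_cols[i]] <- 1
  basis <- integer(m_all)
  basis[seq_len(m_eq)] <- art_cols
  if (m_bd > 0L) basis[m_eq + seq_len(m_bd)] <- nf + seq_len(m_bd)

  pivot <- function(Tab, basis, row, col) {
    Tab[row, ] <- Tab[row, ] / Tab[row, col]
    other <- setdiff(seq_len(nrow(Tab)), row)
    Tab[other, ] <- Tab[other, ] - outer(Tab[other, col], Tab[row, ])
    basis[row] <- col
    list(Tab = Tab, basis = basis)
  }

  run_simplex <- function(Tab, basis, cost, allowed) {
    # maximizes `cost` (length n_all) over allowed columns; Bland's rule
    repeat {
      cB <- cost[basis]
      red <- cost - as.vector(cB %*% Tab[, seq_len(n_all), drop = FALSE])
      cand <- which(allowed & red > tol)
      if (length(cand) == 0L) return(list(Tab = Tab, basis = basis, status = "optimal"))
      j <- min(cand) # Bland: smallest improving index
      colj <- Tab[, j]
      rows <- which(colj > tol)
      if (length(rows) == 0L) return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- Tab[rows, n_all + 1L] / colj[rows]
      rmin <- min(ratio)
      tie <- rows[ratio <= rmin + tol]
      i <- tie[which.min(basis[tie])] # Bland: leave smallest basis index
      p <- pivot(Tab, basis, i, j)
      Tab <- p$Tab; basis <- p$basis
    }
  }

  # phase 1: drive artificials to zero (maximize -sum(artificials))
  cost1 <- rep(0, n_all)
  cost1[art_cols] <- -1
  allowed1 <- rep(TRUE, n_all)
  ph1 <- run_simplex(Tab, basis, cost1, allowed1)
  Tab <- ph1$Tab; basis <- ph1$basis
  ph1_obj <- -sum(cost1[basis] * Tab[, n_all + 1L])
  if (ph1_obj > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  # pivot remaining basic artificials out where possible
  for (i in which(basis %in% art_cols)) {
    cols <- which(abs(Tab[i, seq_len(nf + m_bd)]) > tol)
    if (length(cols) > 0L) {
      p <- pivot(Tab, basis, i, cols[1L])
      Tab <- p$Tab; basis <- p$basis
    }
  }
  # phase 2
  cost2 <- rep(0, n_all)
  cost2[seq_len(nf)] <- cf
  allowed2 <- rep(TRUE, n_all)
  allowed2[art_cols] <- FALSE
  ph2 <- run_simplex(Tab, basis, cost2, allowed2)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  Tab <- ph2$Tab; basis <- ph2$basis
  x <- rep(0, n_all)
  x[basis] <- Tab[, n_all + 1L]
  v_out[free] <- x[seq_len(nf)] + lb[free]
  objv <- sum(obj * v_out)
  list(status = "optimal", objective = objv, solution = v_out)
}
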