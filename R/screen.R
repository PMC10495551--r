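#' Run the hybrid pipeline for one set of initial conditions
#'
#' The full coupling chain: clamp every fixed node, propagate values, compute
#' the minimal trap spaces of the clamped network, derive zero-flux
#' constraints from metabolic components with asymptotic maximum 0, apply
#' them, run FBA and compute the ATP shares.
#'
#' @param net A [boolean_network()].
#' @param conditions An [initial_conditions()].
#' @param map A [component_map()].
#' @param model A [metabolic_model()].
#' @param objective An [objective_spec()].
#' @param ... Passed to [compute_minimal_trap_spaces()].
#' @return List with `trap_spaces`, `constraints`, `fba`
#'   (`flux_distribution`), `shares` (or `NULL` when FBA is not optimal).
#' @export
run_hybrid_pipeline <- function(net, conditions, map, model, objective, ...) {
  clamps <- conditions_to_clamping(conditions)
  prop <- propagate_values(net, clamps)
  clamped <- apply_clamping(net, prop)
  spaces <- compute_minimal_trap_spaces(clamped, ...)
  constraints <- derive_constraints(spaces, map, net = net, model = model)
  constrained <- apply_constraints(model, constraints)
  fba <- run_fba(constrained, objective)
  shares <- if (fba$status == "optimal" && fba$objective_value > 0) {
    atp_shares(fba)
  } else NULL
  list(trap_spaces = spaces, constraints = constraints, fba = fba,
       shares = shares)
}

#' Classify a metabolic profile from its ATP shares
#'
#' @param shares Named vector from [atp_shares()], or `NULL` for an
#'   infeasible/zero-ATP condition.
#' @param threshold Glycolytic-share percentage above which (strictly) the
#'   profile is called glycolytic; default 50.
#' @return `"glycolytic"`, `"oxidative"` or `"infeasible"`.
#' @export
classify_profile <- function(shares, threshold = 50) {
  if (is.null(shares) || anyNA(shares)) return("infeasible")
  if (shares[["glycolytic"]] > threshold) "glycolytic" else "oxidative"
}

#' Enumerate single-node flip perturbations of fixed initial conditions
#'
#' Mimics systematic in-silico knock-out/knock-in: every node fixed at 1 in
#' the base conditions is flipped to 0 and vice versa, one node per
#' condition, all other values unchanged. Conditions are ordered by node
#' order in the model and labelled `C1..Cn`.
#'
#' @param base An [initial_conditions()] (non-empty).
#' @param net A [boolean_network()].
#' @param scope `"all-fixed"` (every fixed node; default) or `"inputs"`
#'   (fixed input nodes only).
#' @return List of perturbation conditions, each a list with `id`, `node`,
#'   `flipped_to` and `conditions` (the flipped [initial_conditions()]).
#' @export
enumerate_perturbations <- function(base, net,
                                    scope = c("all-fixed", "inputs")) {
  scope <- match.arg(scope)
  stopifnot(inherits(base, "initial_conditions"), inherits(net, "boolean_network"))
  if (length(base$values) == 0L) stop("base conditions are empty", call. = FALSE)
  fixed <- intersect(net$nodes, names(base$values)) # deterministic model order
  if (scope == "inputs") fixed <- intersect(fixed, net$inputs)
  out <- vector("list", length(fixed))
  for (k in seq_along(fixed)) {
    nd <- fixed[k]
    flipped <- 1L - base$values[[nd]]
    values <- base$values
    values[nd] <- flipped
    out[[k]] <- list(
      id = paste0("C", k),
      node = nd,
      flipped_to = flipped,
      conditions = initial_conditions(values, base$provenance)
    )
  }
  out
}

#' Knock-out/knock-in screen over the hybrid pipeline
#'
#' Reruns the full hybrid pipeline for the unflipped baseline and for every
#' single-node flip of the base conditions, recording the ATP shares and the
#' profile class of each run. Per-condition failures (infeasible FBA, solver
#' errors) are recorded in the result rather than aborting the screen. The
#' control profile class — used later to call drivers — is determined from
#' the unconstrained model, i.e. an FBA with no regulatory constraints at
#' all.
#'
#' @inheritParams run_hybrid_pipeline
#' @param scope Passed to [enumerate_perturbations()].
#' @param threshold Passed to [classify_profile()].
#' @return Object of class `screen_result`: data.frame with one row per
#'   condition (baseline first) and columns `id`, `node`, `flipped_to`,
#'   `glycolytic`, `oxidative`, `class`, `n_constraints`, `status`; attribute
#'   `control_class` holds the unconstrained profile class.
#' @export
run_screen <- function(net, conditions, map, model, objective,
                       scope = c("all-fixed", "inputs"), threshold = 50, ...) {
  scope <- match.arg(scope)
  control_fba <- run_fba(model, objective)
  control_shares <- if (control_fba$status == "optimal" &&
                        control_fba$objective_value > 0) {
    atp_shares(control_fba)
  } else NULL
  control_class <- classify_profile(control_shares, threshold)

  perts <- enumerate_perturbations(conditions, net, scope)
  all_runs <- c(
    list(list(id = "baseline", node = NA_character_, flipped_to = NA_integer_,
              conditions = conditions)),
    perts
  )
  rows <- lapply(all_runs, function(p) {
    res <- tryCatch(
      run_hybrid_pipeline(net, p$conditions, map, model, objective, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(data.frame(id = p$id, node = p$node, flipped_to = p$flipped_to,
                        glycolytic = NA_real_, oxidative = NA_real_,
                        class = "error", n_constraints = NA_integer_,
                        status = conditionMessage(res), stringsAsFactors = FALSE))
    }
    sh <- res$shares
    data.frame(
      id = p$id, node = p$node, flipped_to = p$flipped_to,
      glycolytic = if (is.null(sh)) NA_real_ else sh[["glycolytic"]],
      oxidative = if (is.null(sh)) NA_real_ else sh[["oxidative"]],
      class = classify_profile(sh, threshold),
      n_constraints = nrow(res$constraints),
      status = res$fba$status,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "control_class") <- control_class
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Identify regulatory driver nodes from a screen
#'
#' Drivers are the flipped nodes of all screen conditions whose profile class
#' equals the control (healthy) class — flips that restore a control-like
#' metabolic profile. Ordered by oxidative share, descending. Failed
#' conditions never qualify.
#'
#' @param screen A `screen_result` from [run_screen()].
#' @param control_class Profile class to match; defaults to the screen's
#'   recorded unconstrained control class.
#' @return Character vector of driver node identifiers (possibly empty).
#' @export
identify_drivers <- function(screen, control_class = attr(screen, "control_class")) {
  stopifnot(inherits(screen, "screen_result"))
  cand <- screen[!is.na(screen$node) & screen$class == control_class, , drop = FALSE]
  cand <- cand[order(-cand$oxidative), , drop = FALSE]
  cand$node
}
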