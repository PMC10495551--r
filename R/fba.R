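#' ATP-production objective specification
#'
#' The objective used throughout is the unweighted sum of the fluxes of the
#' ATP-producing reactions, split into two roles: the glycolytic
#' substrate-level phosphorylation steps (phosphoglycerate kinase and
#' pyruvate kinase, steps seven and ten of glycolysis) and the oxidative
#' route (OXPHOS complex V). The roles partition the objective, so the two
#' ATP shares always sum to 100%.
#'
#' @param glycolytic Character vector of glycolytic-role reaction ids.
#' @param oxidative Character vector of oxidative-role reaction ids.
#' @return Object of class `objective_spec`: data.frame with columns
#'   `reaction`, `role`.
#' @examples
#' objective_spec(glycolytic = c("PGK", "PYK"), oxidative = "CV")
#' @export
objective_spec <- function(glycolytic, oxidative) {
  if (length(intersect(glycolytic, oxidative)) > 0L) {
    stop("a reaction cannot have both roles", call. = FALSE)
  }
  out <- data.frame(
    reaction = c(glycolytic, oxidative),
    role = c(rep("glycolytic", length(glycolytic)),
             rep("oxidative", length(oxidative))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("objective_spec", "data.frame")
  out
}

#' Read/write an objective specification as YAML
#'
#' The YAML layout is `glycolytic: [ids]` / `oxidative: [ids]`.
#'
#' @param path YAML file path.
#' @return [objective_spec()] (reading) or `path` invisibly (writing).
#' @export
read_objective_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$glycolytic) || is.null(y$oxidative)) {
    stop("objective YAML must declare 'glycolytic' and 'oxidative' reaction lists",
         call. = FALSE)
  }
  objective_spec(unlist(y$glycolytic), unlist(y$oxidative))
}

#' @rdname read_objective_yaml
#' @param objective An [objective_spec()].
#' @export
write_objective_yaml <- function(objective, path) {
  yaml::write_yaml(
    list(glycolytic = objective$reaction[objective$role == "glycolytic"],
         oxidative = objective$reaction[objective$role == "oxidative"]),
    path)
  invisible(path)
}

check_objective <- function(model, objective) {
  stopifnot(inherits(model, "metabolic_model"))
  bad <- setdiff(objective$reaction, model$reactions$id)
  if (length(bad) > 0L) {
    stop("objective reaction(s) absent from the model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Flux balance analysis
#'
#' Maximizes the unweighted sum of the objective reactions' fluxes subject to
#' steady state (`S v = 0`) and the model's flux bounds, via the package's
#' two-phase simplex. One optimal vertex is returned; alternate optima are
#' possible in degenerate models.
#'
#' @param model A [metabolic_model()].
#' @param objective An [objective_spec()].
#' @param feas_tol Steady-state residual tolerance used for the returned
#'   distribution's internal consistency check.
#' @return Object of class `flux_distribution`: list with `fluxes` (named),
#'   `objective_value`, `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective` (the spec).
#' @export
run_fba <- function(model, objective, feas_tol = 1e-6) {
  check_objective(model, objective)
  S <- stoichiometric_matrix(model)
  cc <- as.numeric(model$reactions$id %in% objective$reaction)
  sol <- solve_lp(cc, S, rep(0, nrow(S)),
                  lb = model$reactions$lb, ub = model$reactions$ub,
                  maximize = TRUE)
  fluxes <- stats::setNames(sol$solution, model$reactions$id)
  if (sol$status == "optimal") {
    resid <- max(abs(S %*% sol$solution))
    if (resid > feas_tol) {
      stop("solver returned a distribution violating steady state (residual ",
           format(resid), ")", call. = FALSE)
    }
  }
  structure(
    list(fluxes = fluxes, objective_value = sol$objective,
         status = sol$status, objective = objective),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("FBA result:", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Glycolytic and oxidative shares of ATP production
#'
#' @param flux A `flux_distribution` from [run_fba()].
#' @param objective Objective spec; defaults to the one stored in `flux`.
#' @return Named numeric vector `c(glycolytic = %, oxidative = %)`; the two
#'   entries sum to 100.
#' @export
atp_shares <- function(flux, objective = flux$objective) {
  if (flux$status != "optimal") {
    stop("ATP shares undefined: solver status is '", flux$status, "'", call. = FALSE)
  }
  total <- flux$objective_value
  if (!is.finite(total) || total <= 0) {
    stop("ATP shares undefined: objective value is ", format(total), call. = FALSE)
  }
  gly <- sum(flux$fluxes[objective$reaction[objective$role == "glycolytic"]])
  oxi <- sum(flux$fluxes[objective$reaction[objective$role == "oxidative"]])
  c(glycolytic = 100 * gly / total, oxidative = 100 * oxi / total)
}

#' Carbon-flux shares of exchange reactions
#'
#' For the requested direction, each active exchange reaction's share is
#' `100 * carbons * |flux| / sum(carbons * |flux|)` over the carbon-carrying
#' exchanges active in that direction. Carbon-free exchanges (O2, H2O,
#' phosphate, protons) are excluded; a carbon-carrying exchanged metabolite
#' without a formula is an error.
#'
#' @param model A [metabolic_model()].
#' @param flux A `flux_distribution`.
#' @param direction `"uptake"` or `"secretion"`.
#' @param zero_tol Fluxes with magnitude below this are inactive.
#' @return data.frame with `reaction`, `metabolite`, `carbons`, `flux`,
#'   `share` (percent, sums to 100 when any carbon flows).
#' @export
carbon_flux_shares <- function(model, flux, direction = c("uptake", "secretion"),
                               zero_tol = 1e-9) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "metabolic_model"))
  ex <- exchange_metabolites(model)
  if (nrow(ex) == 0L) stop("model declares no exchange reactions", call. = FALSE)
  v <- flux$fluxes[ex$reaction]
  # net removal of the metabolite from the cell: coefficient * flux < 0 means
  # the metabolite is consumed internally, i.e. secreted through the exchange
  net <- ex$coefficient * v
  active <- if (direction == "uptake") net > zero_tol else net < -zero_tol
  ex <- ex[active, , drop = FALSE]
  v <- v[active]
  met_idx <- match(ex$metabolite, model$metabolites$id)
  formulas <- model$metabolites$formula[met_idx]
  carbons <- formula_element_count(formulas)
  carbonated <- !is.na(carbons) & carbons > 0L
  no_formula <- is.na(formulas)
  if (any(no_formula)) {
    stop("active exchanged metabolite(s) without a chemical formula: ",
         paste(ex$metabolite[no_formula], collapse = ", "), call. = FALSE)
  }
  ex <- ex[carbonated, , drop = FALSE]
  v <- v[carbonated]
  carbons <- carbons[carbonated]
  w <- carbons * abs(v)
  share <- if (sum(w) > 0) 100 * w / sum(w) else rep(NA_real_, length(w))
  out <- data.frame(reaction = ex$reaction, metabolite = ex$metabolite,
                    carbons = carbons, flux = unname(v), share = unname(share),
                    stringsAsFactors = FALSE)
  out[order(-out$share), , drop = FALSE]
}

#' Compare two flux distributions reaction by reaction
#'
#' Reports reactions whose flux magnitude changed more than `fold`-fold
#' between conditions. Fluxes below `zero_tol` count as zero; zero-to-nonzero
#' is `"activated"` and nonzero-to-zero `"silenced"`, both always reported.
#'
#' @param control,disease `flux_distribution` objects over the same reactions.
#' @param fold Fold-change threshold (default 2).
#' @param zero_tol Zero threshold (default 1e-9).
#' @return data.frame with `reaction`, `control`, `disease`, `ratio`
#'   (magnitude ratio, `Inf` for activations), `change` in
#'   `increased`/`decreased`/`activated`/`silenced`.
#' @export
compare_fluxes <- function(control, disease, fold = 2, zero_tol = 1e-9) {
  if (!identical(names(control$fluxes), names(disease$fluxes))) {
    stop("flux distributions cover different reaction sets", call. = FALSE)
  }
  a <- abs(control$fluxes)
  b <- abs(disease$fluxes)
  za <- a < zero_tol
  zb <- b < zero_tol
  ratio <- ifelse(za & zb, 1, ifelse(za, Inf, b / a))
  change <- rep(NA_character_, length(a))
  change[za & !zb] <- "activated"
  change[!za & zb] <- "silenced"
  grew <- !za & !zb & ratio > fold
  shrank <- !za & !zb & ratio < 1 / fold
  change[grew] <- "increased"
  change[shrank] <- "decreased"
  keep <- !is.na(change)
  data.frame(reaction = names(a)[keep], control = unname(control$fluxes[keep]),
             disease = unname(disease$fluxes[keep]), ratio = unname(ratio[keep]),
             change = change[keep], stringsAsFactors = FALSE)
}
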