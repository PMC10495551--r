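#' Evaluate a knock-out/knock-in scenario asymptotically
#'
#' Translates an experimental scenario into clamps (knock-out = 0, knock-in
#' = 1), propagates values, computes the minimal trap spaces of the clamped
#' network, and reports each readout's asymptotic value: `"0"` or `"1"` when
#' the readout is fixed at the same value in every minimal trap space,
#' `"varies"` otherwise (including when it is free in some trap space).
#'
#' @param net A `boolean_network`.
#' @param scenario A [clamping()] encoding the experimental condition.
#' @param readouts Character vector of nodes to report.
#' @param ... Passed to [compute_minimal_trap_spaces()].
#' @return Named character vector over `readouts` with values `"0"`, `"1"`,
#'   `"varies"`.
#' @examples
#' net <- boolean_network(list(Hypoxia = NULL, HIF1 = "Hypoxia",
#'                             PDK1 = "HIF1", PDH = "!PDK1"))
#' evaluate_scenario(net, clamping(c(Hypoxia = 1)), "PDH")
#' @export
evaluate_scenario <- function(net, scenario, readouts, ...) {
  stopifnot(inherits(net, "boolean_network"))
  bad <- setdiff(readouts, net$nodes)
  if (length(bad) > 0L) {
    stop("readout(s) absent from the network: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prop <- propagate_values(net, scenario)
  clamped <- apply_clamping(net, prop)
  spaces <- compute_minimal_trap_spaces(clamped, ...)
  out <- vapply(readouts, function(nm) {
    vals <- vapply(spaces, function(sp) {
      if (nm %in% names(sp)) as.integer(sp[[nm]]) else NA_integer_
    }, integer(1))
    if (anyNA(vals) || length(unique(vals)) != 1L) "varies" else as.character(vals[1L])
  }, character(1))
  stats::setNames(out, readouts)
}
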