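#' Reproduce the breast-CAF hybrid analysis from archived inputs
#'
#' Runs the complete published-style analysis given the deposited inputs: the
#' breast CAF SBML-qual regulatory model, the MitoCore SBML metabolic model,
#' the contextualized initial-condition table, the regulatory-metabolic
#' component map and the ATP objective configuration. None of these files
#' ship with the package (the regulatory model and MitoCore are distributed
#' through public model repositories; the archived configuration accompanies
#' the original study); point the arguments at a local copy.
#'
#' @param qual_path SBML-qual regulatory model.
#' @param metabolic_path SBML/fbc metabolic model.
#' @param conditions_path Initial-condition TSV (`node value provenance`).
#' @param map_path Component-map TSV.
#' @param objective_path Objective YAML.
#' @param max_free_nodes Trap-space solver limit for the clamped model.
#' @return List with `n_nodes`, `n_inputs`, `n_trap_spaces`,
#'   `n_constrained_reactions`, `control_shares`, `disease_shares`,
#'   `control_uptake`, `disease_uptake`, `disease_secretion` (carbon-flux
#'   tables), `screen` and `drivers`.
#' @export
reproduce_published_analysis <- function(qual_path, metabolic_path,
                                         conditions_path, map_path,
                                         objective_path,
                                         max_free_nodes = 24L) {
  net <- parse_sbml_qual(qual_path)
  model <- parse_sbml_metabolic(metabolic_path)
  conditions <- read_conditions_tsv(conditions_path)
  map <- read_component_map_tsv(map_path)
  objective <- read_objective_yaml(objective_path)

  res <- run_hybrid_pipeline(net, conditions, map, model, objective,
                             max_free_nodes = max_free_nodes)
  control <- run_fba(model, objective)
  screen <- run_screen(net, conditions, map, model, objective,
                       scope = "all-fixed", max_free_nodes = max_free_nodes)
  list(
    n_nodes = length(net$nodes),
    n_inputs = length(net$inputs),
    n_trap_spaces = length(res$trap_spaces),
    n_constrained_reactions = nrow(res$constraints),
    control_shares = atp_shares(control),
    disease_shares = res$shares,
    control_uptake = carbon_flux_shares(model, control, "uptake"),
    disease_uptake = carbon_flux_shares(model, res$fba, "uptake"),
    disease_secretion = carbon_flux_shares(model, res$fba, "secretion"),
    screen = screen,
    drivers = identify_drivers(screen)
  )
}
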