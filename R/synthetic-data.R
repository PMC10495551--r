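#' Seeded fixture generators
#'
#' Self-contained synthetic inputs for every pipeline stage: a coupled toy
#' regulatory/metabolic system with a planted hypoxia-type driver, synthetic
#' expression contrast tables with planted up/down gene sets, and random
#' Boolean networks for oracle-equivalence testing. All randomness is local
#' to a single integer seed; the global RNG state is left untouched.
#'
#' @name synthetic-data
NULL

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Toy coupled regulatory/metabolic system with a planted driver
#'
#' Emulates, at miniature scale, the situation the hybrid framework is built
#' for: a hypoxia-type input drives a HIF-type factor which activates a PDK
#' kinase that inactivates pyruvate dehydrogenase, switching ATP production
#' from oxidative phosphorylation to aerobic glycolysis. The regulatory core
#' is `Hypoxia -> HIF1 -> PDK1 -| PDH`; PDH is the only mapped metabolic
#' component (enzyme of the lumped TCA/OXPHOS entry reaction). Decoy inputs
#' wired to non-metabolic target nodes are added so the perturbation screen
#' has negatives; they never touch the component map, so the planted driver
#' is the only node whose flip can change the metabolic profile class.
#'
#' The metabolic side is a lumped glycolysis/TCA/OXPHOS chain with glucose
#' uptake capped at 10 flux units. With PDH active the unique optimum routes
#' all pyruvate through the TCA lump (objective 140 = 20 + 20 substrate-level
#' + 100 complex-V; oxidative share 5/7), with PDH inactive all pyruvate goes
#' to lactate (objective 40; glycolytic share 100%).
#'
#' @param seed Integer seed.
#' @param n_decoy_inputs Number of decoy inputs (default 3).
#' @return List of class `toy_coupled_system` with `net`, `model`, `map`,
#'   `objective`, `baseline` ([initial_conditions()] with the hypoxia driver
#'   at 1), `driver`, `expected_baseline_class`, `expected_flip_class`, and
#'   `gene_aliases` (gene symbol -> node).
#' @export
make_toy_coupled_model <- function(seed = 1L, n_decoy_inputs = 3L) {
  stopifnot(n_decoy_inputs >= 0L)
  with_local_seed(seed, {
    funs <- list(
      Hypoxia = NULL,
      HIF1 = "Hypoxia",
      PDK1 = "HIF1",
      PDH = "!PDK1"
    )
    ann <- list(
      Hypoxia = list(name = "HYPOXIA_SIGNAL", class = "simple molecule"),
      HIF1 = list(name = "HIF1A", class = "protein"),
      PDK1 = list(name = "PDK1", class = "protein"),
      PDH = list(name = "PDHA1", class = "protein")
    )
    decoy_values <- integer()
    if (n_decoy_inputs > 0L) {
      for (k in seq_len(n_decoy_inputs)) {
        dcy <- paste0("DCY", k)
        tgt <- paste0("TGT", k)
        funs[dcy] <- list(NULL) # input (assigning NULL directly would drop the entry)
        funs[[tgt]] <- if (stats::runif(1) < 0.5) dcy else paste0("!", dcy)
        ann[[dcy]] <- list(name = paste0("DCYG", k), class = "gene")
        ann[[tgt]] <- list(name = paste0("TGTG", k), class = "protein")
        decoy_values[dcy] <- sample(0:1, 1L)
      }
    }
    net <- boolean_network(funs, annotations = ann)

    metabolites <- data.frame(
      id = c("glc", "triose", "pg", "pyr", "lac", "co2", "nadh", "o2", "h2o"),
      name = c("glucose", "triose phosphate", "phosphoglycerate", "pyruvate",
               "lactate", "carbon dioxide", "reducing equivalents", "oxygen",
               "water"),
      compartment = "c",
      formula = c("C6H12O6", "C3H7O6P", "C3H4O7P", "C3H3O3", "C3H5O3",
                  "CO2", "H", "O2", "H2O"),
      stringsAsFactors = FALSE
    )
    reactions <- data.frame(
      id = c("EX_glc", "GLY1", "PGK", "PYK", "LDH", "TCA", "CV",
             "EX_lac", "EX_o2", "EX_co2", "EX_h2o"),
      name = c("glucose exchange", "upper glycolysis (lumped)",
               "phosphoglycerate kinase", "pyruvate kinase",
               "lactate dehydrogenase", "TCA cycle (lumped, PDH entry)",
               "OXPHOS complex V (lumped)", "lactate exchange",
               "oxygen exchange", "CO2 exchange", "water exchange"),
      lb = c(-10, 0, 0, 0, 0, 0, 0, 0, -1000, 0, 0),
      ub = c(0, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 0, 1000, 1000),
      exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
    stoich <- rbind(
      data.frame(reaction = "EX_glc", metabolite = "glc", coefficient = -1),
      data.frame(reaction = "GLY1", metabolite = c("glc", "triose"),
                 coefficient = c(-1, 2)),
      data.frame(reaction = "PGK", metabolite = c("triose", "pg"),
                 coefficient = c(-1, 1)),
      data.frame(reaction = "PYK", metabolite = c("pg", "pyr"),
                 coefficient = c(-1, 1)),
      data.frame(reaction = "LDH", metabolite = c("pyr", "lac"),
                 coefficient = c(-1, 1)),
      data.frame(reaction = "TCA", metabolite = c("pyr", "co2", "nadh"),
                 coefficient = c(-1, 3, 5)),
      data.frame(reaction = "CV", metabolite = c("nadh", "o2", "h2o"),
                 coefficient = c(-1, -0.5, 1)),
      data.frame(reaction = "EX_lac", metabolite = "lac", coefficient = -1),
      data.frame(reaction = "EX_o2", metabolite = "o2", coefficient = -1),
      data.frame(reaction = "EX_co2", metabolite = "co2", coefficient = -1),
      data.frame(reaction = "EX_h2o", metabolite = "h2o", coefficient = -1)
    )
    model <- metabolic_model(metabolites, reactions, stoich)
    map <- component_map("PDH", "enzyme", list("TCA"))
    objective <- objective_spec(glycolytic = c("PGK", "PYK"), oxidative = "CV")
    baseline <- initial_conditions(
      c(c(Hypoxia = 1L), decoy_values),
      c("curated", rep("data-driven", length(decoy_values)))
    )
    aliases <- vapply(net$annotations, function(a) a$name, character(1))
    structure(
      list(net = net, model = model, map = map, objective = objective,
           baseline = baseline, driver = "Hypoxia",
           expected_baseline_class = "glycolytic",
           expected_flip_class = "oxidative",
           gene_aliases = stats::setNames(names(aliases), unname(aliases))),
      class = "toy_coupled_system"
    )
  })
}

#' Synthetic expression contrast table with planted truth
#'
#' Generates a contrast table in which `n_up` genes are planted above the
#' fold-change threshold with significant adjusted p-values, `n_down`
#' symmetrically below, and the remaining genes are nulls designed to probe
#' the conjunction of the two thresholds: a third carries a large fold change
#' with a non-significant p-value, a third a significant p-value with a small
#' fold change, and the rest fail both cuts.
#'
#' @param seed Integer seed.
#' @param n_genes Total number of genes.
#' @param n_up,n_down Planted set sizes (`n_up + n_down <= n_genes`).
#' @param fc_up Minimum planted linear fold change (must exceed the caller's
#'   threshold; default 2).
#' @param p_signif Upper bound for planted adjusted p-values (default 0.01).
#' @param genes Optional gene-symbol vector (length `n_genes`); defaults to
#'   `G1..Gn`.
#' @return List with `contrast` ([expression_contrast()]), `up`, `down`
#'   (planted truth).
#' @export
make_toy_expression_table <- function(seed = 1L, n_genes = 100L, n_up = 10L,
                                      n_down = 5L, fc_up = 2, p_signif = 0.01,
                                      genes = NULL) {
  if (n_up + n_down > n_genes) {
    stop("n_up + n_down exceeds n_genes", call. = FALSE)
  }
  if (fc_up <= 1) stop("fc_up must exceed 1 (linear fold change)", call. = FALSE)
  if (is.null(genes)) genes <- paste0("G", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  with_local_seed(seed, {
    idx <- sample.int(n_genes)
    up_idx <- idx[seq_len(n_up)]
    down_idx <- idx[n_up + seq_len(n_down)]
    null_idx <- idx[-(seq_len(n_up + n_down))]
    fc <- numeric(n_genes)
    p <- numeric(n_genes)
    fc[up_idx] <- stats::runif(n_up, fc_up, fc_up * 2)
    fc[down_idx] <- -stats::runif(n_down, fc_up, fc_up * 2)
    p[c(up_idx, down_idx)] <- stats::runif(n_up + n_down, 0, p_signif * 0.99)
    n_null <- length(null_idx)
    if (n_null > 0L) {
      kind <- rep_len(c("big_fc", "small_p", "neither"), n_null)
      for (j in seq_len(n_null)) {
        g <- null_idx[j]
        if (kind[j] == "big_fc") {       # fails the p cut only
          fc[g] <- sample(c(-1, 1), 1L) * stats::runif(1, fc_up, fc_up * 2)
          p[g] <- stats::runif(1, 0.10, 1)
        } else if (kind[j] == "small_p") { # fails the FC cut only
          fc[g] <- stats::runif(1, -1.2, 1.2)
          p[g] <- stats::runif(1, 0, p_signif * 0.99)
        } else {
          fc[g] <- stats::runif(1, -1.2, 1.2)
          p[g] <- stats::runif(1, 0.10, 1)
        }
      }
    }
    list(
      contrast = expression_contrast(genes, fc, p, "linear"),
      up = genes[sort(up_idx)],
      down = genes[sort(down_idx)]
    )
  })
}

#' Random Boolean network generator
#'
#' Random update rules over at most `max_in_degree` regulators per node:
#' each node is, with small probability, a constant or an input; otherwise
#' its rule combines randomly negated regulators with random AND/OR
#' operators. Intended for oracle-equivalence and propagation-soundness
#' testing at small sizes.
#'
#' @param seed Integer seed.
#' @param n_nodes Number of nodes.
#' @param max_in_degree Maximum regulators per rule (default 3).
#' @param p_input Probability that a node is an input (default 0.15).
#' @param p_constant Probability that a node is a constant (default 0.05).
#' @return A [boolean_network()] with nodes `N1..Nn`.
#' @export
make_random_boolean_network <- function(seed, n_nodes, max_in_degree = 3L,
                                        p_input = 0.15, p_constant = 0.05) {
  stopifnot(n_nodes >= 1L, max_in_degree >= 0L)
  with_local_seed(seed, {
    nodes <- paste0("N", seq_len(n_nodes))
    funs <- stats::setNames(vector("list", n_nodes), nodes)
    for (k in seq_len(n_nodes)) {
      u <- stats::runif(1)
      if (u < p_constant || max_in_degree == 0L) {
        funs[[k]] <- sample(c(TRUE, FALSE), 1L)
      } else if (u < p_constant + p_input) {
        funs[k] <- list(NULL) # input
      } else {
        d <- sample.int(max_in_degree, 1L)
        regs <- sample(nodes, d, replace = FALSE)
        lits <- ifelse(stats::runif(d) < 0.5, regs, paste0("!", regs))
        if (d == 1L) {
          funs[[k]] <- lits
        } else {
          ops <- sample(c("&", "|"), d - 1L, replace = TRUE)
          txt <- lits[1L]
          for (j in seq_len(d - 1L)) txt <- paste(txt, ops[j], lits[j + 1L])
          funs[[k]] <- txt
        }
      }
    }
    boolean_network(funs)
  })
}

#' Write all fixtures of a toy coupled system to a directory
#'
#' Serializes the system in the same standard formats real inputs use:
#' `toyreg.sbml` (SBML-qual), `toymet.sbml` (SBML/fbc), `compmap.tsv`,
#' `conditions.tsv`, `objective.yaml`, `dea.tsv` (a contrast table planted to
#' reproduce the baseline decoy values through the contextualization module)
#' and `truth.json` (driver and expected classes).
#'
#' @param sys A [make_toy_coupled_model()] result.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the planted contrast table.
#' @param n_genes Size of the contrast table's gene universe.
#' @return `dir`, invisibly.
#' @export
write_toy_fixtures <- function(sys, dir, seed = 1L, n_genes = 60L) {
  stopifnot(inherits(sys, "toy_coupled_system"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sbml_qual(sys$net, file.path(dir, "toyreg.sbml"))
  write_sbml_metabolic(sys$model, file.path(dir, "toymet.sbml"),
                       objective = sys$objective)
  write_component_map_tsv(sys$map, file.path(dir, "compmap.tsv"))
  write_conditions_tsv(sys$baseline, file.path(dir, "conditions.tsv"))
  write_objective_yaml(sys$objective, file.path(dir, "objective.yaml"))
  dd <- sys$baseline$values[sys$baseline$provenance == "data-driven"]
  alias_of <- stats::setNames(names(sys$gene_aliases), sys$gene_aliases)
  up_genes <- alias_of[names(dd)[dd == 1L]]
  down_genes <- alias_of[names(dd)[dd == 0L]]
  filler <- paste0("G", seq_len(max(0L, n_genes - length(dd))))
  genes <- unname(c(up_genes, down_genes, filler))
  planted <- make_planted_contrast(genes, up_genes, down_genes, seed)
  write_contrast_tsv(planted, file.path(dir, "dea.tsv"))
  jsonlite::write_json(
    list(driver = sys$driver,
         expected_baseline_class = sys$expected_baseline_class,
         expected_flip_class = sys$expected_flip_class,
         planted_up = up_genes, planted_down = down_genes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

## Contrast table whose planted up/down sets are exactly the given genes.
make_planted_contrast <- function(genes, up_genes, down_genes, seed,
                                  fc_up = 2, p_signif = 0.01) {
  with_local_seed(seed, {
    fc <- stats::runif(length(genes), -1.2, 1.2)
    p <- stats::runif(length(genes), 0.10, 1)
    iu <- match(up_genes, genes)
    idn <- match(down_genes, genes)
    fc[iu] <- stats::runif(length(iu), fc_up, fc_up * 2)
    fc[idn] <- -stats::runif(length(idn), fc_up, fc_up * 2)
    p[c(iu, idn)] <- stats::runif(length(iu) + length(idn), 0, p_signif * 0.99)
    expression_contrast(genes, fc, p, "linear")
  })
}
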