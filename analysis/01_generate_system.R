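#!/usr/bin/env Rscript

# Step 1 — generate the study system.
#
# Builds the coupled toy regulatory/metabolic system (hypoxia-driven
# glycolytic switch with decoy inputs) and serializes every input the later
# steps consume, in the same standard formats real data would arrive in:
# SBML-qual for the regulatory model, SBML/fbc for the metabolic model, TSV
# for the component map / initial conditions / expression contrast, YAML for
# the ATP objective.

suppressPackageStartupMessages(library(boolfba))

seed <- 1L
fix_dir <- "results/fixtures"

sys <- make_toy_coupled_model(seed = seed, n_decoy_inputs = 3L)
write_toy_fixtures(sys, fix_dir, seed = seed)

cat("Regulatory model:", length(sys$net$nodes), "nodes,",
    length(sys$net$inputs), "inputs\n")
cat("Metabolic model:", nrow(sys$model$metabolites), "metabolites,",
    nrow(sys$model$reactions), "reactions (",
    sum(sys$model$reactions$exchange), "exchanges )\n")
cat("Planted driver:", sys$driver, "- baseline fixes",
    length(sys$baseline$values), "nodes\n")
cat("Fixtures written to", fix_dir, "\n")
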