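#!/usr/bin/env Rscript

# Step 2 — contextualize the regulatory model.
#
# Calls differentially expressed genes from the contrast table at the
# standard thresholds (adjusted p < 0.05, |FC| > 1.5), discretizes them onto
# model nodes (up -> 1, down -> 0), and fills the remaining input nodes from
# the curated assignments. The merged table of initial conditions drives all
# later steps.

suppressPackageStartupMessages(library(boolfba))

fix_dir <- "results/fixtures"
net <- parse_sbml_qual(file.path(fix_dir, "toyreg.sbml"))
contrast <- read_contrast_tsv(file.path(fix_dir, "dea.tsv"))
shipped <- read_conditions_tsv(file.path(fix_dir, "conditions.tsv"))

degs <- call_degs(contrast, p_threshold = 0.05, fc_threshold = 1.5)
cat("DEGs called:", length(degs$up), "up,", length(degs$down), "down of",
    nrow(contrast), "genes\n")

data_driven <- map_and_discretize(degs$up, degs$down, net)
cat("Mapped onto", length(data_driven$values), "nodes;",
    length(attr(data_driven, "unmapped")), "genes unmapped\n")

curated <- initial_conditions(
  shipped$values[shipped$provenance == "curated"], "curated")
merged <- merge_with_curation(data_driven, curated, net)
cat("Merged conditions fix", length(merged$values), "nodes (",
    sum(merged$provenance == "data-driven"), "data-driven,",
    sum(merged$provenance == "curated"), "curated );",
    length(attr(merged, "unfixed_inputs")), "inputs left unfixed\n")

write_conditions_tsv(merged, "results/conditions.tsv")
cat("Wrote results/conditions.tsv\n")
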