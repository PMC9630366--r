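#!/usr/bin/env Rscript
# Generate the synthetic cross-study design: a catalog of mouse/rat SNI,
# ScNI and SpNI comparisons with planted conserved, species-preference and
# null genes, written as the same TSV dialect the readers consume.

suppressMessages(library(drgmeta))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)

out_dir <- "results/simulated"
dir.create(file.path(out_dir, "tables"), recursive = TRUE,
           showWarnings = FALSE)

cfg <- generator_config(seed = seed)
sim <- generate_comparisons(cfg)

write_study_catalog(sim$catalog, file.path(out_dir, "catalog.tsv"))
readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
yaml::write_yaml(unclass(cfg), file.path(out_dir, "generator_config.yaml"))
for (tab in sim$tables) {
  write_comparison_table(
    tab, file.path(out_dir, "tables", paste0(tab$comparison_id, ".tsv")))
}

message(sprintf(
  "simulated %d comparisons across %d groups, %d genes each (%d planted effect genes); wrote %s",
  nrow(sim$catalog), length(group_comparisons(sim$catalog)), cfg$n_genes,
  sum(sim$truth$class != "null"), out_dir))
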