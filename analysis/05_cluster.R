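#!/usr/bin/env Rscript
# Temporal expression patterns: standardize the simulated time-series
# datasets, soft-cluster DEG profiles by fuzzy c-means, and map cluster
# correspondence between the first (reference) dataset and the others.

suppressMessages(library(drgmeta))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)

out_dir <- "results/temporal"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg_gen <- generator_config(seed = seed)
cfg <- analysis_config(seed = seed)
ts <- generate_timeseries(cfg_gen)

fits <- list()
for (ds in names(ts$datasets)) {
  x <- standardize_rows(ts$datasets[[ds]])
  # four planted archetypes; the configured default of eight clusters is
  # meant for real DEG sets, so the drivers cluster at the archetype count
  fit <- fuzzy_cmeans(x, c = 4, m = cfg$fuzzifier, seed = cfg$seed)
  fits[[ds]] <- fit
  mem <- tibble::as_tibble(fit$membership, .name_repair = ~paste0("cls", seq_along(.)))
  mem <- cbind(tibble::tibble(gene_id = rownames(fit$membership),
                              hard = fit$hard), mem)
  readr::write_tsv(mem, file.path(out_dir, paste0(ds, "_membership.tsv")))
  tab <- table(ts$truth$archetype[match(names(fit$hard),
                                        ts$truth$gene_id)], fit$hard)
  message(sprintf("%s: %d iterations, purity vs planted archetypes %.3f",
                  ds, fit$iterations, sum(apply(tab, 2, max)) / sum(tab)))
}

cc <- cluster_correspondence(fits[[1]]$hard,
                             lapply(fits[-1], `[[`, "hard"),
                             min_shared = cfg$correspondence_min)
readr::write_tsv(cc, file.path(out_dir, "correspondence.tsv"))
message(sprintf(
  "correspondence: %d edges with >= %d shared genes between reference and %d other dataset(s)",
  nrow(cc), cfg$correspondence_min, length(fits) - 1L))
message("wrote memberships and correspondence edges to ", out_dir)
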