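#!/usr/bin/env Rscript
# Rank each comparison's DEGs by pi-value (log2FC for no-replicate tables)
# and summarize how often genes recur in the per-comparison top 15, per
# species x model group. Expects analysis/01_simulate.R outputs.

suppressMessages(library(drgmeta))

in_dir <- "results/simulated"
out_dir <- "results/ranking"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

catalog <- read_study_catalog(file.path(in_dir, "catalog.tsv"))
tables <- lapply(catalog$comparison_id, function(id) {
  read_comparison_table(file.path(in_dir, "tables", paste0(id, ".tsv")),
                        comparison_id = id)
})
names(tables) <- catalog$comparison_id
cfg <- analysis_config()

ranked_all <- list()
for (id in names(tables)) {
  rk <- rank_genes(tables[[id]], cfg)
  ranked_all[[id]] <- rk
  both <- rbind(cbind(direction = "up", rk$up),
                cbind(direction = "down", rk$down))
  readr::write_tsv(both, file.path(out_dir, paste0(id, "_ranked.tsv")))
}

freq_rows <- list()
for (grp in names(grps <- group_comparisons(catalog))) {
  freq <- topk_frequency(ranked_all[grps[[grp]]], k = cfg$top_k)
  freq$group <- grp
  freq_rows[[grp]] <- freq
  top <- freq[freq$direction == "up", ][1:3, ]
  message(sprintf("%s: most recurrent top-%d up genes: %s", grp, cfg$top_k,
                  paste(sprintf("%s (%d/%d)", top$gene_id, top$count,
                                top$denominator), collapse = ", ")))
}
readr::write_tsv(do.call(rbind, freq_rows),
                 file.path(out_dir, "topk_frequency.tsv"))
message("wrote per-comparison rankings and group frequencies to ", out_dir)
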