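#!/usr/bin/env Rscript
# Step 1: simulate a structured lung-like section with known ground truth.
#
# Generates the tissue used by the downstream steps (three TLS, bronchi,
# vessels, a mesothelial capsule, CD4 expression gradients with
# a = 20 counts, lambda = 100 um, b = 1) plus a pooled hashtag droplet
# experiment, and writes everything under results/01_simulate/.

suppressPackageStartupMessages(library(tlsniche))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
tis <- generate_tissue(cfg)
message(sprintf("simulated %d cells over %d structures (%s)",
                nrow(tis$cells), nrow(tis$truth$structures),
                paste(sprintf("%d %s", table(tis$truth$structures$kind),
                              names(table(tis$truth$structures$kind))),
                      collapse = ", ")))
print(table(tis$cells$true_zone))

write_cell_table(tis$cells, file.path(out, "cells.csv"))
write_counts_mtx(tis$counts, out)
utils::write.csv(tis$gene_info, file.path(out, "gene_panel.csv"),
                 row.names = FALSE)
utils::write.csv(tis$truth$cell_truth, file.path(out, "cell_truth.csv"),
                 row.names = FALSE)
utils::write.csv(tis$truth$structures, file.path(out, "structures.csv"),
                 row.names = FALSE)
jsonlite::write_json(tis$truth$params, file.path(out, "gradient_truth.json"),
                     auto_unbox = TRUE, digits = NA)

hto <- generate_hashtag_counts(n_hashtags = 10, n_singlets = 200,
                               n_doublets = 100, n_empty = 50,
                               signal_mean = 100, background_mean = 1,
                               seed = seed + 1L)
utils::write.csv(hto$counts, file.path(out, "hashtag_counts.csv"))
utils::write.csv(hto$truth, file.path(out, "hashtag_truth.csv"),
                 row.names = FALSE)
message(sprintf("simulated %d droplets (%d singlets, %d doublets, %d empty)",
                nrow(hto$counts), sum(hto$truth$label == "singlet"),
                sum(hto$truth$label == "doublet"),
                sum(hto$truth$label == "empty")))
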