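#!/usr/bin/env Rscript
# Step 2: demultiplex the simulated hashtag droplets and apply the QC
# rules (10-count / strictly-more-than-double demultiplexing; 10-transcript
# minimum for spatial cells), reporting accuracy against ground truth.

suppressPackageStartupMessages(library(tlsniche))
sim <- "results/01_simulate"
out <- "results/02_preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hto <- as.matrix(utils::read.csv(file.path(sim, "hashtag_counts.csv"),
                                 row.names = 1L))
truth <- utils::read.csv(file.path(sim, "hashtag_truth.csv"))
dmx <- demux_hashtags(hto, naive_doublets = TRUE)
utils::write.csv(dmx, file.path(out, "demux.csv"), row.names = FALSE)

singlet <- truth$label == "singlet"
acc <- mean(dmx$label[singlet] == truth$hashtag[singlet])
message(sprintf("singlet assignment accuracy: %.2f%% of %d singlets",
                100 * acc, sum(singlet)))
message(sprintf("labelled doublet: %d of %d true doublets",
                sum(dmx$label[truth$label == "doublet"] == "doublet"),
                sum(truth$label == "doublet")))

cells <- read_cell_table(file.path(sim, "cells.csv"))
counts <- read_counts(file.path(sim, "counts.mtx"),
                      barcodes_path = file.path(sim, "barcodes.tsv"),
                      genes_path = file.path(sim, "genes.tsv"),
                      cell_table = cells)
kept <- qc_filter_spatial(counts, min_counts = 10)
message(sprintf("spatial QC: kept %d of %d cells (>= 10 transcripts)",
                length(kept), nrow(counts)))
writeLines(kept, file.path(out, "kept_cells.txt"))
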