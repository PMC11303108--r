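#!/usr/bin/env Rscript

# Step 1 — generate the synthetic study inputs.
#
# Emulates the workflow's raw materials on a toy genome: CUT&Tag-style peak
# calls for c-Fos (TF), H3K27ac, H3K4me3 and H3K27me3 in normal and OIR
# retinas at P14, a rod-dominant single-cell count matrix with a bimodal
# TF in OIR rods, and promoter sequences with planted TRE sites. Every
# planted signal is recorded in a truth ledger so downstream steps can be
# scored. All later steps read the bundle from results/bundle.

suppressMessages(library(fostarget))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 0L
out <- "results/bundle"

cfg <- sim_config(seed = seed)
bundle <- simulate_bundle(cfg)
write_bundle(bundle, out)

cat("Synthetic bundle written to", out, "\n")
cat(sprintf("  genes: %d on %d chromosomes\n", nrow(bundle$genes),
            cfg$n_chromosomes))
cat(sprintf("  peak tracks: %d (4 marks + IgG x 2 conditions)\n",
            length(bundle$peaks)))
cat(sprintf("  cells: %d (%d per condition), genes detected per cell ~%d\n",
            nrow(bundle$cells$counts), cfg$n_cells_per_condition,
            round(mean(Matrix::rowSums(bundle$cells$counts > 0)))))
cat(sprintf("  planted: %d direct targets, %d total DEGs, decoys %s\n",
            length(bundle$truth$direct_targets),
            length(bundle$truth$planted_degs),
            paste(lengths(bundle$truth$decoys), collapse = "/")))
cat(sprintf("  promoters: %d sequences of %d bp\n",
            length(bundle$promoters), cfg$promoter_length))
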