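#!/usr/bin/env Rscript

# Step 4 — candidate direct targets: gate x expression x DEG intersection.
#
# Re-runs the full chain in memory (the package orchestrator guarantees
# identical logic to steps 2-3) and writes the discovery report:
# genes gated exclusively in OIR, filtered to those expressed in OIR rods,
# intersected with OIR-exclusive DEGs. Scores the candidates against the
# generator's planted direct targets.

suppressMessages(library(fostarget))

b <- read_bundle("results/bundle")
report <- run_pipeline(b$genes, b$peaks, b$cells, b$markers,
                       tf_gene_id = b$truth$tf_gene_id)
print(report)
write_report(report, "results/discovery")

sc <- score_recovery(report, b$truth)
cat(sprintf("planted-target recovery: sensitivity %.2f, precision %.2f (tp=%d fp=%d fn=%d)\n",
            sc["sensitivity"], sc["precision"], sc["tp"], sc["fp"], sc["fn"]))
cat("report written to results/discovery/\n")
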