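#!/usr/bin/env Rscript
# Stage 1 — simulate the paired study dataset.
#
# Emits a 16-sample community on the stratified-lake sampling grid (four
# depths, four months, three oxygen regimes) with 60 taxa, three planted hub
# taxa carrying environmental effects, and an expression (RNA) layer whose
# interaction network is 30% re-wired relative to the abundance (DNA) layer.
# Everything downstream reads the TSVs written here; truth.json records the
# planted ground truth for later comparison.

library(keystonet)

SEED <- 1
out <- "results/data"

sim <- simulate_dataset(synthetic_config(seed = SEED))
write_synthetic_dataset(sim, out)

sz <- condition_sizes(assign_condition_groups(sim$meta))
write.table(sz, file.path(out, "condition_sizes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("samples:", nrow(sim$meta), " taxa:", length(sim$network$taxon_ids),
    " planted hubs:", paste(sim$network$hub_ids, collapse = ", "), "\n")
cat("condition groups:", nrow(sz), "(expected 11)\n")
cat("written to", out, "\n")
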