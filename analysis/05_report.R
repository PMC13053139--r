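#!/usr/bin/env Rscript
# Stage 5 — collate the headline numbers from all stages into one summary.

library(keystonet)

com <- "results/community"
net <- "results/network"
rob <- "results/robustness"

perm <- read.delim(file.path(com, "permanova.tsv"))
prev <- read.delim(file.path(com, "prevalence.tsv"))
rk <- read.delim(file.path(net, "degree_ranking.tsv"))
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
top <- readLines(file.path(net, "top15_by_degree.txt"))
robres <- jsonlite::read_json(file.path(rob, "robustness_results.json"),
                              simplifyVector = TRUE)
coords <- read.delim(file.path(com, "pcoa_coordinates.tsv"), check.names = FALSE)

summary <- list(
  n_samples = nrow(coords),
  n_taxa = nrow(rk),
  permanova_model_r2_pct =
    round(100 * sum(perm$R2[perm$term %in% c("depth_m", "month", "oxygen")]), 2),
  top_prevalent_taxon = prev$taxon_id[1],
  top_prevalent_bar_percent = prev$Bar_Percent[1],
  planted_hubs_in_top15 = sum(truth$hub_ids %in% top),
  focal = robres)

jsonlite::write_json(summary, "results/summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

cat("== keystone workflow summary ==\n")
cat("combined PERMANOVA R2:", summary$permanova_model_r2_pct, "%\n")
cat("planted hubs in degree top-15:", summary$planted_hubs_in_top15, "of",
    length(truth$hub_ids), "\n")
for (i in seq_len(nrow(robres)))
  cat(sprintf("%s: CRI %.0f%% (DNA) / %.0f%% (RNA) -> %s\n",
              robres$focal_id[i], robres$index_dna[i], robres$index_rna[i],
              robres$classification[i]))
cat("full summary in results/summary.json\n")
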