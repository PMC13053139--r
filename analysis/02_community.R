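#!/usr/bin/env Rscript
# Stage 2 — community-level structure.
#
# TSS-normalises the abundance layer, screens for strongly concordant sample
# pairs (r > 0.8 under both Pearson and Spearman), builds the Bray-Curtis
# matrix on Hellinger-transformed counts, ordinates it by PCoA, tests
# depth/month/oxygen effects by sequential PERMANOVA with pairwise
# contrasts, and tabulates the top-10 most abundant taxa per condition.

library(keystonet)

SEED <- 1
dat <- "results/data"
out <- "results/community"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dna <- read_abundance_table(file.path(dat, "abundance_dna.tsv"),
                            "sample_major", "dna")
meta <- read_sample_metadata(file.path(dat, "metadata.tsv"))

tss <- tss_normalise(dna)
pairs <- sample_correlation_screen(tss, threshold = 0.8)
write.table(pairs, file.path(out, "correlation_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("concordant sample pairs (r > 0.8, both metrics):", nrow(pairs), "\n")

d <- bray_curtis(hellinger_transform(dna))
ord <- pcoa(d)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE),
            file.path(out, "pcoa_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA1 = %.2f%%, PCoA2 = %.2f%% of variance\n",
            ord$variance_explained[1], ord$variance_explained[2]))

fit <- permanova(d, meta, c("depth_m", "month", "oxygen"), n_perm = 999,
                 seed = derive_seed(SEED, "permanova"))
write.table(fit$table, file.path(out, "permanova.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(fit)

pw <- do.call(rbind, lapply(c("depth_m", "month", "oxygen"), function(f)
  suppressWarnings(cbind(factor_name = f,
    pairwise_permanova(d, meta, f, n_perm = 999,
                       seed = derive_seed(SEED, paste0("pw_", f)))))))
write.table(pw, file.path(out, "pairwise_permanova.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

groups <- assign_condition_groups(meta)
prev <- top_taxa_prevalence(tss, groups, k = 10)
write.table(prev$top_taxa, file.path(out, "top_taxa.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prev$prevalence, file.path(out, "prevalence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("taxa ever in a condition top-10:", nrow(prev$prevalence),
    "| max Presence_Count:", max(prev$prevalence$Presence_Count), "of",
    prev$n_conditions, "\n")
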