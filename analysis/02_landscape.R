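#!/usr/bin/env Rscript
# Step 2 — mutation landscape and co-occurrence structure.
#
# Applies the variant retention rules, builds the gene-by-patient mutation
# matrix, summarises the landscape (additional-mutation burden, per-category
# counts, isolated fractions, CNV rates), tests pairwise mutation-clinical
# associations with BH correction, learns the co-occurrence Bayesian
# network, and clusters genes on their VAF profiles.

library(pvhmr)

dir.create("results/landscape", recursive = TRUE, showWarnings = FALSE)
co <- read_cohort("scratch/cohort/variants.tsv", "scratch/cohort/cnv.tsv",
                  "scratch/cohort/clinical.tsv")

n_raw <- nrow(co$variants)
kept <- filter_variants(co$variants)
prog <- prognostic_subset(kept)
message(sprintf("variants: %d raw -> %d after retention rules -> %d P/LP",
                n_raw, nrow(kept), nrow(prog)))

mm <- build_mutation_matrix(prog, co$clinical$patient_id)
s <- summarize_landscape(mm, prog)
d <- s$n_additional_distribution
message(sprintf(">=1 additional mutation: %.1f%%; >=2: %.1f%%",
                d$pct[d$n_additional == ">=1"], d$pct[d$n_additional == ">=2"]))
write.table(s$category_counts, "results/landscape/category_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(d, "results/landscape/n_additional.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s$isolated, "results/landscape/isolated.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(summarize_cnv(co$cnv, co$clinical$patient_id),
            "results/landscape/cnv_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# mutation presence vs clinical presentation
gene_bin <- as.data.frame(mm$presence[, colSums(mm$presence) >= 7])
clin_bin <- co$clinical[, c("prior_arterial_thrombosis",
                            "prior_venous_thrombosis", "pruritus",
                            "constitutional_symptoms")]
clin_cont <- co$clinical[, c("age_dx", "leukocytes", "platelets",
                             "neutrophil_lymphocyte_ratio", "driver_vaf")]
assoc <- pairwise_association(binary = cbind(gene_bin, clin_bin),
                              continuous = clin_cont)
write.table(assoc, "results/landscape/associations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("associations: %d pairs tested, %d at p < 0.05 (%d at q < 0.05)",
                nrow(assoc), sum(assoc$reported), sum(assoc$q_value < 0.05)))

net <- learn_network(mm, min_patients = 7, n_boot = 100, seed = 11)
message(sprintf("network: %d nodes, %d edges (BIC %.1f)",
                length(net$nodes), nrow(net$edges), net$score))
jsonlite::write_json(list(nodes = net$nodes, edges = net$edges,
                          score = net$score),
                     "results/landscape/network.json", digits = NA)

cl <- cluster_genes(mm)
clusters <- data.frame(category = names(cl$clusters),
                       cluster = unname(cl$clusters))
write.table(clusters, "results/landscape/gene_clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("gene clusters at mid-tree cut: ", max(cl$clusters))
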