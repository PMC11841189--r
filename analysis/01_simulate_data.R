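#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs with planted ground truth.
#
# Emulates the experimental design the pipeline consumes: four treatments
# (control, H2O2, LaCl3, H2O2 + LaCl3) x three biological replicates,
# negative-binomial counts with planted per-contrast effects covering every
# calcium-dependency class, a ranked/typed knowledge network with planted
# regulatory paths and a hub, and a qPCR Ct table for twelve genes.
# Everything is written as plain text under results/synthetic/.

library(caldep)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
params <- sim_params(n_genes = 2000, seed = 123)

sim <- simulate_counts(params)
write.table(data.frame(gene_id = rownames(sim$counts), sim$counts,
                       check.names = FALSE),
            file.path(out, "counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$design, file.path(out, "design.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# DE tables drawn directly from the planted effects (Wald-style noise);
# the surrogate count-based DE route is exercised separately in step 2
de <- simulate_de_tables(params)
write_de_table(de$tables$h2o2, file.path(out, "de_h2o2.tsv"))
write_de_table(de$tables$combined, file.path(out, "de_h2o2_lacl3.tsv"))
write_de_table(de$tables$lacl3, file.path(out, "de_lacl3.tsv"))

sn <- simulate_network(n_nodes = 80, n_planted = 8, decoy_density = 1.5,
                       seed = 123, n_hub_targets = 5)
write.table(sn$network$edges, file.path(out, "network.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sn$annotations, file.path(out, "annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sn$truth$targets, file.path(out, "targets.txt"))
writeLines(sn$truth$path_nodes, file.path(out, "planted_paths.txt"))

ct <- simulate_ct_table(de$truth, n_genes_qpcr = 12, ct_noise_sd = 0.15,
                        seed = 123)
write.csv(ct, file.path(out, "ct.csv"), row.names = FALSE)
write.table(attr(ct, "assayed_genes"), file.path(out, "qpcr_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes (%d planted non-null), %d network edges, %d planted paths\n",
            params$n_genes, sum(de$truth$true_class != "NULL"),
            nrow(sn$network$edges), length(sn$truth$path_nodes)))
cat("inputs written to", out, "\n")
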