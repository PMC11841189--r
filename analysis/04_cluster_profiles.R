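#!/usr/bin/env Rscript
# Step 4: response-profile clustering of the calcium-dependent genes.
#
# Clusters the (lfc_h2o2, lfc_combined) profiles of the dependent genes with
# k-means; the number of clusters comes from the gap statistic (B = 100
# uniform references, seed 123, one-standard-error rule).

library(caldep)

out <- "results/synthetic"
cl <- read.delim(file.path(out, "classes.tsv"))
cfg <- run_config()

dep <- cl[!is.na(cl$dep_class) & cl$dep_class != "INDEPENDENT", ]
X <- as.matrix(dep[, c("lfc_h2o2", "lfc_combined")])
rownames(X) <- dep$gene_id

gap <- gap_select_k(X, k_max = 8, B = cfg$gap_B, seed = cfg$seed)
write.table(data.frame(k = gap$k_values, gap = gap$gap, sk = gap$sk,
                       log_wk = gap$log_wk, elog_wk = gap$elog_wk),
            file.path(out, "gap_curve.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("gap statistic (B = %d) chose k = %d\n", gap$B, gap$chosen_k))

model <- kmeans_fit(X, gap$chosen_k, seed = cfg$seed)
assign_df <- data.frame(gene_id = names(model$assignments),
                        cluster = as.integer(model$assignments))
write.table(assign_df, file.path(out, "clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

summary_df <- summarize_clusters(model, dep[, c("lfc_h2o2", "lfc_combined")],
                                 classifications = dep)
write.table(summary_df, file.path(out, "cluster_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("per-cluster mean log2FC (H2O2 | H2O2+LaCl3) and dominant pattern:\n")
print(summary_df[, c("cluster", "n", "mean_h2o2", "mean_combined", "pattern")],
      row.names = FALSE)
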