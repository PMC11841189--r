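#!/usr/bin/env Rscript
# Step 3: calcium-dependency classification.
#
# Reads the three contrast tables, removes combined-treatment DEGs shared
# with the LaCl3-alone treatment, assigns each H2O2-responsive gene its
# dependency class, and checks the result against the planted truth.

library(caldep)

out <- "results/synthetic"
cfg <- run_config()  # FDR < 0.01, |log2FC| >= 0.5, delta log2FC >= 1

h2o2 <- read_de_table(file.path(out, "de_h2o2.tsv"), "H2O2_vs_ctrl")
comb <- read_de_table(file.path(out, "de_h2o2_lacl3.tsv"), "H2O2LaCl3_vs_ctrl")
lacl3 <- read_de_table(file.path(out, "de_lacl3.tsv"), "LaCl3_vs_ctrl")

cl <- classify_genes(h2o2, comb, lacl3, config = cfg)
write.table(cl, file.path(out, "classes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

tab <- tabulate_classes(cl)
cat("per-class counts:\n")
print(tab$per_class)
cat(sprintf("dependent total: %d of %d H2O2-DEGs (%.1f%%); %d excluded as LaCl3-shared\n",
            tab$total_dependent, tab$n_total, 100 * tab$dependent_fraction,
            tab$n_excluded))
cat(sprintf("identity check: strict (%d) + partial/antagonistic (%d) = %d\n",
            tab$strict, tab$partial_or_antagonistic, tab$total_dependent))

truth <- read.delim(file.path(out, "truth.tsv"))
expected <- expected_classification(truth$true_class)
kept <- cl[!cl$excluded_lacl3_shared, ]
m <- match(kept$gene_id, truth$gene_id)
cat(sprintf("agreement with planted classes: %.2f%%\n",
            100 * mean(kept$dep_class == expected$dep_class[m])))

summary_df <- data.frame(class = names(tab$per_class),
                         count = as.integer(tab$per_class))
write.table(summary_df, file.path(out, "class_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
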