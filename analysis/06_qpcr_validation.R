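#!/usr/bin/env Rscript
# Step 6: qPCR validation and reporter-trace summaries.
#
# Quantifies the assayed genes with the 2^-ddCt method against the two
# reference genes, regresses the qPCR log2 ratios on the RNA-seq log2 fold
# changes (concordance check), runs the standard ANOVA + Tukey comparison for
# one gene, and extracts the baseline-subtracted peak from a synthetic
# calcium reporter trace.

library(caldep)

out <- "results/synthetic"
ct <- read_ct_table(file.path(out, "ct.csv"))
genes <- read.delim(file.path(out, "qpcr_genes.tsv"))

rows <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
  g <- genes$gene_id[i]
  do.call(rbind, lapply(c(h2o2 = "h2o2", h2o2_lacl3 = "h2o2_lacl3"), function(cond) {
    dd <- delta_delta_ct(ct, g, treated = cond, control = "control")
    data.frame(gene_id = g, condition = cond, ratio = dd$ratio,
               log2_ratio = dd$log2_ratio,
               se = stats::sd(dd$per_replicate) / sqrt(length(dd$per_replicate)))
  }))
}))
write.table(rows, file.path(out, "qpcr_ratios.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# concordance with the RNA-seq fold changes, per contrast
for (cond in c("h2o2", "h2o2_lacl3")) {
  qp <- rows$log2_ratio[rows$condition == cond]
  rs <- if (cond == "h2o2") genes$lfc_h2o2 else genes$lfc_combined
  cc <- concordance(qp, rs)
  cat(sprintf("%-11s qPCR vs RNA-seq: r = %.3f, slope = %.3f, R2 = %.3f, p = %.2g\n",
              cond, cc$pearson_r, cc$slope, cc$r_squared, cc$p))
}

res <- ratio_anova(ct, genes$gene_id[1], control = "control",
                   conditions = c("h2o2", "lacl3", "h2o2_lacl3"))
cat(sprintf("\nANOVA for %s across treatments: p = %.3g\n", genes$gene_id[1],
            summary(res$anova)[[1]][["Pr(>F)"]][1]))

# synthetic cytosolic calcium trace: 90 s baseline, injection, transient
set.seed(123)
tm <- seq(0, 300, by = 1)
trace <- data.frame(
  time_s = tm,
  value = 0.1 + ifelse(tm > 90, 0.45 * exp(-(tm - 95)^2 / 200), 0) +
    rnorm(length(tm), 0, 0.005)
)
write.csv(trace, file.path(out, "trace.csv"), row.names = FALSE)
dp <- delta_peak(read_trace(file.path(out, "trace.csv")), injection_time = 90)
cat(sprintf("reporter trace delta peak (baseline-subtracted): %.3f\n", dp))
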