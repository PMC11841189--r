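# Relative qPCR quantification (2^-ddCt against dual reference genes),
# RNA-seq/qPCR concordance, and baseline-subtracted peak extraction for
# calcium reporter traces.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, the gene's Ct is normalised against the arithmetic mean of
#' the reference genes' Ct in the same sample (dCt); the treated-vs-control
#' difference of mean dCt gives ddCt and the expression ratio `2^-ddCt`.
#' Technical replicates are expected to be averaged at the Ct level before
#' this is called; biological replicates are carried through so per-replicate
#' ratios can feed SE and ANOVA summaries. The result is invariant to any
#' common additive shift of all Ct values.
#'
#' @param ct Ct table (`gene_id`, `sample_id`, `condition`, `replicate`,
#'   `ct`) with attribute `reference_genes` (two by default).
#' @param gene assayed gene id.
#' @param treated,control condition labels to compare.
#' @param reference_genes overrides the table attribute.
#' @return List: `gene`, `treated`, `control`, `ddct`, `ratio`
#'   (`2^-ddct`), `log2_ratio`, `per_replicate` (treated replicate ratios
#'   against the mean control dCt).
#' @export
#' @examples
#' truth <- simulate_de_tables(sim_params(n_genes = 50, seed = 7))$truth
#' ct <- simulate_ct_table(truth, n_genes_qpcr = 3, ct_noise_sd = 0, seed = 7)
#' gene <- attr(ct, "assayed_genes")$gene_id[1]
#' delta_delta_ct(ct, gene, treated = "h2o2", control = "control")$ratio
delta_delta_ct <- function(ct, gene, treated, control,
                           reference_genes = attr(ct, "reference_genes")) {
  .require_columns(ct, c("gene_id", "sample_id", "condition", "replicate", "ct"), "ct")
  if (is.null(reference_genes) || length(reference_genes) == 0) {
    caldep_stop("no reference genes given")
  }
  dct_for <- function(cond) {
    sub <- ct[ct$condition == cond, , drop = FALSE]
    g <- sub[sub$gene_id == gene, , drop = FALSE]
    if (nrow(g) == 0) caldep_stop("gene '%s' not measured in condition '%s'", gene, cond)
    vapply(seq_len(nrow(g)), function(i) {
      refs <- sub$ct[sub$sample_id == g$sample_id[i] &
                       sub$gene_id %in% reference_genes]
      if (length(refs) != length(reference_genes)) {
        caldep_stop("missing reference measurement(s) for gene '%s' in sample '%s'",
                    gene, g$sample_id[i])
      }
      g$ct[i] - mean(refs)
    }, numeric(1))
  }
  dct_t <- dct_for(treated)
  dct_c <- dct_for(control)
  ddct <- mean(dct_t) - mean(dct_c)
  list(gene = gene, treated = treated, control = control,
       ddct = ddct, ratio = 2^(-ddct), log2_ratio = -ddct,
       per_replicate = 2^(-(dct_t - mean(dct_c))))
}

#' RNA-seq / qPCR concordance
#'
#' Ordinary least squares of the qPCR log2 ratios on the RNA-seq log2 fold
#' changes plus the Pearson correlation.
#'
#' @param qpcr_log2_ratios numeric vector (e.g. `log2_ratio` from
#'   [delta_delta_ct()]).
#' @param rnaseq_log2fc numeric vector of matching RNA-seq log2FC values.
#' @return List: `pearson_r`, `slope`, `intercept`, `r_squared`, `p`.
#' @export
concordance <- function(qpcr_log2_ratios, rnaseq_log2fc) {
  if (length(qpcr_log2_ratios) != length(rnaseq_log2fc) ||
      length(qpcr_log2_ratios) < 3) {
    caldep_stop("need two equal-length vectors with at least 3 points")
  }
  if (stats::var(qpcr_log2_ratios) == 0 || stats::var(rnaseq_log2fc) == 0) {
    caldep_stop("zero variance; concordance undefined")
  }
  fit <- stats::lm(qpcr_log2_ratios ~ rnaseq_log2fc)
  ct <- stats::cor.test(qpcr_log2_ratios, rnaseq_log2fc, method = "pearson")
  # R^2 from residuals directly: summary.lm() warns on perfect fits, which
  # are a designed case here (noiseless validation chains)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((qpcr_log2_ratios - mean(qpcr_log2_ratios))^2)
  list(pearson_r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       p = ct$p.value)
}

#' Baseline-subtracted peak response of a reporter trace
#'
#' Subtracts the mean signal over the `baseline_window` seconds immediately
#' before the injection from the maximum signal after the injection. Only
#' the post-injection segment is searched for the peak, so a pre-injection
#' spike yields a non-positive delta rather than an error. Operates on
#' already-calibrated traces (no luminescence calibration is performed).
#'
#' @param trace `data.frame` with strictly increasing `time_s` and `value`.
#' @param injection_time time of treatment injection (seconds).
#' @param baseline_window seconds of baseline before the injection
#'   (default 10).
#' @return The peak increase (same units as `value`).
#' @export
#' @examples
#' tr <- data.frame(time_s = 0:60,
#'                  value = c(rep(2, 31), 2 + 5 * exp(-(0:29) / 8)))
#' delta_peak(tr, injection_time = 30)
delta_peak <- function(trace, injection_time, baseline_window = 10) {
  .require_columns(trace, c("time_s", "value"), "trace")
  if (any(diff(trace$time_s) <= 0)) caldep_stop("time_s must be strictly increasing")
  assert_scalar_number(baseline_window, "baseline_window")
  if (baseline_window > injection_time - min(trace$time_s)) {
    caldep_stop("baseline_window extends before the start of the trace")
  }
  base_idx <- trace$time_s >= injection_time - baseline_window &
    trace$time_s < injection_time
  post_idx <- trace$time_s > injection_time
  if (!any(base_idx)) caldep_stop("no samples in the baseline window")
  if (!any(post_idx)) caldep_stop("no samples after the injection")
  max(trace$value[post_idx]) - mean(trace$value[base_idx])
}

#' ANOVA with Tukey HSD on per-replicate expression ratios
#'
#' Convenience wrapper comparing a gene's per-replicate 2^-ddCt ratios
#' across treated conditions (standard one-way ANOVA followed by Tukey's
#' honest significant differences).
#'
#' @param ct Ct table (see [delta_delta_ct()]).
#' @param gene assayed gene id.
#' @param control control condition label.
#' @param conditions treated condition labels to compare.
#' @return List with `anova` (the [stats::aov()] fit), `tukey`
#'   ([stats::TukeyHSD()]), and `ratios` (`condition`, `replicate`,
#'   `ratio`).
#' @export
ratio_anova <- function(ct, gene, control, conditions) {
  rows <- do.call(rbind, lapply(conditions, function(cond) {
    dd <- delta_delta_ct(ct, gene, treated = cond, control = control)
    data.frame(condition = cond,
               replicate = seq_along(dd$per_replicate),
               ratio = dd$per_replicate, stringsAsFactors = FALSE)
  }))
  rows$condition <- factor(rows$condition, levels = conditions)
  fit <- stats::aov(ratio ~ condition, data = rows)
  list(anova = fit, tukey = stats::TukeyHSD(fit), ratios = rows)
}
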