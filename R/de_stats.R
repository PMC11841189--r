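#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (delegating to
#' [stats::p.adjust()] with `method = "BH"`). Output values always satisfy
#' `p <= fdr <= 1` and are monotone non-decreasing after sorting by p.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    caldep_stop("p-values must be finite numbers in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential-expression status for one or more genes
#'
#' A gene is `UP` iff `fdr < fdr_cutoff` and `log2fc >= lfc_cutoff`, `DOWN`
#' iff `fdr < fdr_cutoff` and `log2fc <= -lfc_cutoff`, and otherwise `UC`
#' (unchanged) -- including significant genes whose fold change is below the
#' magnitude gate. The FDR gate is strict (`<`), the fold-change gate
#' inclusive (`>=`). Non-finite FDR values yield `UC` with a warning.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param fdr numeric vector of adjusted p-values.
#' @param fdr_cutoff FDR threshold (default 0.01).
#' @param lfc_cutoff absolute log2FC threshold (default 0.5).
#' @return Character vector of statuses in `{"UP", "DOWN", "UC"}`.
#' @export
#' @examples
#' call_deg(c(0.7, 3.0, -0.5), c(0.005, 0.02, 0.005))
call_deg <- function(log2fc, fdr, fdr_cutoff = 0.01, lfc_cutoff = 0.5) {
  assert_scalar_number(fdr_cutoff, "fdr_cutoff")
  assert_scalar_number(lfc_cutoff, "lfc_cutoff")
  if (length(log2fc) != length(fdr)) caldep_stop("log2fc and fdr lengths differ")
  bad <- !is.finite(fdr)
  if (any(bad)) {
    caldep_warn("%d gene(s) with non-finite FDR called UC", sum(bad))
    fdr[bad] <- 1
  }
  status <- rep("UC", length(log2fc))
  sig <- fdr < fdr_cutoff & is.finite(log2fc)
  status[sig & log2fc >= lfc_cutoff] <- "UP"
  status[sig & log2fc <= -lfc_cutoff] <- "DOWN"
  status
}

#' Call DEG status for a whole DE table
#'
#' @param de a DE table (columns `gene_id`, `log2fc`, `fdr`).
#' @param config a [run_config()] supplying the thresholds.
#' @return `data.frame` with `gene_id`, `status`, `log2fc`, `fdr` and the
#'   table's `contrast_id` attribute carried over.
#' @export
call_degs <- function(de, config = run_config()) {
  .require_columns(de, c("gene_id", "log2fc", "fdr"), "de table")
  out <- data.frame(
    gene_id = de$gene_id,
    status = call_deg(de$log2fc, de$fdr,
                      fdr_cutoff = config$fdr_cutoff,
                      lfc_cutoff = config$lfc_cutoff),
    log2fc = de$log2fc,
    fdr = de$fdr,
    stringsAsFactors = FALSE
  )
  attr(out, "contrast_id") <- attr(de, "contrast_id")
  out
}

# Vectorised Welch two-sample t-test on the rows of two matrices.
.welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: both groups constant
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  p
}

#' Surrogate two-group differential-expression test
#'
#' A minimal DE test for end-to-end synthetic runs: median-of-ratios size
#' factors, `log2fc = log2((mean normalised b + 0.5) / (mean normalised a +
#' 0.5))` (the 0.5 pseudo-count avoids log of zero), a Welch t-test on
#' `log2(normalised + 1)` and BH adjustment. It is deliberately simple --
#' no dispersion shrinkage or variance-stabilising transformation -- and is
#' not a substitute analysis for real count data.
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param group_a,group_b column names or indices of the two groups
#'   (reference group first); at least two replicates each.
#' @param contrast_id contrast label attached to the result.
#' @return A DE table (`gene_id`, `log2fc`, `pvalue`, `fdr`).
#' @export
surrogate_de <- function(counts, group_a, group_b,
                         contrast_id = CONTRAST_IDS) {
  contrast_id <- match.arg(contrast_id)
  counts <- as.matrix(counts)
  a <- counts[, group_a, drop = FALSE]
  b <- counts[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) caldep_stop("need >= 2 replicates per group")
  sub <- cbind(a, b)
  # median-of-ratios size factors over genes expressed in every sample
  logs <- log(sub)
  loggeo <- rowMeans(logs)
  usable <- is.finite(loggeo)
  sf <- if (any(usable)) {
    apply(logs[usable, , drop = FALSE], 2, function(x) exp(stats::median(x - loggeo[usable])))
  } else {
    caldep_warn("no gene expressed in all samples; falling back to library-size factors")
    cs <- colSums(sub); cs / exp(mean(log(cs)))
  }
  norm <- sweep(sub, 2, sf, "/")
  ia <- seq_len(ncol(a)); ib <- ncol(a) + seq_len(ncol(b))
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  p <- .welch_rows(log2(norm[, ia, drop = FALSE] + 1),
                   log2(norm[, ib, drop = FALSE] + 1))
  allzero <- rowSums(sub) == 0
  log2fc[allzero] <- 0
  p[allzero] <- 1
  out <- data.frame(
    gene_id = rownames(counts) %||% paste0("gene", seq_len(nrow(counts))),
    log2fc = log2fc,
    pvalue = p,
    fdr = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "contrast_id") <- contrast_id
  out
}
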