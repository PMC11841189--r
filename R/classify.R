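# Calcium-dependency classification of H2O2-responsive genes.
#
# Pipeline: (1) call DEG status in the H2O2, H2O2+LaCl3 ("combined") and
# LaCl3-alone contrasts; (2) remove combined-treatment DEGs that are shared
# with the LaCl3-alone treatment (channel-blocker artifacts); (3) for every
# H2O2-DEG, compare its response with and without the calcium transient:
# a gene whose response disappears entirely (combined = UC) is strictly
# calcium-dependent; a gene responding in both contrasts is
# calcium-modulated when |delta log2FC| = |lfc_h2o2 - lfc_combined| >= 1
# (a twofold difference), split into partial/additive (same sign, weaker),
# enhanced (same sign, stronger) and antagonistic (sign flip); all other
# H2O2-DEGs are calcium-independent.

DEP_CLASSES <- c("STRICT", "PARTIAL_ADDITIVE", "ENHANCED", "ANTAGONISTIC",
                 "INDEPENDENT")

#' Remove combined-treatment DEGs shared with the LaCl3-alone treatment
#'
#' @param combined_degs `data.frame` with `gene_id`, `status` (output of
#'   [call_degs()] for the H2O2 + LaCl3 contrast).
#' @param lacl3_degs same for the LaCl3-alone contrast.
#' @param mode `"identity"` removes any combined DEG that is also a
#'   LaCl3-alone DEG regardless of direction (Venn-style exclusion, the
#'   default); `"same_direction"` removes only same-sign overlaps.
#' @return Character vector of combined-DEG gene ids retained (unique to the
#'   combined treatment).
#' @export
filter_lacl3_shared <- function(combined_degs, lacl3_degs,
                                mode = c("identity", "same_direction")) {
  mode <- match.arg(mode)
  .require_columns(combined_degs, c("gene_id", "status"), "combined_degs")
  .require_columns(lacl3_degs, c("gene_id", "status"), "lacl3_degs")
  comb <- combined_degs[combined_degs$status != "UC", c("gene_id", "status")]
  la <- lacl3_degs[lacl3_degs$status != "UC", c("gene_id", "status")]
  la_status <- la$status[match(comb$gene_id, la$gene_id)]
  shared <- if (mode == "identity") {
    !is.na(la_status)
  } else {
    !is.na(la_status) & la_status == comb$status
  }
  comb$gene_id[!shared]
}

.classify_vec <- function(status_h2o2, lfc_h2o2, status_combined, lfc_combined,
                          delta_cutoff) {
  n <- length(status_h2o2)
  delta <- lfc_h2o2 - lfc_combined
  dep <- rep("INDEPENDENT", n)
  combined_uc <- status_combined == "UC"
  dep[combined_uc] <- "STRICT"
  modulated <- !combined_uc & abs(delta) >= delta_cutoff
  same_sign <- sign(lfc_h2o2) == sign(lfc_combined)
  dep[modulated & !same_sign] <- "ANTAGONISTIC"
  dep[modulated & same_sign & abs(lfc_combined) < abs(lfc_h2o2)] <- "PARTIAL_ADDITIVE"
  dep[modulated & same_sign & abs(lfc_combined) > abs(lfc_h2o2)] <- "ENHANCED"
  # same sign, equal magnitude and |delta| >= cutoff is arithmetically
  # impossible (equal values give delta = 0); assert the branch is dead.
  stopifnot(!any(modulated & same_sign & abs(lfc_combined) == abs(lfc_h2o2)))
  list(dep_class = dep, delta = delta,
       direction = ifelse(lfc_h2o2 >= 0, "UP", "DOWN"))
}

#' Classify a single H2O2-responsive gene
#'
#' @param status_h2o2 DEG status under H2O2 alone; must not be `"UC"` (only
#'   H2O2-responsive genes are in the classification domain).
#' @param lfc_h2o2 log2 fold change under H2O2 alone.
#' @param status_combined DEG status under H2O2 + LaCl3, called with the same
#'   cutoffs.
#' @param lfc_combined log2 fold change under H2O2 + LaCl3.
#' @param delta_cutoff minimum |delta log2FC| for a both-contrast DEG to be
#'   calcium-modulated (default 1 = twofold difference).
#' @return List with `dep_class`, `direction` and `delta_log2fc`.
#' @export
#' @examples
#' classify_gene("UP", 1.2, "UC", 0.1)          # strict dependency
#' classify_gene("UP", 2.6, "UP", 1.2)          # partial/additive
#' classify_gene("UP", 0.8, "DOWN", -0.9)       # antagonistic
classify_gene <- function(status_h2o2, lfc_h2o2, status_combined, lfc_combined,
                          delta_cutoff = 1.0) {
  if (status_h2o2 == "UC") {
    caldep_stop("gene is not an H2O2 DEG (status UC); outside the classification domain")
  }
  r <- .classify_vec(status_h2o2, lfc_h2o2, status_combined, lfc_combined,
                     delta_cutoff)
  list(dep_class = r$dep_class, direction = r$direction,
       delta_log2fc = r$delta)
}

#' Classify every H2O2-responsive gene in a tissue
#'
#' Runs the full per-tissue inference: DEG calling in the three contrasts,
#' exclusion of LaCl3-shared combined DEGs, and dependency classification of
#' each H2O2-DEG. Genes excluded by the LaCl3 filter keep
#' `excluded_lacl3_shared = TRUE` and an `NA` class. Genes that are DEGs
#' under the combined treatment but unchanged under H2O2 alone are outside
#' the classification domain and are reported in the `combined_only`
#' attribute.
#'
#' @param h2o2 DE table for the H2O2 vs control contrast. When
#'   `config$h2o2_deg_source = "external"` this table is the prior study's
#'   DEG reference set and is used unchanged with the same thresholds.
#' @param combined DE table for the H2O2 + LaCl3 vs control contrast.
#' @param lacl3 optional DE table for the LaCl3-alone vs control contrast;
#'   when `NULL` no exclusion filter is applied.
#' @param config a [run_config()].
#' @return `data.frame` with one row per H2O2-DEG: `gene_id`,
#'   `status_h2o2`, `status_combined`, `status_lacl3`, `lfc_h2o2`,
#'   `lfc_combined`, `delta_log2fc`, `dep_class`, `direction`,
#'   `excluded_lacl3_shared`; attribute `combined_only` lists combined-only
#'   DEG gene ids.
#' @export
classify_genes <- function(h2o2, combined, lacl3 = NULL, config = run_config()) {
  sh <- call_degs(h2o2, config)
  sc <- call_degs(combined, config)
  common <- intersect(sh$gene_id, sc$gene_id)
  n_only <- length(unique(c(sh$gene_id, sc$gene_id))) - length(common)
  if (n_only > 0) {
    caldep_warn("%d gene(s) present in only one of the H2O2/combined tables were skipped",
                n_only)
  }
  ih <- match(common, sh$gene_id)
  ic <- match(common, sc$gene_id)

  status_lacl3 <- rep("UC", length(common))
  excluded <- rep(FALSE, length(common))
  if (!is.null(lacl3)) {
    sl <- call_degs(lacl3, config)
    status_lacl3 <- sl$status[match(common, sl$gene_id)]
    status_lacl3[is.na(status_lacl3)] <- "UC"
    retained <- filter_lacl3_shared(sc, sl, mode = config$filter_mode)
    is_comb_deg <- sc$status[ic] != "UC"
    excluded <- is_comb_deg & !(common %in% retained)
  }

  is_h2o2_deg <- sh$status[ih] != "UC"
  combined_only <- common[!is_h2o2_deg & sc$status[ic] != "UC" & !excluded]

  keep <- which(is_h2o2_deg)
  res <- data.frame(
    gene_id = common[keep],
    status_h2o2 = sh$status[ih][keep],
    status_combined = sc$status[ic][keep],
    status_lacl3 = status_lacl3[keep],
    lfc_h2o2 = sh$log2fc[ih][keep],
    lfc_combined = sc$log2fc[ic][keep],
    stringsAsFactors = FALSE
  )
  cl <- .classify_vec(res$status_h2o2, res$lfc_h2o2,
                      res$status_combined, res$lfc_combined,
                      config$delta_cutoff)
  res$delta_log2fc <- cl$delta
  res$dep_class <- cl$dep_class
  res$direction <- cl$direction
  res$excluded_lacl3_shared <- excluded[keep]
  res$dep_class[res$excluded_lacl3_shared] <- NA_character_
  res$direction[res$excluded_lacl3_shared] <- NA_character_
  attr(res, "combined_only") <- combined_only
  res
}

#' Summarise dependency classes
#'
#' Counts per class and direction plus the derived totals: the dependent
#' total is strict + partial/additive + enhanced + antagonistic, and the
#' dependent fraction divides by all H2O2-DEGs considered (classified plus
#' LaCl3-excluded).
#'
#' @param classifications output of [classify_genes()], or a character
#'   vector of dependency classes.
#' @return List with `per_class`, `per_direction`, `strict`,
#'   `partial_or_antagonistic`, `independent`, `total_dependent`,
#'   `n_classified`, `n_excluded`, `n_total`, `dependent_fraction`.
#' @export
tabulate_classes <- function(classifications) {
  if (is.character(classifications)) {
    cl <- classifications
    excl <- rep(FALSE, length(cl))
    dir <- rep(NA_character_, length(cl))
  } else {
    cl <- classifications$dep_class
    excl <- classifications$excluded_lacl3_shared %||% rep(FALSE, length(cl))
    dir <- classifications$direction
  }
  bad <- !is.na(cl) & !(cl %in% DEP_CLASSES)
  if (any(bad)) caldep_stop("unknown dependency class: %s", cl[bad][1])
  classified <- !is.na(cl) & !excl
  per_class <- vapply(DEP_CLASSES, function(k) sum(cl[classified] == k), integer(1))
  per_direction <- c(UP = sum(dir[classified] == "UP", na.rm = TRUE),
                     DOWN = sum(dir[classified] == "DOWN", na.rm = TRUE))
  dependent <- sum(per_class[c("STRICT", "PARTIAL_ADDITIVE", "ENHANCED",
                               "ANTAGONISTIC")])
  list(
    per_class = per_class,
    per_direction = per_direction,
    strict = unname(per_class["STRICT"]),
    partial_or_antagonistic = unname(dependent - per_class["STRICT"]),
    independent = unname(per_class["INDEPENDENT"]),
    total_dependent = unname(dependent),
    n_classified = sum(classified),
    n_excluded = sum(excl),
    n_total = length(cl),
    dependent_fraction = if (length(cl) > 0) dependent / length(cl) else 0
  )
}
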