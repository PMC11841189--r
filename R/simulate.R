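# Synthetic-data generators with planted ground truth. The generators
# emulate the study design downstream code expects: four conditions
# (control, H2O2, LaCl3, H2O2 + LaCl3) with three biological replicates,
# negative-binomial counts with per-contrast planted log2FC effects
# realising every dependency class, Wald-style DE tables, ranked/typed/
# mixed-direction knowledge networks with planted constrained paths, and
# qPCR Ct tables consistent with the planted fold changes. Every generator
# is deterministic given its seed and leaves the caller's RNG stream alone.

TRUE_CLASSES <- c("NULL", "INDEPENDENT", "STRICT_UP", "STRICT_DOWN",
                  "PARTIAL_UP", "PARTIAL_DOWN", "ENHANCED_DOWN",
                  "ANTAG_UP_TO_DOWN", "ANTAG_DOWN_TO_UP", "LACL3_ARTIFACT")

CONDITIONS <- c("control", "h2o2", "lacl3", "h2o2_lacl3")

.default_proportions <- c(
  "NULL" = 0.30, INDEPENDENT = 0.15, STRICT_UP = 0.10, STRICT_DOWN = 0.10,
  PARTIAL_UP = 0.08, PARTIAL_DOWN = 0.07, ENHANCED_DOWN = 0.05,
  ANTAG_UP_TO_DOWN = 0.05, ANTAG_DOWN_TO_UP = 0.05, LACL3_ARTIFACT = 0.05
)

#' Simulation parameters
#'
#' Defaults encode the emulated study conditions: 3 biological replicates,
#' a log-normal baseline around 200 counts, a shared negative-binomial
#' dispersion of 0.05 (var = mu + 0.05 mu^2), and a per-contrast log2FC
#' standard error of 0.15 -- small relative to the 0.5 DEG gate and the
#' planted between-class separations (>= 1), so classes are recoverable.
#' Planted effect magnitudes are drawn per class so that the noiseless
#' classifier reproduces the planted class exactly (e.g. a strictly
#' dependent gene has `lfc_combined = 0`; a partially dependent gene has a
#' planted delta-log2FC of at least 1.7).
#'
#' @param n_genes number of genes.
#' @param n_reps biological replicates per condition (default 3).
#' @param baseline_log_mean,baseline_log_sd natural-log mean/sd of the
#'   per-gene baseline expression.
#' @param nb_dispersion shared negative-binomial dispersion (> 0).
#' @param lfc_se standard error of observed log2FC in simulated DE tables.
#' @param class_proportions named simplex vector over the true classes.
#' @param seed integer seed.
#' @return A validated `"sim_params"` list.
#' @export
sim_params <- function(n_genes = 2000L, n_reps = 3L,
                       baseline_log_mean = log(200), baseline_log_sd = 1,
                       nb_dispersion = 0.05, lfc_se = 0.15,
                       class_proportions = .default_proportions,
                       seed = 123L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_reps <- assert_count(n_reps, "n_reps", min = 2L)
  assert_scalar_number(nb_dispersion, "nb_dispersion")
  assert_scalar_number(lfc_se, "lfc_se")
  assert_scalar_number(baseline_log_sd, "baseline_log_sd")
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% TRUE_CLASSES)) {
    caldep_stop("class_proportions must be named with known classes")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    caldep_stop("class_proportions must sum to 1")
  }
  structure(
    list(n_genes = n_genes, n_reps = n_reps,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         nb_dispersion = nb_dispersion, lfc_se = lfc_se,
         class_proportions = class_proportions, seed = seed),
    class = "sim_params"
  )
}

# Planted per-gene truth: class assignment plus per-contrast log2FC values
# consistent with the class under the classifier's definitions at zero
# noise. Runs on the ambient RNG stream (callers seed it).
.make_truth <- function(params) {
  n <- params$n_genes
  props <- params$class_proportions
  cls <- sample(names(props), n, replace = TRUE, prob = props)
  h <- numeric(n); cmb <- numeric(n); la <- numeric(n)
  U <- function(k, a, b) stats::runif(k, a, b)
  for (k in unique(cls)) {
    i <- which(cls == k)
    m <- length(i)
    if (k == "NULL") {
      # all zero
    } else if (k == "INDEPENDENT") {
      s <- sample(c(-1, 1), m, replace = TRUE)
      h[i] <- s * U(m, 1.5, 3.0)
      cmb[i] <- h[i] - s * U(m, 0, 0.3)       # |delta| stays well below 1
    } else if (k == "STRICT_UP") {
      h[i] <- U(m, 1.5, 3.0)
    } else if (k == "STRICT_DOWN") {
      h[i] <- -U(m, 1.5, 3.0)
    } else if (k == "PARTIAL_UP") {
      h[i] <- U(m, 3.0, 4.0)
      cmb[i] <- h[i] - U(m, 1.7, 2.1)         # same sign, weaker, delta >= 1.7
    } else if (k == "PARTIAL_DOWN") {
      h[i] <- -U(m, 3.0, 4.0)
      cmb[i] <- h[i] + U(m, 1.7, 2.1)
    } else if (k == "ENHANCED_DOWN") {
      h[i] <- -U(m, 1.5, 2.0)
      cmb[i] <- h[i] - U(m, 1.7, 2.1)         # same sign, stronger
    } else if (k == "ANTAG_UP_TO_DOWN") {
      h[i] <- U(m, 1.5, 2.5)
      cmb[i] <- -h[i]
    } else if (k == "ANTAG_DOWN_TO_UP") {
      h[i] <- -U(m, 1.5, 2.5)
      cmb[i] <- -h[i]
    } else if (k == "LACL3_ARTIFACT") {
      s <- sample(c(-1, 1), m, replace = TRUE)
      v <- s * U(m, 1.5, 2.5)
      h[i] <- v; cmb[i] <- v; la[i] <- v      # identical LaCl3-alone effect
    }
  }
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    true_class = cls,
    lfc_h2o2 = h, lfc_combined = cmb, lfc_lacl3 = la,
    stringsAsFactors = FALSE
  )
}

#' Simulate negative-binomial counts with planted effects
#'
#' Gene-wise baseline means are log-normal; each condition's mean is the
#' baseline scaled by `2^lfc` for that condition's planted contrast effect;
#' counts are negative-binomial with the shared dispersion
#' (`var = mu + d mu^2`).
#'
#' @param params a [sim_params()] object.
#' @return List with `counts` (genes x (4 conditions x n_reps) integer
#'   matrix), `design` (`sample`, `condition`, `replicate`), `truth`, and
#'   `baseline_mean` (the per-gene control mean, useful for moment checks).
#' @export
simulate_counts <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  local_seed(params$seed, {
    truth <- .make_truth(params)
    n <- params$n_genes
    mu0 <- exp(stats::rnorm(n, params$baseline_log_mean, params$baseline_log_sd))
    lfc_by_cond <- list(control = numeric(n), h2o2 = truth$lfc_h2o2,
                        lacl3 = truth$lfc_lacl3, h2o2_lacl3 = truth$lfc_combined)
    size <- 1 / params$nb_dispersion
    cols <- list(); nm <- character(0)
    design <- NULL
    for (cond in CONDITIONS) {
      mu <- mu0 * 2^lfc_by_cond[[cond]]
      for (r in seq_len(params$n_reps)) {
        cols[[length(cols) + 1L]] <- stats::rnbinom(n, mu = mu, size = size)
        nm <- c(nm, paste(cond, r, sep = "_"))
        design <- rbind(design, data.frame(sample = paste(cond, r, sep = "_"),
                                           condition = cond, replicate = r,
                                           stringsAsFactors = FALSE))
      }
    }
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(truth$gene_id, nm)
    list(counts = counts, design = design, truth = truth,
         baseline_mean = stats::setNames(mu0, truth$gene_id))
  })
}

#' Simulate differential-expression tables with planted classes
#'
#' For each contrast, the observed log2FC is the planted value plus
#' `Normal(0, lfc_se)` noise; the p-value is the two-sided normal tail of
#' `z = observed / lfc_se` (a Wald test with known standard error) and the
#' FDR is the BH adjustment within the contrast.
#'
#' @param params a [sim_params()] object.
#' @return List with `tables` (named list `h2o2`, `combined`, `lacl3` of DE
#'   tables) and `truth`.
#' @export
simulate_de_tables <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  local_seed(params$seed, {
    truth <- .make_truth(params)
    make_table <- function(true_lfc, contrast_id) {
      obs <- true_lfc + stats::rnorm(length(true_lfc), 0, params$lfc_se)
      p <- 2 * stats::pnorm(-abs(obs / params$lfc_se))
      out <- data.frame(gene_id = truth$gene_id, log2fc = obs, pvalue = p,
                        fdr = bh_adjust(p), stringsAsFactors = FALSE)
      attr(out, "contrast_id") <- contrast_id
      out
    }
    list(
      tables = list(
        h2o2 = make_table(truth$lfc_h2o2, "H2O2_vs_ctrl"),
        combined = make_table(truth$lfc_combined, "H2O2LaCl3_vs_ctrl"),
        lacl3 = make_table(truth$lfc_lacl3, "LaCl3_vs_ctrl")
      ),
      truth = truth
    )
  })
}

# Expected classification of a planted class once noise is zero; used by
# recovery tests and the acceptance script.
#' Map planted true classes to expected classifier output
#'
#' @param true_class character vector of planted classes.
#' @return `data.frame` with `dep_class` and `direction` (`NA` for genes the
#'   classifier never sees: nulls and LaCl3 artifacts).
#' @export
expected_classification <- function(true_class) {
  map <- list(
    INDEPENDENT = c(NA, NA),  # direction depends on the planted sign
    STRICT_UP = c("STRICT", "UP"), STRICT_DOWN = c("STRICT", "DOWN"),
    PARTIAL_UP = c("PARTIAL_ADDITIVE", "UP"),
    PARTIAL_DOWN = c("PARTIAL_ADDITIVE", "DOWN"),
    ENHANCED_DOWN = c("ENHANCED", "DOWN"),
    ANTAG_UP_TO_DOWN = c("ANTAGONISTIC", "UP"),
    ANTAG_DOWN_TO_UP = c("ANTAGONISTIC", "DOWN")
  )
  dep <- rep(NA_character_, length(true_class))
  dir <- rep(NA_character_, length(true_class))
  for (k in names(map)) {
    i <- true_class == k
    dep[i] <- map[[k]][1]
    dir[i] <- map[[k]][2]
  }
  dep[true_class == "INDEPENDENT"] <- "INDEPENDENT"
  data.frame(dep_class = dep, direction = dir, stringsAsFactors = FALSE)
}

#' Simulate a knowledge network with planted constrained paths
#'
#' Plants `n_planted` valid regulatory paths (length 1-3, exactly one
#' terminal TF edge, ranks 0-2) from annotated calcium-signalling source
#' nodes to target nodes, each non-hub target owning exactly one planted
#' path.
#' With `decoy_density > 0`, constraint-violating near-paths (two TF edges;
#' a non-terminal TF edge; a length-4 route; a rank-3 parallel route) and
#' random background edges are added. Decoys are wired through reserved
#' nodes so they can never create an additional valid source-to-target
#' path; the planted paths therefore remain the complete extraction result
#' at any decoy density (fully random graphs for oracle comparisons should
#' be generated separately).
#'
#' @param n_nodes total node budget (>= 4).
#' @param n_planted number of planted source-to-target paths.
#' @param decoy_density expected decoy edges per node (default 0).
#' @param seed integer seed.
#' @param n_hub_targets if > 0, additionally plants one hub node that is the
#'   terminal TF regulator of this many extra targets, reachable from as
#'   many dedicated sources; all source-hub-target routes are planted truth
#'   (used for hub-recovery experiments).
#' @return List with `network` (a [knowledge_network()] including
#'   annotations), `annotations`, and `truth` (planted paths as signatures,
#'   plus `sources`, `targets`, `hub`).
#' @export
simulate_network <- function(n_nodes, n_planted, decoy_density = 0,
                             seed = 1L, n_hub_targets = 0L) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 4L)
  n_planted <- assert_count(n_planted, "n_planted", min = 0L)
  n_hub_targets <- assert_count(n_hub_targets, "n_hub_targets", min = 0L)
  if (decoy_density < 0) caldep_stop("decoy_density must be >= 0")
  if (n_planted + n_hub_targets == 0) caldep_stop("nothing to plant")
  local_seed(seed, {
    lens <- if (n_planted > 0) sample(1:3, n_planted, replace = TRUE) else integer(0)
    n_sources <- max(1L, ceiling(n_planted / 2))
    need <- n_sources + sum(pmax(lens - 1L, 0L)) + n_planted +
      (if (n_hub_targets > 0) 1L + 2L * n_hub_targets else 0L)
    if (need > n_nodes) {
      caldep_stop("n_planted exceeds node capacity: need %d nodes, have %d",
                  need, n_nodes)
    }
    sources <- sprintf("SRC%02d", seq_len(n_sources))
    edges <- NULL
    add_edge <- function(src, dst, etype, rank, directed) {
      edges <<- rbind(edges, data.frame(src = src, dst = dst, etype = etype,
                                        rank = rank, directed = directed,
                                        stringsAsFactors = FALSE))
    }
    mid_counter <- 0L
    new_mid <- function() {
      mid_counter <<- mid_counter + 1L
      sprintf("INT%03d", mid_counter)
    }
    planted <- list()
    targets <- character(0)
    plant_path <- function(s, target, len) {
      nodes <- s
      for (j in seq_len(len - 1L)) {
        v <- new_mid()
        und <- stats::runif(1) < 0.5
        add_edge(nodes[length(nodes)], v, if (und) "BINDING" else "PTM",
                 sample(0:2, 1), !und)
        nodes <- c(nodes, v)
      }
      add_edge(nodes[length(nodes)], target, "TF_REGULATION", sample(0:2, 1), TRUE)
      nodes <- c(nodes, target)
      planted[[length(planted) + 1L]] <<- nodes
      targets <<- c(targets, target)
    }
    for (i in seq_len(n_planted)) {
      plant_path(sources[1L + (i - 1L) %% n_sources], sprintf("TGT%02d", i), lens[i])
    }
    hub <- NA_character_
    if (n_hub_targets > 0) {
      hub <- "HUB01"
      hub_sources <- sprintf("HSRC%02d", seq_len(n_hub_targets))
      hub_targets <- sprintf("HTGT%02d", seq_len(n_hub_targets))
      sources <- c(sources, hub_sources)
      targets <- c(targets, hub_targets)
      for (s in hub_sources) add_edge(s, hub, "BINDING", sample(0:2, 1), FALSE)
      for (tgt in hub_targets) add_edge(hub, tgt, "TF_REGULATION", sample(0:2, 1), TRUE)
      # every hub source reaches every hub target through the hub, and all
      # those length-2 routes are equally short, so all are planted truth
      for (s in hub_sources) {
        for (tgt in hub_targets) {
          planted[[length(planted) + 1L]] <- c(s, hub, tgt)
        }
      }
    }
    reserved <- character(0)  # decoy nodes that must receive no extra in-edges
    decoy_counter <- 0L
    new_decoy <- function(reserve = FALSE) {
      decoy_counter <<- decoy_counter + 1L
      nd <- sprintf("DCY%03d", decoy_counter)
      if (reserve) reserved <<- c(reserved, nd)
      nd
    }
    if (decoy_density > 0 && length(targets) > 0) {
      for (tgt in targets) {
        s <- sources[sample.int(length(sources), 1)]
        # (a) two TF edges on the route
        xa <- new_decoy(reserve = TRUE)
        add_edge(s, xa, "TF_REGULATION", sample(0:2, 1), TRUE)
        add_edge(xa, tgt, "TF_REGULATION", sample(0:2, 1), TRUE)
        # (b) TF edge not terminal
        xb <- new_decoy(reserve = TRUE)
        add_edge(s, xb, "TF_REGULATION", sample(0:2, 1), TRUE)
        add_edge(xb, tgt, "BINDING", sample(0:2, 1), FALSE)
        # (c) length-4 route of non-TF edges plus terminal TF
        a1 <- new_decoy(reserve = TRUE); a2 <- new_decoy(reserve = TRUE)
        a3 <- new_decoy(reserve = TRUE)
        add_edge(s, a1, "PTM", sample(0:2, 1), TRUE)
        add_edge(a1, a2, "PTM", sample(0:2, 1), TRUE)
        add_edge(a2, a3, "PTM", sample(0:2, 1), TRUE)
        add_edge(a3, tgt, "TF_REGULATION", sample(0:2, 1), TRUE)
        # (d) parallel route whose interior edge is rank 3 (unreliable)
        xd <- new_decoy(reserve = TRUE)
        add_edge(s, xd, "BINDING", 3L, FALSE)
        add_edge(xd, tgt, "TF_REGULATION", sample(0:2, 1), TRUE)
      }
      # background decoys among free nodes; destinations exclude targets,
      # planted intermediates and reserved decoy nodes so no new valid
      # source->target route can arise
      n_bg <- round(decoy_density * n_nodes)
      free <- setdiff(sprintf("BGD%03d", seq_len(max(4L, n_bg))), reserved)
      src_pool <- c(targets, free)
      dst_pool <- c(sources, free)
      for (i in seq_len(n_bg)) {
        u <- src_pool[sample.int(length(src_pool), 1)]
        v <- dst_pool[sample.int(length(dst_pool), 1)]
        if (u == v) next
        und <- stats::runif(1) < 0.5
        add_edge(u, v, sample(c("BINDING", "PTM", "OTHER"), 1),
                 sample(0:3, 1), !und)
      }
    }
    ca_terms <- c("30.3", "34.21", "34.22", "30.3.2", "34.21.1")
    ann <- data.frame(node_id = sources,
                      term = ca_terms[1L + (seq_along(sources) - 1L) %% length(ca_terms)],
                      stringsAsFactors = FALSE)
    net <- knowledge_network(edges, annotations = ann)
    truth_paths <- vapply(planted, function(nd) paste(nd, collapse = ">"), character(1))
    list(
      network = net, annotations = ann,
      truth = list(paths = planted, path_nodes = truth_paths,
                   sources = sources, targets = targets, hub = hub)
    )
  })
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' Generates Ct values such that the noiseless 2^-ddCt ratio of each assayed
#' gene (treated condition vs control) equals `2^(planted lfc)` for every
#' contrast, with two reference genes whose expected Ct is
#' condition-invariant. Gaussian measurement noise with standard deviation
#' `ct_noise_sd` is added to every Ct value.
#'
#' @param truth planted truth table (from [simulate_de_tables()] or
#'   [simulate_counts()]).
#' @param n_genes_qpcr number of assayed genes, sampled from the non-null
#'   planted classes.
#' @param ct_noise_sd Ct measurement noise SD (>= 0; PCR cycles).
#' @param seed integer seed.
#' @param n_reps biological replicates per condition (default 3).
#' @return A Ct `data.frame` (`gene_id`, `sample_id`, `condition`,
#'   `replicate`, `ct`) with attributes `reference_genes` and `assayed_genes`.
#' @export
simulate_ct_table <- function(truth, n_genes_qpcr = 10L, ct_noise_sd = 0,
                              seed = 1L, n_reps = 3L) {
  n_genes_qpcr <- assert_count(n_genes_qpcr, "n_genes_qpcr")
  n_reps <- assert_count(n_reps, "n_reps", min = 2L)
  if (ct_noise_sd < 0) caldep_stop("ct_noise_sd must be >= 0")
  pool <- truth[truth$true_class != "NULL", , drop = FALSE]
  if (nrow(pool) < n_genes_qpcr) caldep_stop("not enough non-null genes in truth")
  local_seed(seed, {
    genes <- pool[sample.int(nrow(pool), n_genes_qpcr), , drop = FALSE]
    refs <- data.frame(gene_id = c("HvACTIN", "HvGAPDH"),
                       base_ct = c(19, 21), stringsAsFactors = FALSE)
    base_ct <- stats::runif(n_genes_qpcr, 22, 28)
    lfc_by_cond <- function(g) c(control = 0, h2o2 = genes$lfc_h2o2[g],
                                 lacl3 = genes$lfc_lacl3[g],
                                 h2o2_lacl3 = genes$lfc_combined[g])
    rows <- list()
    for (cond in CONDITIONS) {
      for (r in seq_len(n_reps)) {
        sample_id <- paste(cond, r, sep = "_")
        for (g in seq_len(n_genes_qpcr)) {
          # higher expression = earlier amplification = lower Ct
          ct <- base_ct[g] - lfc_by_cond(g)[[cond]] +
            stats::rnorm(1, 0, ct_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = genes$gene_id[g], sample_id = sample_id,
            condition = cond, replicate = r, ct = ct,
            stringsAsFactors = FALSE)
        }
        for (j in seq_len(nrow(refs))) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = refs$gene_id[j], sample_id = sample_id,
            condition = cond, replicate = r,
            ct = refs$base_ct[j] + stats::rnorm(1, 0, ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    ct <- do.call(rbind, rows)
    attr(ct, "reference_genes") <- refs$gene_id
    attr(ct, "assayed_genes") <- genes
    ct
  })
}
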