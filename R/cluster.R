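# k-means clustering of dependency profiles with gap-statistic selection of
# the number of clusters. The feature space is the per-gene pair
# (lfc_h2o2, lfc_combined), unscaled: clusters group raw log2FC response
# patterns, matching per-cluster mean +/- SE bar summaries.

# k-means++ initial centres: first centre uniform, subsequent centres with
# probability proportional to squared distance from the nearest chosen one.
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- colSums((t(X) - centers[1, ])^2)
  for (j in 2:k) {
    pick <- if (sum(d2) <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
  }
  centers
}

#' Fit k-means with k-means++ restarts
#'
#' Runs Lloyd's algorithm (via [stats::kmeans()]) from `n_restarts`
#' k-means++ initialisations and keeps the fit with the smallest total
#' within-cluster sum of squares. Restarts that collapse a cluster are
#' repaired by reseeding the empty centre at the point farthest from its
#' assigned centroid. Deterministic given `seed`; the caller's RNG stream is
#' left untouched.
#'
#' @param X numeric matrix (rows = genes, columns = features), no missing
#'   values.
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @param n_restarts number of k-means++ restarts (default 25).
#' @return A `"cluster_model"` list: `k`, `assignments` (named integer
#'   vector), `centroids` (k x p matrix), `within_ss`.
#' @export
kmeans_fit <- function(X, k, seed = NULL, n_restarts = 25L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) caldep_stop("X must be a finite numeric matrix")
  k <- assert_count(k, "k")
  n_restarts <- assert_count(n_restarts, "n_restarts")
  if (k > nrow(X)) caldep_stop("k (%d) exceeds number of rows (%d)", k, nrow(X))
  n_distinct <- nrow(unique(X))
  if (k > n_distinct) caldep_stop("k (%d) exceeds number of distinct points (%d)", k, n_distinct)

  run_once <- function() {
    centers <- .kmeanspp_init(X, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers, iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(km)) return(NULL)
    guard <- 0L
    while (any(km$size == 0) && guard < 5L) {
      guard <- guard + 1L
      d2 <- rowSums((X - km$centers[km$cluster, , drop = FALSE])^2)
      km$centers[which(km$size == 0)[1], ] <- X[which.max(d2), ]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, km$centers, iter.max = 100L, algorithm = "Lloyd")),
        error = function(e) NULL
      )
      if (is.null(km)) return(NULL)
    }
    if (any(km$size == 0)) return(NULL)
    km
  }

  best <- local_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- run_once()
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
    best
  })
  if (is.null(best)) caldep_stop("k-means failed for all restarts")
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  structure(
    list(k = k,
         assignments = stats::setNames(best$cluster, ids),
         centroids = best$centers,
         within_ss = best$tot.withinss),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means model: k = %d, n = %d, within-SS = %.4g\n",
              x$k, length(x$assignments), x$within_ss))
  print(table(x$assignments))
  invisible(x)
}

#' Choose the number of clusters with the gap statistic
#'
#' Computes Gap(k) = E*[log W_k] - log W_k against `B` reference datasets
#' drawn uniformly over each feature's observed range (via
#' [cluster::clusGap()] with `spaceH0 = "original"`, `d.power = 2`), with
#' simulation error `s_k = sd * sqrt(1 + 1/B)`. The chosen k is the smallest
#' k with `Gap(k) >= Gap(k+1) - s_{k+1}` (the one-standard-error rule),
#' falling back to `argmax Gap` when no k qualifies.
#'
#' @param X numeric matrix of profiles.
#' @param k_max largest k to evaluate (>= 1).
#' @param B number of reference replicates (default 100).
#' @param seed integer seed (default 123).
#' @param n_restarts k-means++ restarts per fit inside the gap computation
#'   (default 5; the final model is typically refit with more restarts).
#' @return A `"gap_curve"` list: `k_values`, `gap`, `sk`, `log_wk`,
#'   `elog_wk`, `B`, `chosen_k`, `degenerate_se` (TRUE when `B = 1` left the
#'   simulation SE undefined and it was reported as 0).
#' @export
gap_select_k <- function(X, k_max, B = 100L, seed = 123L, n_restarts = 5L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) caldep_stop("X must be finite")
  k_max <- assert_count(k_max, "k_max")
  B <- assert_count(B, "B")
  rng <- apply(X, 2, range)
  if (all(rng[2, ] == rng[1, ])) caldep_stop("X is constant in every feature; gap statistic undefined")
  if (k_max > nrow(unique(X))) caldep_stop("k_max exceeds number of distinct points")

  if (k_max == 1L) {
    # single candidate: nothing to compare, k = 1 by construction
    w1 <- kmeans_fit(X, 1L, n_restarts = 1L)$within_ss
    return(structure(
      list(k_values = 1L, gap = NA_real_, sk = NA_real_,
           log_wk = log(w1), elog_wk = NA_real_, B = B,
           chosen_k = 1L, degenerate_se = TRUE),
      class = "gap_curve"
    ))
  }

  fun <- function(x, k) list(cluster = unname(kmeans_fit(x, k, n_restarts = n_restarts)$assignments))
  cg <- local_seed(seed, {
    cluster::clusGap(X, FUNcluster = fun, K.max = k_max, B = B,
                     d.power = 2, spaceH0 = "original", verbose = FALSE)
  })
  tab <- cg$Tab
  gap <- tab[, "gap"]
  sk <- tab[, "SE.sim"]
  degenerate <- any(!is.finite(sk))
  if (degenerate) {
    caldep_warn("simulation SE undefined (B = %d); reporting 0", B)
    sk[!is.finite(sk)] <- 0
  }
  qualifies <- which(gap[-k_max] >= gap[-1] - sk[-1])
  chosen_k <- if (length(qualifies) > 0) min(qualifies) else which.max(gap)
  structure(
    list(k_values = seq_len(k_max), gap = unname(gap), sk = unname(sk),
         log_wk = unname(tab[, "logW"]), elog_wk = unname(tab[, "E.logW"]),
         B = B, chosen_k = as.integer(chosen_k), degenerate_se = degenerate),
    class = "gap_curve"
  )
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(sprintf("Gap statistic curve (B = %d): chosen k = %d\n", x$B, x$chosen_k))
  print(data.frame(k = x$k_values, gap = x$gap, sk = x$sk))
  invisible(x)
}

# Pattern label for a cluster from its mean profile: mirrors the dependency
# rule applied to the centroid (combined response below lfc_cutoff in
# magnitude counts as unchanged).
.centroid_pattern <- function(mean_h2o2, mean_combined, lfc_cutoff, delta_cutoff) {
  dir <- if (mean_h2o2 >= 0) "up" else "down"
  if (abs(mean_combined) < lfc_cutoff) return(paste0("strict-", dir))
  if (abs(mean_h2o2 - mean_combined) < delta_cutoff) return(paste0("independent-", dir))
  if (sign(mean_h2o2) != sign(mean_combined)) return(paste0("antagonistic-", dir))
  if (abs(mean_combined) < abs(mean_h2o2)) return(paste0("partial-", dir))
  paste0("enhanced-", dir)
}

#' Per-cluster response summaries
#'
#' Mean and standard error of each contrast's log2FC per cluster, plus a
#' pattern label. The label comes from the dominant dependency class of the
#' members when classifications are supplied, otherwise from the centroid.
#' Singleton clusters have no defined SE; it is reported as 0 and flagged.
#'
#' @param model a [kmeans_fit()] result.
#' @param profiles matrix or data.frame with columns `lfc_h2o2` and
#'   `lfc_combined`, rows aligned with `model$assignments`.
#' @param classifications optional [classify_genes()] output (matched by
#'   `gene_id` against the assignment names) used for dominant-class labels.
#' @param lfc_cutoff,delta_cutoff thresholds used for centroid-derived
#'   labels.
#' @return `data.frame` with one row per cluster: `cluster`, `n`,
#'   `mean_h2o2`, `se_h2o2`, `mean_combined`, `se_combined`, `pattern`,
#'   `singleton`.
#' @export
summarize_clusters <- function(model, profiles, classifications = NULL,
                               lfc_cutoff = 0.5, delta_cutoff = 1.0) {
  profiles <- as.data.frame(profiles)
  .require_columns(profiles, c("lfc_h2o2", "lfc_combined"), "profiles")
  if (nrow(profiles) != length(model$assignments)) {
    caldep_stop("profiles rows (%d) do not match assignments (%d)",
                nrow(profiles), length(model$assignments))
  }
  cl <- model$assignments
  ks <- sort(unique(cl))
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  out <- do.call(rbind, lapply(ks, function(k) {
    idx <- which(cl == k)
    mh <- mean(profiles$lfc_h2o2[idx])
    mc <- mean(profiles$lfc_combined[idx])
    pattern <- if (!is.null(classifications)) {
      m <- match(names(cl)[idx], classifications$gene_id)
      lab <- paste(tolower(classifications$dep_class[m]),
                   tolower(classifications$direction[m]), sep = "-")
      names(sort(table(lab), decreasing = TRUE))[1]
    } else {
      .centroid_pattern(mh, mc, lfc_cutoff, delta_cutoff)
    }
    data.frame(cluster = k, n = length(idx),
               mean_h2o2 = mh, se_h2o2 = se(profiles$lfc_h2o2[idx]),
               mean_combined = mc, se_combined = se(profiles$lfc_combined[idx]),
               pattern = pattern, singleton = length(idx) == 1L,
               stringsAsFactors = FALSE)
  }))
  if (any(out$singleton)) {
    caldep_warn("%d singleton cluster(s); SE reported as 0", sum(out$singleton))
  }
  rownames(out) <- NULL
  out
}
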