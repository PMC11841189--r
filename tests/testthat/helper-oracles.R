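# Independent oracles and fixture builders used across the test files.
# Each oracle is deliberately written as a different algorithm from the
# implementation it checks.

# Naive Benjamini-Hochberg step-up: sort, p * m / rank, cumulative min from
# the largest rank down, undo the sort.
bh_naive <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive constrained-path enumerator: generates every node sequence of
# length <= max_len + 1 by brute expansion, then every compatible edge
# combination per sequence, and applies the path predicates (simple path,
# rank cutoff, direction respected, exactly one TF edge and it is final),
# followed by the closest-source (minimal length) reduction. Returns
# canonical signatures "n1>n2>...|ETYPE:rank,..." for set comparison.
oracle_paths <- function(net, sources, target, max_len = 3, max_rank = Inf) {
  edges <- net$edges[net$edges$rank <= max_rank, , drop = FALSE]
  nodes <- net$nodes
  sources <- intersect(unique(sources), setdiff(nodes, target))
  if (!(target %in% nodes) || length(sources) == 0 || nrow(edges) == 0) {
    return(character(0))
  }
  compatible <- function(from, to) {
    which((edges$src == from & edges$dst == to) |
            (!edges$directed & edges$src == to & edges$dst == from))
  }
  sigs <- character(0)
  lens <- integer(0)
  for (L in seq_len(max_len)) {
    mids <- if (L == 1) list(character(0)) else {
      grid <- do.call(expand.grid,
                      c(rep(list(nodes), L - 1),
                        list(stringsAsFactors = FALSE)))
      lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
    }
    for (s in sources) {
      for (mid in mids) {
        seqn <- c(s, mid, target)
        if (anyDuplicated(seqn)) next
        steps <- lapply(seq_len(L), function(j) compatible(seqn[j], seqn[j + 1]))
        if (any(vapply(steps, length, integer(1)) == 0)) next
        combos <- do.call(expand.grid, steps)
        for (r in seq_len(nrow(combos))) {
          idx <- unlist(combos[r, ], use.names = FALSE)
          et <- edges$etype[idx]
          if (sum(et == "TF_REGULATION") != 1) next
          if (et[L] != "TF_REGULATION") next
          sigs <- c(sigs, paste(paste(seqn, collapse = ">"),
                                paste(et, edges$rank[idx], sep = ":", collapse = ","),
                                sep = "|"))
          lens <- c(lens, L)
        }
      }
    }
  }
  if (length(sigs) == 0) return(character(0))
  sort(unique(sigs[lens == min(lens)]))
}

# Structural validator for an emitted path (used for property tests).
path_is_valid <- function(p, net, sources, target, max_len = 3) {
  L <- p$length
  if (L < 1 || L > max_len) return(FALSE)
  if (anyDuplicated(p$nodes)) return(FALSE)
  if (!(p$nodes[1] %in% sources) || p$nodes[length(p$nodes)] != target) return(FALSE)
  et <- p$edges$etype
  if (sum(et == "TF_REGULATION") != 1 || et[L] != "TF_REGULATION") return(FALSE)
  for (j in seq_len(L)) {
    e <- p$edges[j, ]
    fwd <- e$src == p$nodes[j] && e$dst == p$nodes[j + 1]
    bwd <- !e$directed && e$dst == p$nodes[j] && e$src == p$nodes[j + 1]
    if (!fwd && !bwd) return(FALSE)
  }
  TRUE
}

# Random mixed-direction multigraph with arbitrary types and ranks, plus a
# random source set and target (for oracle-equivalence sweeps).
random_network_case <- function(seed, n_nodes = NULL, n_edges = NULL) {
  set.seed(seed)
  n_nodes <- n_nodes %||% sample(5:12, 1)
  n_edges <- n_edges %||% sample(8:30, 1)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  etype <- sample(c("TF_REGULATION", "PTM", "BINDING", "OTHER"), n_edges,
                  replace = TRUE, prob = c(0.35, 0.25, 0.25, 0.15))
  ed <- data.frame(
    src = sample(ids, n_edges, replace = TRUE),
    dst = sample(ids, n_edges, replace = TRUE),
    etype = etype,
    rank = sample(0:3, n_edges, replace = TRUE),
    directed = ifelse(etype == "TF_REGULATION", TRUE, runif(n_edges) < 0.6),
    stringsAsFactors = FALSE
  )
  ed <- ed[ed$src != ed$dst, , drop = FALSE]
  if (nrow(ed) == 0) return(random_network_case(seed + 10000))
  net <- knowledge_network(ed, nodes = ids)
  sources <- sample(ids, min(3, n_nodes - 1))
  target <- sample(setdiff(ids, sources), 1)
  list(net = net, sources = sources, target = target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive k-means optimum: best within-SS over all assignments of n
# points to k non-empty clusters (feasible for n <= 9).
kmeans_oracle_ss <- function(X, k) {
  n <- nrow(X)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    a <- unlist(grid[i, ], use.names = FALSE)
    if (length(unique(a)) < k) next
    ss <- 0
    for (c in seq_len(k)) {
      pts <- X[a == c, , drop = FALSE]
      ctr <- colMeans(pts)
      ss <- ss + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, ss)
  }
  best
}

# Convenience: path signatures of an extraction result.
extraction_signatures <- function(paths) {
  sort(vapply(paths, path_signature, character(1)))
}
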