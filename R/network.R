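# Knowledge-network representation and constrained regulatory-path
# extraction. Paths run from calcium-signalling "source" nodes to
# H2O2-responsive "target" genes through a ranked, typed interaction graph:
# at most `max_len` edges, exactly one transcription-regulation
# (TF_REGULATION) edge which must be the final edge into the target, every
# directed edge traversed in its stated direction, undirected edges usable
# either way, simple paths only. Per target, only paths of the minimal
# realised length survive ("closest source" reduction); paths are then
# merged across targets into a single network whose nodes carry hub scores.

#' Construct a knowledge network
#'
#' @param edges `data.frame` with columns `src`, `dst`, `etype` (one of
#'   `TF_REGULATION`, `PTM`, `BINDING`, `OTHER`), `rank` (integer >= 0,
#'   0 = most reliable) and `directed` (logical). Self-loops are rejected;
#'   TF_REGULATION edges must be directed. Parallel edges of different type
#'   are distinct edges (multigraph).
#' @param annotations optional `data.frame` with columns `node_id`, `term`.
#' @param nodes optional character vector of extra (possibly isolated) nodes.
#' @return A `"knowledge_network"` list with `nodes`, `edges`,
#'   `annotations`.
#' @export
knowledge_network <- function(edges, annotations = NULL, nodes = NULL) {
  .require_columns(edges, c("src", "dst", "etype", "rank", "directed"), "edges")
  edges <- data.frame(src = as.character(edges$src),
                      dst = as.character(edges$dst),
                      etype = as.character(edges$etype),
                      rank = as.integer(edges$rank),
                      directed = as.logical(edges$directed),
                      stringsAsFactors = FALSE)
  if (any(!(edges$etype %in% EDGE_TYPES))) {
    caldep_stop("unknown etype: %s",
                edges$etype[!(edges$etype %in% EDGE_TYPES)][1])
  }
  if (any(edges$src == edges$dst)) caldep_stop("self-loops are not allowed")
  if (any(edges$rank < 0)) caldep_stop("edge rank must be >= 0")
  if (any(edges$etype == "TF_REGULATION" & !edges$directed)) {
    caldep_stop("TF_REGULATION edges must be directed")
  }
  all_nodes <- sort(unique(c(edges$src, edges$dst, nodes)))
  rownames(edges) <- NULL
  structure(list(nodes = all_nodes, edges = edges, annotations = annotations),
            class = "knowledge_network")
}

#' @export
print.knowledge_network <- function(x, ...) {
  cat(sprintf("Knowledge network: %d nodes, %d edges (%d TF_REGULATION)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$etype == "TF_REGULATION")))
  invisible(x)
}

#' Keep only reliable edges
#'
#' Retains edges with `rank <= max_rank` and drops nodes left isolated.
#'
#' @param net a [knowledge_network()].
#' @param max_rank highest reliability rank kept (default 2).
#' @return Filtered `"knowledge_network"`.
#' @export
filter_by_rank <- function(net, max_rank = 2L) {
  max_rank <- assert_count(max_rank, "max_rank", min = 0L)
  keep <- net$edges$rank <= max_rank
  edges <- net$edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    caldep_warn("no edges with rank <= %d; network is empty", max_rank)
    return(structure(list(nodes = character(0),
                          edges = edges,
                          annotations = net$annotations),
                     class = "knowledge_network"))
  }
  knowledge_network(edges, annotations = net$annotations)
}

#' Select nodes by annotation term
#'
#' Matches hierarchical annotation bins with dot-boundary prefix semantics:
#' query `"30.3"` selects nodes annotated `"30.3"` or `"30.3.1"` but not
#' `"30.31"`.
#'
#' @param net a [knowledge_network()] (used to restrict to present nodes).
#' @param annotations annotation `data.frame` (`node_id`, `term`); defaults
#'   to the network's own table.
#' @param terms character vector of query terms (non-empty).
#' @return Sorted character vector of matching node ids (possibly empty,
#'   with a warning).
#' @export
select_by_terms <- function(net, annotations = net$annotations, terms) {
  if (length(terms) == 0) caldep_stop("terms must be non-empty")
  if (is.null(annotations)) caldep_stop("no annotation table available")
  hit <- rep(FALSE, nrow(annotations))
  for (q in terms) {
    hit <- hit | annotations$term == q |
      startsWith(annotations$term, paste0(q, "."))
  }
  sel <- sort(unique(annotations$node_id[hit]))
  sel <- sel[sel %in% net$nodes]
  if (length(sel) == 0) caldep_warn("no nodes match terms: %s", paste(terms, collapse = ", "))
  sel
}

# Adjacency index for traversal: per node, the outgoing edge indices split
# into terminal candidates (TF edges) and interior candidates (non-TF).
# Undirected edges appear under both endpoints.
.adjacency <- function(edges) {
  n <- nrow(edges)
  from <- c(edges$src, edges$dst[!edges$directed])
  to <- c(edges$dst, edges$src[!edges$directed])
  idx <- c(seq_len(n), which(!edges$directed))
  is_tf <- edges$etype[idx] == "TF_REGULATION"
  # undirected TF edges cannot exist (constructor invariant), so every TF
  # entry here is a forward traversal
  list(
    interior = split(data.frame(to = to[!is_tf], idx = idx[!is_tf]), from[!is_tf]),
    tf = split(data.frame(to = to[is_tf], idx = idx[is_tf]), from[is_tf])
  )
}

.new_path <- function(nodes, edge_rows) {
  structure(list(nodes = nodes, edges = edge_rows, length = nrow(edge_rows)),
            class = "regulatory_path")
}

#' @export
print.regulatory_path <- function(x, ...) {
  cat(paste(x$nodes, collapse = " -> "), sprintf("[%d edge(s)]\n", x$length))
  invisible(x)
}

#' Canonical path signature
#'
#' A string identifying a path by its node sequence and the type and rank of
#' each traversed edge; used for deterministic ordering and set comparison.
#'
#' @param path a `"regulatory_path"`.
#' @return Character scalar.
#' @export
path_signature <- function(path) {
  paste(paste(path$nodes, collapse = ">"),
        paste(path$edges$etype, path$edges$rank, sep = ":", collapse = ","),
        sep = "|")
}

#' Extract constrained regulatory paths to one target
#'
#' Enumerates all simple paths of length `<= max_len` from any source to the
#' target such that exactly one edge is a transcription-regulation edge and
#' it is the final edge (it directly regulates the target); directed edges
#' are traversed in their stated direction and undirected edges either way.
#' The result is then reduced to the paths of the minimal realised length
#' for this target (closest-source reduction). Edge ranks are taken as
#' given: apply [filter_by_rank()] first to impose a reliability cutoff.
#'
#' @param net a [knowledge_network()].
#' @param sources character vector of source node ids.
#' @param target target node id (must be in the network).
#' @param max_len maximum path length in edges (default 3).
#' @return List of `"regulatory_path"` objects, ordered by signature; empty
#'   list when no valid path exists.
#' @export
constrained_paths <- function(net, sources, target, max_len = 3L) {
  max_len <- assert_count(max_len, "max_len")
  if (!(target %in% net$nodes)) caldep_stop("target '%s' not in network", target)
  sources <- unique(sources[sources %in% net$nodes & sources != target])
  if (length(sources) == 0) return(list())
  adj <- .adjacency(net$edges)
  found <- list()

  emit <- function(nodes, edge_idx) {
    found[[length(found) + 1L]] <<- .new_path(
      nodes, net$edges[edge_idx, , drop = FALSE]
    )
  }

  dfs <- function(node, nodes, edge_idx) {
    # terminal step: a TF edge from the current node directly into the target
    tf <- adj$tf[[node]]
    if (!is.null(tf)) {
      for (i in which(tf$to == target)) emit(c(nodes, target), c(edge_idx, tf$idx[i]))
    }
    if (length(edge_idx) >= max_len - 1L) return(invisible())
    nb <- adj$interior[[node]]
    if (is.null(nb)) return(invisible())
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      if (v == target || v %in% nodes) next
      dfs(v, c(nodes, v), c(edge_idx, nb$idx[i]))
    }
  }

  for (s in sort(sources)) dfs(s, s, integer(0))
  if (length(found) == 0) return(list())
  lens <- vapply(found, function(p) p$length, integer(1))
  found <- found[lens == min(lens)]
  # duplicate edge records (identical src/dst/type/rank) yield
  # indistinguishable paths; keep one representative per signature
  sigs <- vapply(found, path_signature, character(1))
  found <- found[!duplicated(sigs)]
  found[order(vapply(found, path_signature, character(1)))]
}

#' Extract constrained paths for many targets
#'
#' @param net a [knowledge_network()].
#' @param sources source node ids.
#' @param targets target node ids.
#' @param max_len maximum path length (default 3).
#' @return Named list (one entry per target, sorted) of path lists; targets
#'   with no valid path map to empty lists.
#' @export
extract_paths <- function(net, sources, targets, max_len = 3L) {
  targets <- sort(unique(targets))
  targets <- targets[targets %in% net$nodes]
  stats::setNames(
    lapply(targets, function(t) constrained_paths(net, sources, t, max_len)),
    targets
  )
}

#' Merge retained paths into a single network with hub scores
#'
#' Unions the nodes and edges of all retained paths, tags node roles and
#' scores every node by `n_path_occurrences` (retained paths containing it,
#' any position) and `n_distinct_targets` (targets with at least one
#' retained path containing it). `hub_ranking` sorts by
#' (`n_distinct_targets`, `n_path_occurrences`, node id), all descending.
#' Role precedence: a node that is ever a path's endpoint is a `target`;
#' otherwise a penultimate TF regulator reaching two or more distinct
#' targets is a `TF-hub`; otherwise a path's first node is a `source`; all
#' remaining nodes are `intermediate`.
#'
#' @param paths_by_target named list mapping each target id to its list of
#'   retained `"regulatory_path"` objects (see [extract_paths()]).
#' @return A `"merged_path_network"` list: `nodes` (`node_id`, `role`,
#'   `n_path_occurrences`, `n_distinct_targets`), `edges`, `hub_ranking`,
#'   `paths_by_target`.
#' @export
merge_paths <- function(paths_by_target) {
  paths_by_target <- paths_by_target[vapply(paths_by_target, length, integer(1)) > 0]
  flat <- list(); flat_target <- character(0)
  for (t in names(paths_by_target)) {
    for (p in paths_by_target[[t]]) {
      flat[[length(flat) + 1L]] <- p
      flat_target <- c(flat_target, t)
    }
  }
  if (length(flat) == 0) {
    return(structure(
      list(nodes = data.frame(node_id = character(0), role = character(0),
                              n_path_occurrences = integer(0),
                              n_distinct_targets = integer(0)),
           edges = data.frame(src = character(0), dst = character(0),
                              etype = character(0), rank = integer(0),
                              directed = logical(0)),
           hub_ranking = NULL, paths_by_target = list()),
      class = "merged_path_network"
    ))
  }
  all_nodes <- sort(unique(unlist(lapply(flat, `[[`, "nodes"))))
  occ <- stats::setNames(integer(length(all_nodes)), all_nodes)
  tgt_sets <- stats::setNames(vector("list", length(all_nodes)), all_nodes)
  first_nodes <- character(0); last_nodes <- character(0)
  penult_targets <- list()  # penultimate node -> targets it regulates
  for (i in seq_along(flat)) {
    p <- flat[[i]]
    for (nd in unique(p$nodes)) {
      occ[nd] <- occ[nd] + 1L
      tgt_sets[[nd]] <- union(tgt_sets[[nd]], flat_target[i])
    }
    first_nodes <- c(first_nodes, p$nodes[1])
    last_nodes <- c(last_nodes, p$nodes[length(p$nodes)])
    pen <- p$nodes[length(p$nodes) - 1L]
    penult_targets[[pen]] <- union(penult_targets[[pen]], flat_target[i])
  }
  n_targets <- vapply(tgt_sets, length, integer(1))
  role <- vapply(all_nodes, function(nd) {
    if (nd %in% last_nodes) return("target")
    if (!is.null(penult_targets[[nd]]) && length(penult_targets[[nd]]) >= 2) {
      return("TF-hub")
    }
    if (nd %in% first_nodes) return("source")
    "intermediate"
  }, character(1))
  edges <- unique(do.call(rbind, lapply(flat, `[[`, "edges")))
  edges <- edges[order(edges$src, edges$dst, edges$etype, edges$rank), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(node_id = all_nodes, role = unname(role),
                      n_path_occurrences = unname(occ),
                      n_distinct_targets = unname(n_targets),
                      stringsAsFactors = FALSE)
  ord <- order(nodes$n_distinct_targets, nodes$n_path_occurrences,
               nodes$node_id, decreasing = TRUE)
  structure(
    list(nodes = nodes, edges = edges, hub_ranking = nodes[ord, , drop = FALSE],
         paths_by_target = paths_by_target),
    class = "merged_path_network"
  )
}

#' @export
print.merged_path_network <- function(x, ...) {
  n_paths <- sum(vapply(x$paths_by_target, length, integer(1)))
  cat(sprintf("Merged path network: %d nodes, %d edges, %d paths to %d targets\n",
              nrow(x$nodes), nrow(x$edges), n_paths, length(x$paths_by_target)))
  invisible(x)
}

#' Extract the sub-network of paths through one hub
#'
#' @param merged a [merge_paths()] result.
#' @param hub node id present in the merged network.
#' @return A `"merged_path_network"` restricted to retained paths containing
#'   `hub`.
#' @export
extract_hub_subnetwork <- function(merged, hub) {
  if (!(hub %in% merged$nodes$node_id)) {
    caldep_stop("hub '%s' not in merged network", hub)
  }
  sub <- lapply(merged$paths_by_target, function(paths) {
    Filter(function(p) hub %in% p$nodes, paths)
  })
  merge_paths(sub)
}

#' Map genes to orthologs by best hit
#'
#' Per query gene, hits with `evalue <= evalue_cutoff` are considered and the
#' best hit is the minimal E-value, ties broken by maximal bitscore, then
#' lexicographically smallest subject. Queries with no passing hit are
#' unmapped (`NA`). The mapping may be many-to-one.
#'
#' @param genes character vector of query gene ids.
#' @param hits `data.frame` with columns `query`, `subject`, `evalue`,
#'   `bitscore` (see [read_ortholog_hits()]).
#' @param evalue_cutoff maximal E-value accepted (default 1e-30).
#' @return Named character vector over `genes`; `NA` marks unmapped queries.
#' @export
map_orthologs <- function(genes, hits, evalue_cutoff = 1e-30) {
  assert_scalar_number(evalue_cutoff, "evalue_cutoff")
  .require_columns(hits, c("query", "subject", "evalue", "bitscore"), "hits")
  out <- stats::setNames(rep(NA_character_, length(genes)), genes)
  h <- hits[hits$evalue <= evalue_cutoff & hits$query %in% genes, , drop = FALSE]
  if (nrow(h) > 0) {
    h <- h[order(h$query, h$evalue, -h$bitscore, h$subject), , drop = FALSE]
    best <- h[!duplicated(h$query), , drop = FALSE]
    out[best$query] <- best$subject
  }
  out
}

#' Flatten path lists to a table
#'
#' @param paths_by_target named list of path lists (see [extract_paths()]).
#' @return `data.frame` with `target`, `source`, `regulator` (penultimate
#'   node), `length`, `nodes` (collapsed with `>`), `signature`.
#' @export
paths_to_df <- function(paths_by_target) {
  rows <- list()
  for (t in names(paths_by_target)) {
    for (p in paths_by_target[[t]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = t, source = p$nodes[1],
        regulator = p$nodes[length(p$nodes) - 1L],
        length = p$length,
        nodes = paste(p$nodes, collapse = ">"),
        signature = path_signature(p),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target = character(0), source = character(0),
                      regulator = character(0), length = integer(0),
                      nodes = character(0), signature = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$target, out$signature), , drop = FALSE]
}
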