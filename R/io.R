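# Readers and writers for the tabular and graph formats the pipeline touches.
# Canonical table dialect is TSV; CSV is accepted for qPCR Ct tables only.
# All parse failures are dropped with a warning that carries a count --
# silent drops are forbidden.

CONTRAST_IDS <- c("H2O2_vs_ctrl", "H2O2LaCl3_vs_ctrl", "LaCl3_vs_ctrl")
EDGE_TYPES <- c("TF_REGULATION", "PTM", "BINDING", "OTHER")

.read_tsv <- function(path) {
  if (!file.exists(path)) caldep_stop("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

.require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    caldep_stop("%s: missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
}

#' Read a differential-expression table
#'
#' Parses a tab-separated table with columns `gene_id`, `log2fc`, `pvalue`
#' and `fdr` (extra columns are ignored). Rows whose numeric fields cannot be
#' parsed, whose p-value or FDR falls outside `[0, 1]`, or whose `gene_id` is
#' missing are dropped with a warning stating the count.
#'
#' @param path path to the TSV file.
#' @param contrast_id which contrast the table describes; one of
#'   `"H2O2_vs_ctrl"`, `"H2O2LaCl3_vs_ctrl"`, `"LaCl3_vs_ctrl"`.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `pvalue`, `fdr`
#'   and attribute `contrast_id`.
#' @export
read_de_table <- function(path, contrast_id = CONTRAST_IDS) {
  contrast_id <- match.arg(contrast_id)
  raw <- .read_tsv(path)
  .require_columns(raw, c("gene_id", "log2fc", "pvalue", "fdr"), path)
  df <- data.frame(
    gene_id = as.character(raw$gene_id),
    log2fc = suppressWarnings(as.numeric(raw$log2fc)),
    pvalue = suppressWarnings(as.numeric(raw$pvalue)),
    fdr = suppressWarnings(as.numeric(raw$fdr)),
    stringsAsFactors = FALSE
  )
  bad <- is.na(df$gene_id) | !is.finite(df$log2fc) |
    !is.finite(df$pvalue) | !is.finite(df$fdr) |
    df$pvalue < 0 | df$pvalue > 1 | df$fdr < 0 | df$fdr > 1
  if (any(bad)) {
    caldep_warn("%s: dropped %d row(s) with unparseable or out-of-range values",
                path, sum(bad))
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    caldep_stop("%s: duplicate gene_id (first duplicate: %s)",
                path, df$gene_id[which(dup)[1]])
  }
  rownames(df) <- NULL
  attr(df, "contrast_id") <- contrast_id
  df
}

#' Write a differential-expression table as TSV
#'
#' @param de a DE table as returned by [read_de_table()], [surrogate_de()] or
#'   [simulate_de_tables()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  .require_columns(de, c("gene_id", "log2fc", "pvalue", "fdr"), "de table")
  utils::write.table(de[, c("gene_id", "log2fc", "pvalue", "fdr")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parse_directed <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a knowledge-network edge list (plus optional node annotations)
#'
#' Edge TSV columns: `src`, `dst`, `etype`, `rank`, `directed`. Edge-type
#' tokens are matched case-insensitively against `TF_REGULATION`, `PTM`,
#' `BINDING`, `OTHER`; unknown tokens are mapped to `OTHER` with a warning.
#' Self-loop rows are rejected with a warning. Undirected edges are stored
#' once but traversable both ways; parallel edges of different type between
#' the same node pair are kept as distinct edges. Transcription-regulation
#' edges must be directed; an undirected TF row is an input error.
#'
#' @param edges_path path to the edge TSV.
#' @param annotations_path optional path to a node-annotation TSV
#'   (columns `node_id`, `term`).
#' @return A [knowledge_network()] object.
#' @export
read_network <- function(edges_path, annotations_path = NULL) {
  raw <- .read_tsv(edges_path)
  .require_columns(raw, c("src", "dst", "etype", "rank", "directed"), edges_path)
  edges <- data.frame(
    src = as.character(raw$src),
    dst = as.character(raw$dst),
    etype = toupper(trimws(as.character(raw$etype))),
    rank = suppressWarnings(as.integer(raw$rank)),
    directed = .parse_directed(raw$directed),
    stringsAsFactors = FALSE
  )
  bad <- is.na(edges$src) | is.na(edges$dst) | is.na(edges$rank) |
    edges$rank < 0 | is.na(edges$directed)
  if (any(bad)) {
    caldep_warn("%s: dropped %d unparseable edge row(s)", edges_path, sum(bad))
    edges <- edges[!bad, , drop = FALSE]
  }
  unknown <- !(edges$etype %in% EDGE_TYPES)
  if (any(unknown)) {
    caldep_warn("%s: %d edge(s) with unknown etype mapped to OTHER",
                edges_path, sum(unknown))
    edges$etype[unknown] <- "OTHER"
  }
  loops <- edges$src == edges$dst
  if (any(loops)) {
    caldep_warn("%s: rejected %d self-loop edge(s)", edges_path, sum(loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0) caldep_stop("%s: no usable edges", edges_path)
  annotations <- if (!is.null(annotations_path)) read_annotations(annotations_path)
  knowledge_network(edges, annotations = annotations)
}

#' Read a node-annotation table
#'
#' TSV with columns `node_id`, `term` (hierarchical functional-annotation
#' bins such as `"30.3"`). Duplicate (node, term) pairs are collapsed;
#' unknown terms are kept verbatim.
#'
#' @param path path to the annotation TSV.
#' @return A `data.frame` with columns `node_id`, `term`.
#' @export
read_annotations <- function(path) {
  raw <- .read_tsv(path)
  .require_columns(raw, c("node_id", "term"), path)
  ann <- data.frame(node_id = as.character(raw$node_id),
                    term = as.character(raw$term),
                    stringsAsFactors = FALSE)
  bad <- is.na(ann$node_id) | is.na(ann$term)
  if (any(bad)) {
    caldep_warn("%s: dropped %d annotation row(s) with missing fields",
                path, sum(bad))
    ann <- ann[!bad, , drop = FALSE]
  }
  ann <- unique(ann)
  rownames(ann) <- NULL
  ann
}

#' Read an ortholog best-hit table
#'
#' TSV with columns `query`, `subject`, `evalue`, `bitscore` (a BLAST-style
#' tabular summary). Rows with negative or unparseable E-values are dropped
#' with a warning.
#'
#' @param path path to the hits TSV.
#' @return A `data.frame` with columns `query`, `subject`, `evalue`,
#'   `bitscore`.
#' @export
read_ortholog_hits <- function(path) {
  raw <- .read_tsv(path)
  .require_columns(raw, c("query", "subject", "evalue", "bitscore"), path)
  hits <- data.frame(
    query = as.character(raw$query),
    subject = as.character(raw$subject),
    evalue = suppressWarnings(as.numeric(raw$evalue)),
    bitscore = suppressWarnings(as.numeric(raw$bitscore)),
    stringsAsFactors = FALSE
  )
  bad <- is.na(hits$query) | is.na(hits$subject) |
    !is.finite(hits$evalue) | hits$evalue < 0 | !is.finite(hits$bitscore)
  if (any(bad)) {
    caldep_warn("%s: dropped %d unusable hit row(s)", path, sum(bad))
    hits <- hits[!bad, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Read a qPCR Ct table (CSV)
#'
#' Columns: `gene_id`, `sample_id`, `condition`, `replicate`, `ct`.
#'
#' @param path path to the CSV file.
#' @param reference_genes character vector of reference (housekeeping) gene
#'   ids; stored as an attribute consumed by [delta_delta_ct()].
#' @return A `data.frame` with attribute `reference_genes`.
#' @export
read_ct_table <- function(path, reference_genes = c("HvACTIN", "HvGAPDH")) {
  if (!file.exists(path)) caldep_stop("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(raw, c("gene_id", "sample_id", "condition", "replicate", "ct"), path)
  ct <- data.frame(
    gene_id = as.character(raw$gene_id),
    sample_id = as.character(raw$sample_id),
    condition = as.character(raw$condition),
    replicate = as.integer(raw$replicate),
    ct = suppressWarnings(as.numeric(raw$ct)),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(ct$ct) | is.na(ct$gene_id) | is.na(ct$sample_id)
  if (any(bad)) {
    caldep_warn("%s: dropped %d Ct row(s) with missing or non-finite values",
                path, sum(bad))
    ct <- ct[!bad, , drop = FALSE]
  }
  attr(ct, "reference_genes") <- reference_genes
  ct
}

#' Read a reporter trace (CSV)
#'
#' Columns: `time_s` (strictly increasing) and `value`.
#'
#' @param path path to the CSV file.
#' @return A `data.frame` with columns `time_s`, `value`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) caldep_stop("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(raw, c("time_s", "value"), path)
  tr <- data.frame(time_s = as.numeric(raw$time_s),
                   value = as.numeric(raw$value))
  if (any(diff(tr$time_s) <= 0)) caldep_stop("%s: time_s must be strictly increasing", path)
  tr
}

#' Export a merged path network as SIF and GraphML
#'
#' Writes `<basepath>.sif` (`src<TAB>etype<TAB>dst`, one line per edge) and
#' `<basepath>.graphml` with node attributes `role` (source / intermediate /
#' target / TF-hub) and `cluster`, and edge attributes `etype` and `rank`.
#' Nodes and edges are sorted before writing so output is byte-stable for
#' identical input. Suitable for import into Cytoscape.
#'
#' @param merged a [merge_paths()] result.
#' @param basepath output path without extension.
#' @param clusters optional named vector mapping node ids to cluster labels;
#'   unnamed nodes get `"NA"`.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_network_exports <- function(merged, basepath, clusters = NULL) {
  if (!inherits(merged, "merged_path_network")) {
    caldep_stop("'merged' must be a merged_path_network (see merge_paths())")
  }
  edges <- merged$edges
  nodes <- merged$nodes
  if (is.null(edges) || nrow(edges) == 0) {
    caldep_stop("merged network is empty; nothing to export")
  }
  edges <- edges[order(edges$src, edges$dst, edges$etype, edges$rank), , drop = FALSE]
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]

  sif_path <- paste0(basepath, ".sif")
  writeLines(paste(edges$src, edges$etype, edges$dst, sep = "\t"), sif_path)

  cl <- rep("NA", nrow(nodes))
  if (!is.null(clusters)) {
    hit <- match(nodes$node_id, names(clusters))
    cl[!is.na(hit)] <- as.character(clusters[hit[!is.na(hit)]])
  }
  vdf <- data.frame(name = nodes$node_id, role = nodes$role, cluster = cl,
                    stringsAsFactors = FALSE)
  edf <- data.frame(from = edges$src, to = edges$dst, etype = edges$etype,
                    rank = edges$rank, directed = edges$directed,
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  graphml_path <- paste0(basepath, ".graphml")
  igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(c(sif = sif_path, graphml = graphml_path))
}
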