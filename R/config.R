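#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the dependency-classification and
#' path-extraction pipeline with the study defaults: differential expression
#' is called at FDR < 0.01 with |log2FC| >= 0.5; a gene's H2O2 response is
#' called calcium-modulated when its log2 fold changes under H2O2 and
#' H2O2 + LaCl3 differ by at least `delta_cutoff` (1, i.e. twofold);
#' knowledge-network paths are limited to `max_path_len` (3) edges of
#' reliability rank <= `max_rank` (2); the gap statistic uses `gap_B` (100)
#' reference replicates.
#'
#' @param fdr_cutoff FDR threshold for DEG calling (strict `<`). Default 0.01.
#' @param lfc_cutoff absolute log2 fold-change threshold for DEG calling
#'   (inclusive `>=`). Default 0.5.
#' @param delta_cutoff minimum |delta log2FC| between the H2O2 and
#'   H2O2 + LaCl3 contrasts for a both-contrast DEG to count as
#'   calcium-modulated. Default 1.
#' @param max_path_len maximum number of edges in a regulatory path. Default 3.
#' @param max_rank maximum edge reliability rank retained (0 = most reliable).
#'   Default 2.
#' @param gap_B number of uniform reference datasets for the gap statistic.
#'   Default 100.
#' @param seed integer seed used by seeded pipeline steps. Default 123.
#' @param filter_mode how LaCl3-shared DEGs are removed before
#'   classification: `"identity"` drops any combined-treatment DEG that is
#'   also a LaCl3-alone DEG; `"same_direction"` drops only same-sign
#'   overlaps. Default `"identity"`.
#' @param h2o2_deg_source whether the H2O2 DEG reference set is computed from
#'   the supplied H2O2 contrast table (`"computed"`) or supplied externally
#'   (`"external"`, e.g. from a prior study's table).
#' @return A list of validated settings with class `"run_config"`.
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$delta_cutoff
run_config <- function(fdr_cutoff = 0.01, lfc_cutoff = 0.5, delta_cutoff = 1.0,
                       max_path_len = 3L, max_rank = 2L, gap_B = 100L,
                       seed = 123L,
                       filter_mode = c("identity", "same_direction"),
                       h2o2_deg_source = c("computed", "external")) {
  assert_scalar_number(fdr_cutoff, "fdr_cutoff")
  assert_scalar_number(lfc_cutoff, "lfc_cutoff")
  assert_scalar_number(delta_cutoff, "delta_cutoff")
  max_path_len <- assert_count(max_path_len, "max_path_len")
  max_rank <- assert_count(max_rank, "max_rank", min = 0L)
  gap_B <- assert_count(gap_B, "gap_B")
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  filter_mode <- match.arg(filter_mode)
  h2o2_deg_source <- match.arg(h2o2_deg_source)
  structure(
    list(
      fdr_cutoff = fdr_cutoff, lfc_cutoff = lfc_cutoff,
      delta_cutoff = delta_cutoff, max_path_len = max_path_len,
      max_rank = max_rank, gap_B = gap_B, seed = seed,
      filter_mode = filter_mode, h2o2_deg_source = h2o2_deg_source
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Fields absent from the file keep their [run_config()] defaults; named
#' arguments passed through `...` override the file (mirroring command-line
#' flags overriding a config file).
#'
#' @param path path to a YAML file whose keys are `run_config` field names.
#' @param ... overrides applied after the file is read.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) caldep_stop("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) caldep_stop("config file does not contain a mapping: %s", path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    caldep_warn("ignoring %d unknown config field(s): %s",
                length(unknown), paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw[intersect(names(raw), known)])
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
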