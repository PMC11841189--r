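# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' state on exit. With `seed = NULL` the code runs on the ambient stream.
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop()/warning() wrappers so every message carries the package tag and
# parse-time drops are always reported with counts (silent drops forbidden).
caldep_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

caldep_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    caldep_stop("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) caldep_stop("'%s' must be > 0", name)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    caldep_stop("'%s' must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}
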