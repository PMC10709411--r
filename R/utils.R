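# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Namespaced progress/log messages; silenced via options(omixnet.verbose = FALSE).
omix_log <- function(...) {
  if (isTRUE(getOption("omixnet.verbose", TRUE))) {
    message("[omixnet] ", ...)
  }
  invisible(NULL)
}

# Pearson correlation that maps undefined (zero-variance) cases to 0.
cor0 <- function(x, y) {
  out <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs"))
  out[is.na(out)] <- 0
  out
}

# Accept either a raw gene x sample matrix or a compute_eigenloci() result.
eigenloci_values <- function(eigenloci) {
  if (is.matrix(eigenloci)) return(eigenloci)
  if (is.list(eigenloci) && is.matrix(eigenloci$values)) return(eigenloci$values)
  stop("`eigenloci` must be a matrix or the result of compute_eigenloci()")
}

assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have row and column names")
  }
  invisible(x)
}
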