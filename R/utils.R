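# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so simulation helpers can draw from a
#' fixed stream without disturbing the caller's RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Row geometric means; zero if any entry is zero (matches the reference-free
# median-of-ratios convention).
row_geomeans <- function(x) {
  apply(x, 1L, function(r) if (any(r <= 0)) 0 else exp(mean(log(r))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a count matrix container
#'
#' Light-weight container bundling an integer transcript-by-sample count
#' matrix with its sample metadata, in the style of expression-analysis list
#' objects.
#'
#' @param counts Integer matrix, transcripts in rows, samples in columns.
#' @param samples Data frame with one row per column of `counts`; must contain
#'   columns `sample`, `individual` and `compartment` (values `"cell"` or
#'   `"exosome"`).
#' @return An object of class `count_matrix` with elements `counts` and
#'   `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop_config("counts must have rownames (transcripts)")
    rownames(counts) <- character(0)
  }
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("counts must be non-negative integers")
  samples <- as.data.frame(samples)
  need <- c("sample", "individual", "compartment")
  if (!all(need %in% names(samples)))
    stop_config("sample metadata must contain: %s", paste(need, collapse = ", "))
  if (nrow(samples) != ncol(counts))
    stop_config("metadata rows (%d) != count columns (%d)", nrow(samples), ncol(counts))
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (!identical(colnames(counts), as.character(samples$sample)))
    stop_config("count column names must match samples$sample")
  if (anyDuplicated(paste(samples$individual, samples$compartment)))
    stop_config("each (individual, compartment) pair must be unique")
  if (!all(samples$compartment %in% c("cell", "exosome")))
    stop_config("compartment must be 'cell' or 'exosome'")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d transcripts x %d samples (%d cell, %d exosome)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$compartment == "cell"),
              sum(x$samples$compartment == "exosome")))
  invisible(x)
}

# Subset a count_matrix by sample index or logical vector.
subset_samples <- function(cm, idx) {
  count_matrix(cm$counts[, idx, drop = FALSE], cm$samples[idx, , drop = FALSE])
}
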