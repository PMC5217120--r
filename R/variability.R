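# Interindividual variability: Spearman correlation matrices, average-linkage
# hierarchical clustering on 1 - rho, and the cell-vs-exosome
# within-compartment variability comparison (Wilcoxon rank-sum).

#' Pairwise Spearman correlation between samples
#'
#' @param expr Matrix of (normalized) expression, transcripts x samples.
#' @param compartments Optional character vector of per-sample compartment
#'   labels, attached to the result.
#' @return Symmetric samples x samples matrix of Spearman rho (class
#'   `correlation_matrix`); pairs involving a constant sample are `NA`.
#' @export
spearman_matrix <- function(expr, compartments = NULL) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop_config("need >= 2 samples")
  if (nrow(expr) < 3L) stop_config("need >= 3 transcripts")
  suppressWarnings(rho <- stats::cor(expr, method = "spearman"))
  diag(rho) <- 1
  structure(rho, compartments = compartments,
            class = c("correlation_matrix", class(rho)))
}

#' Hierarchically cluster samples from a correlation matrix
#'
#' Agglomerative clustering on distance `1 - rho`, average linkage.
#'
#' @param correlations A `correlation_matrix`.
#' @return An `hclust` object.
#' @export
cluster_samples <- function(correlations) {
  rho <- unclass(correlations)
  if (any(is.na(rho)))
    stop_config("correlation matrix contains NA; remove constant samples first")
  stats::hclust(stats::as.dist(1 - rho), method = "average")
}

#' Write a dendrogram as Newick
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Compare within-compartment variability
#'
#' Collects all within-cell and within-exosome pairwise correlations
#' (n(n-1)/2 each) and compares them with a two-sided Wilcoxon rank-sum
#' test: exact when both groups have at most `exact_max` values and no ties,
#' normal approximation with tie/continuity correction otherwise. Note the
#' pairwise correlations share samples and are therefore dependent; the test
#' is reported as-is.
#'
#' @param correlations A `correlation_matrix` with a `compartments`
#'   attribute, or provide `compartments` explicitly.
#' @param compartments Character vector of per-sample labels ("cell" /
#'   "exosome").
#' @param exact_max Largest group size for which the exact distribution is
#'   used (default 12).
#' @return List with `mean_cell`, `mean_exosome`, `n_cell_pairs`,
#'   `n_exosome_pairs`, `p` (two-sided), `statistic`, and the raw pairwise
#'   values.
#' @export
compare_within_compartment_variability <- function(correlations,
                                                   compartments = NULL,
                                                   exact_max = 12L) {
  rho <- unclass(correlations)
  comp <- compartments %||% attr(correlations, "compartments")
  if (is.null(comp)) stop_config("compartment labels required")
  within_vals <- function(lv) {
    idx <- which(comp == lv)
    if (length(idx) < 2L)
      stop_config("compartment '%s' has < 2 samples", lv)
    sub <- rho[idx, idx, drop = FALSE]
    sub[upper.tri(sub)]
  }
  vc <- within_vals("cell")
  ve <- within_vals("exosome")
  ties <- anyDuplicated(c(vc, ve)) > 0
  use_exact <- length(vc) <= exact_max && length(ve) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(vc, ve, exact = use_exact,
                                            correct = !use_exact))
  list(mean_cell = mean(vc), mean_exosome = mean(ve),
       n_cell_pairs = length(vc), n_exosome_pairs = length(ve),
       statistic = unname(wt$statistic), p = wt$p.value,
       cell_values = vc, exosome_values = ve,
       note = "pairwise correlations share samples; p-value is descriptive")
}
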