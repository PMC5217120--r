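# k-mer QC for candidate eQTLs: spurious haplotype associations driven by
# mapping differences would leave an excess of particular k-mers in the
# unmapped reads of the low-expression haplotype group.

#' Count k-mers in a set of reads
#'
#' All overlapping windows of width `k` (a read of length L contributes
#' L - k + 1 windows).
#'
#' @param reads Character vector of sequences.
#' @param k k-mer width (default 10).
#' @return Named integer vector of k-mer counts.
#' @export
count_kmers <- function(reads, k = 10L) {
  reads <- reads[nchar(reads) >= k]
  if (!length(reads)) return(stats::setNames(integer(0), character(0)))
  kmers <- unlist(lapply(reads, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  tab <- table(kmers)
  stats::setNames(as.integer(tab), names(tab))
}

#' k-mer mapping-bias check for a candidate eQTL
#'
#' Counts k-mers per child's unmapped reads, normalizes by that child's total
#' sequenced reads, and tests each sufficiently prevalent k-mer with a
#' one-sided Wilcoxon rank-sum test between the haplotype groups, in the
#' direction opposing the eQTL effect (if the effect raises expression in the
#' code-1 group, a mapping artifact would inflate unmapped k-mers in the
#' code-0 group). The candidate passes if no k-mer reaches `alpha`.
#'
#' @param reads_per_child Named list (child id -> character vector of
#'   unmapped read sequences).
#' @param total_reads Named numeric vector of total sequenced reads per child
#'   (normalization denominators).
#' @param codes Named 0/1 haplotype codes per child.
#' @param beta Signed eQTL effect (direction only is used).
#' @param k k-mer width (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @param min_prevalence Minimum fraction of children whose reads contain a
#'   k-mer for it to be tested (default 0.5).
#' @return List with `verdict` ("pass"/"fail"), `offending` k-mers, and the
#'   per-k-mer test table.
#' @export
kmer_bias_check <- function(reads_per_child, total_reads, codes, beta,
                            k = 10L, alpha = 0.05, min_prevalence = 0.5) {
  children <- names(reads_per_child)
  if (is.null(children) || !length(children)) stop_config("empty read sets")
  if (any(lengths(reads_per_child) == 0)) stop_config("empty read sets")
  if (!all(children %in% names(codes)) || !all(children %in% names(total_reads)))
    stop_config("codes and total_reads must cover every child")
  counts <- lapply(reads_per_child, count_kmers, k = k)
  kmers <- unique(unlist(lapply(counts, names)))
  mat <- matrix(0, length(kmers), length(children),
                dimnames = list(kmers, children))
  for (ch in children) mat[names(counts[[ch]]), ch] <- counts[[ch]]
  prevalence <- rowMeans(mat > 0)
  mat <- mat[prevalence >= min_prevalence, , drop = FALSE]
  norm <- sweep(mat, 2L, total_reads[children], `/`)

  g1 <- children[codes[children] == 1]
  g0 <- children[codes[children] == 0]
  if (!length(g1) || !length(g0))
    stop_config("both haplotype groups must be non-empty")
  # opposing direction: excess k-mers in the LOW-expression group
  low <- if (beta > 0) g0 else g1
  high <- setdiff(children, low)
  res <- lapply(rownames(norm), function(km) {
    wt <- suppressWarnings(stats::wilcox.test(norm[km, low], norm[km, high],
                                              alternative = "greater"))
    data.frame(kmer = km, p = wt$p.value, stringsAsFactors = FALSE)
  })
  tab <- if (length(res)) do.call(rbind, res) else
    data.frame(kmer = character(), p = numeric())
  offending <- tab$kmer[tab$p <= alpha]
  list(verdict = if (length(offending)) "fail" else "pass",
       offending = offending, tests = tab,
       n_kmers_tested = nrow(tab))
}
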