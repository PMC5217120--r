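# RNA-biotype composition: two-step count merging, per-sample proportions
# over the six plotted classes, and the paired cell-vs-exosome comparison
# with Bonferroni correction.

BIOTYPE_CLASSES <- c("lincRNA", "miRNA", "misc", "piRNA", "rRNA", "snoRNA")

#' Merge counts from the two mapping steps
#'
#' Per transcript and sample, adds the direct-mapping counts to the
#' genome-assigned counts; transcripts present in only one input keep that
#' input's count.
#'
#' @param direct_counts,genome_assigned_counts [count_matrix()] objects over
#'   the same samples.
#' @return A [count_matrix()] over the union of transcripts.
#' @export
merge_two_step_counts <- function(direct_counts, genome_assigned_counts) {
  a <- direct_counts; b <- genome_assigned_counts
  stopifnot(inherits(a, "count_matrix"), inherits(b, "count_matrix"))
  if (!setequal(colnames(a$counts), colnames(b$counts)))
    stop_config("sample sets differ between the two inputs")
  samp <- colnames(a$counts)
  tx <- union(rownames(a$counts), rownames(b$counts))
  out <- matrix(0L, length(tx), length(samp), dimnames = list(tx, samp))
  out[rownames(a$counts), ] <- out[rownames(a$counts), ] + a$counts[, samp]
  out[rownames(b$counts), ] <- out[rownames(b$counts), ] + b$counts[, samp]
  count_matrix(out, a$samples)
}

#' Per-sample biotype proportions
#'
#' Computes, for each sample, the proportion of reads in each of the six
#' classes (lincRNA, miRNA, misc, piRNA, rRNA, snoRNA). By default the
#' composition is closed over the six classes: transcripts of other biotypes
#' are dropped before normalization.
#'
#' @param counts A [count_matrix()].
#' @param biotype Named character vector transcript -> biotype class.
#' @param classes Classes defining the composition (default the six plotted
#'   classes).
#' @return A `proportion_table`: samples x classes matrix of proportions
#'   (rows sum to 1), with the sample metadata attached as attribute
#'   `samples`.
#' @export
biotype_proportions <- function(counts, biotype,
                                classes = BIOTYPE_CLASSES) {
  stopifnot(inherits(counts, "count_matrix"))
  tx <- rownames(counts$counts)
  unknown <- tx[!tx %in% names(biotype)]
  if (length(unknown))
    stop_config("transcripts without biotype: %s",
                paste(utils::head(unknown, 5), collapse = ", "))
  cls <- biotype[tx]
  keep <- cls %in% classes
  sub <- counts$counts[keep, , drop = FALSE]
  totals <- colSums(sub)
  if (any(totals == 0))
    stop_config("sample(s) with zero mapped reads in the composition classes: %s",
                paste(colnames(sub)[totals == 0], collapse = ", "))
  by_class <- rowsum(sub, cls[keep])
  prop <- matrix(0, ncol(sub), length(classes),
                 dimnames = list(colnames(sub), classes))
  for (cl in intersect(classes, rownames(by_class)))
    prop[, cl] <- by_class[cl, ] / totals
  structure(prop, samples = counts$samples, class = c("proportion_table",
                                                      class(prop)))
}

#' Compare biotype composition between compartments
#'
#' Paired two-sided t-test per class (pairing on individual, exosome minus
#' cell), Bonferroni-corrected over the number of classes tested. Classes
#' whose paired differences have zero variance are reported with `p = NA`
#' and flagged degenerate rather than forced to a p-value.
#'
#' @param proportions A `proportion_table` from [biotype_proportions()].
#' @param metadata Optional sample metadata (defaults to the table's
#'   attribute); must pair every individual across both compartments.
#' @param bonferroni_m Number of tests to correct for (default: number of
#'   classes).
#' @return Data frame with per-class means, t statistic, df, raw and
#'   Bonferroni-adjusted p-values, and a `degenerate` flag.
#' @export
compare_compositions <- function(proportions, metadata = NULL,
                                 bonferroni_m = NULL) {
  meta <- metadata %||% attr(proportions, "samples")
  prop <- unclass(proportions)[meta$sample, , drop = FALSE]
  cell <- meta[meta$compartment == "cell", ]
  exo <- meta[meta$compartment == "exosome", ]
  if (!setequal(cell$individual, exo$individual))
    stop_config("unpaired individuals between compartments")
  ind <- sort(cell$individual)
  cmat <- prop[cell$sample[match(ind, cell$individual)], , drop = FALSE]
  emat <- prop[exo$sample[match(ind, exo$individual)], , drop = FALSE]
  classes <- colnames(prop)
  m <- bonferroni_m %||% length(classes)
  rows <- lapply(classes, function(cl) {
    d <- emat[, cl] - cmat[, cl]
    degenerate <- stats::sd(d) < .Machine$double.eps^0.5
    if (degenerate) {
      t <- if (all(abs(d) < .Machine$double.eps^0.5)) 0 else NA_real_
      p <- NA_real_
    } else {
      tt <- stats::t.test(emat[, cl], cmat[, cl], paired = TRUE)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(class = cl, mean_cell = mean(cmat[, cl]),
               mean_exosome = mean(emat[, cl]), t = t,
               df = length(d) - 1L, p = p,
               p_bonferroni = if (is.na(p)) NA_real_ else min(1, m * p),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binomially downsample a count matrix
#'
#' Each count is replaced by a Binomial(count, fraction) draw, emulating a
#' shallower sequencing run.
#'
#' @param counts A [count_matrix()].
#' @param fraction Retention fraction in (0, 1].
#' @param seed Integer seed.
#' @return A downsampled [count_matrix()].
#' @export
downsample_counts <- function(counts, fraction, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_config("fraction must be in (0, 1]")
  if (fraction == 1) return(counts)
  with_seed(seed, {
    x <- counts$counts
    y <- matrix(stats::rbinom(length(x), as.vector(x), fraction),
                nrow(x), ncol(x), dimnames = dimnames(x))
    count_matrix(y, counts$samples)
  })
}
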