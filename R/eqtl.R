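# Haplotype-based cis-eQTL mapping: log(Y+1) ~ mu + beta_p * p + beta_m * m
# over the children, where p and m are the paternal and maternal haplotype
# codes (0/1) of the block containing the transcript. The model fit R^2
# yields the p-value through the overall F-test. Natural log throughout.

#' Expression filter for eQTL testing
#'
#' Keeps transcripts whose median size-factor-normalized expression over the
#' children's samples is at least `min_median`, excluding transcripts flagged
#' as mapping to multiple loci and transcripts whose genomic interval
#' overlaps a retained variant position.
#'
#' @param norm Matrix of normalized expression (transcripts x samples).
#' @param children_samples Column names of the children's samples.
#' @param transcripts Data frame with rownames = transcript names and columns
#'   `chrom`, `start`, `end`, `multi_locus`.
#' @param variants Optional data frame of retained variants (`chrom`, `pos`).
#' @param min_median Median-expression threshold (default 10).
#' @return Character vector of transcripts passing all filters.
#' @export
eqtl_expression_filter <- function(norm, children_samples, transcripts,
                                   variants = NULL, min_median = 10) {
  tested <- rownames(norm)
  missing <- setdiff(tested, rownames(transcripts))
  if (length(missing))
    stop_config("transcripts without annotation interval: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  med <- apply(norm[, children_samples, drop = FALSE], 1L, stats::median)
  keep <- med >= min_median
  keep <- keep & !transcripts[tested, "multi_locus"]
  if (!is.null(variants) && nrow(variants)) {
    tx <- transcripts[tested, ]
    overlaps <- vapply(seq_along(tested), function(i) {
      any(variants$chrom == tx$chrom[i] &
            variants$pos >= tx$start[i] & variants$pos <= tx$end[i])
    }, logical(1))
    keep <- keep & !overlaps
  }
  tested[keep]
}

#' Fit the two-haplotype linear model for one transcript
#'
#' OLS of `log(y + 1)` (natural log) on the paternal and maternal codes.
#' A regressor constant across children is dropped (reducing k); with both
#' constant the transcript is untestable. `F = (R^2/k) / ((1-R^2)/(n-k-1))`
#' and the p-value is the upper tail of F(k, n-k-1).
#'
#' @param y Normalized expression of the children (length n).
#' @param p,m Paternal and maternal codes in \{0,1\} (length n).
#' @return One-row data frame: `n`, `k`, `mu`, `beta_p`, `beta_m`, `r2`,
#'   `fstat`, `p`, `flag` ("" / "perfect_fit" / "untestable").
#' @export
fit_haplotype_model <- function(y, p, m) {
  n <- length(y)
  if (length(p) != n || length(m) != n)
    stop_config("y, p, m must have equal length")
  if (!all(stats::na.omit(c(p, m)) %in% c(0, 1)))
    stop_config("haplotype codes must be 0/1")
  ly <- log(y + 1)
  use_p <- length(unique(p)) > 1L
  use_m <- length(unique(m)) > 1L
  k <- sum(use_p, use_m)
  if (k == 0L)
    return(data.frame(n = n, k = 0L, mu = mean(ly), beta_p = NA_real_,
                      beta_m = NA_real_, r2 = NA_real_, fstat = NA_real_,
                      p = NA_real_, flag = "untestable",
                      stringsAsFactors = FALSE))
  if (n < k + 2L) stop_config("need at least k + 2 = %d children", k + 2L)
  X <- cbind(1, if (use_p) p, if (use_m) m)
  fit <- stats::lm.fit(X, ly)
  coefs <- fit$coefficients
  mu <- coefs[1]
  beta_p <- if (use_p) coefs[2] else NA_real_
  beta_m <- if (use_m) coefs[1 + use_p + 1] else NA_real_
  tss <- sum((ly - mean(ly))^2)
  rss <- sum(fit$residuals^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  flag <- ""
  if (is.na(r2)) {
    fstat <- NA_real_; pv <- NA_real_; flag <- "untestable"
  } else if (r2 > 1 - 1e-12) {
    fstat <- Inf; pv <- .Machine$double.xmin; flag <- "perfect_fit"
    r2 <- 1
  } else {
    fstat <- (r2 / k) / ((1 - r2) / (n - k - 1L))
    pv <- stats::pf(fstat, k, n - k - 1L, lower.tail = FALSE)
    pv <- max(pv, .Machine$double.xmin)
  }
  data.frame(n = n, k = k, mu = unname(mu), beta_p = unname(beta_p),
             beta_m = unname(beta_m), r2 = r2, fstat = fstat, p = pv,
             flag = flag, stringsAsFactors = FALSE)
}

#' Map cis eQTLs in one compartment
#'
#' Normalizes the compartment's counts (size factors from all 17 samples of
#' that compartment, children subset afterwards), applies the expression and
#' exclusion filters, assigns each transcript to the haplotype block
#' containing its locus midpoint (for matures, the parent hairpin midpoint),
#' fits the two-haplotype model, and computes BH q-values within the
#' compartment.
#'
#' @param counts A [count_matrix()] (both compartments; the requested one is
#'   subset internally).
#' @param blocks A `haplotype_blocks` object.
#' @param annotation A `mirna_annotation` (with `$transcripts`).
#' @param variants Optional retained-variant data frame (`chrom`, `pos`).
#' @param compartment "cell" or "exosome".
#' @param pedigree Pedigree data frame (identifies the children).
#' @param min_median Expression filter threshold (default 10).
#' @param biotypes Optional biotype subset (e.g. "miRNA").
#' @return Data frame of fits (one row per tested transcript) with block
#'   assignment and `q` (BH); attribute `skipped` lists transcripts outside
#'   all blocks.
#' @export
map_eqtls <- function(counts, blocks, annotation, variants = NULL,
                      compartment = c("cell", "exosome"), pedigree,
                      min_median = 10, biotypes = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(counts, "count_matrix"), inherits(blocks, "haplotype_blocks"))
  comp_idx <- counts$samples$compartment == compartment
  cm <- subset_samples(counts, comp_idx)
  norm <- normalize_counts(cm)
  children <- pedigree$id[pedigree$generation == 3L]
  child_samples <- cm$samples$sample[cm$samples$individual %in% children]

  tx <- annotation$transcripts
  if (!is.null(biotypes)) {
    norm <- norm[rownames(norm) %in% tx$name[tx$biotype %in% biotypes], ,
                 drop = FALSE]
  }
  norm <- norm[rownames(norm) %in% tx$name, , drop = FALSE]
  passing <- eqtl_expression_filter(norm, child_samples, tx, variants,
                                    min_median)
  mid <- transcript_midpoints(annotation)
  b <- blocks$blocks
  child_order <- match(children, colnames(blocks$paternal))
  rows <- list(); skipped <- character(0)
  for (t in passing) {
    bi <- which(b$chrom == mid[t, "chrom"] & b$start <= mid[t, "mid"] &
                  b$end > mid[t, "mid"])
    if (length(bi) != 1L) { skipped <- c(skipped, t); next }
    p <- blocks$paternal[bi, child_order]
    m <- blocks$maternal[bi, child_order]
    if (anyNA(p) || anyNA(m)) { skipped <- c(skipped, t); next }
    y <- norm[t, cm$samples$sample[match(children, cm$samples$individual)]]
    fit <- fit_haplotype_model(unname(y), unname(p), unname(m))
    fit <- cbind(data.frame(transcript = t, compartment = compartment,
                            block = b$block[bi], stringsAsFactors = FALSE),
                 fit)
    rows[[t]] <- fit
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript = character(), compartment = character(),
               block = character(), n = integer(), k = integer(),
               mu = numeric(), beta_p = numeric(), beta_m = numeric(),
               r2 = numeric(), fstat = numeric(), p = numeric(),
               flag = character(), stringsAsFactors = FALSE)
  out$q <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Locus midpoint per transcript; matures use their parent hairpin midpoint.
transcript_midpoints <- function(annotation) {
  tx <- annotation$transcripts
  mid <- (tx$start + tx$end) / 2
  chrom <- tx$chrom
  if (!is.null(annotation$matures) && nrow(annotation$matures)) {
    mt <- annotation$matures
    hp <- annotation$hairpins
    hp_mid <- stats::setNames((hp$start + hp$end) / 2, hp$name)
    hp_chr <- stats::setNames(hp$chrom, hp$name)
    sel <- match(mt$name, tx$name)
    ok <- !is.na(sel)
    mid[sel[ok]] <- hp_mid[mt$parent[ok]]
    chrom[sel[ok]] <- hp_chr[mt$parent[ok]]
  }
  out <- data.frame(chrom = chrom, mid = mid, row.names = tx$name,
                    stringsAsFactors = FALSE)
  out
}

#' Cross-compartment correlation of eQTL effect sizes
#'
#' @param cell_fits,exosome_fits Outputs of [map_eqtls()].
#' @return Data frame with one row per coefficient (`beta_p`, `beta_m`):
#'   Pearson r, two-sided p, and the number of shared transcripts.
#' @export
effect_correlation <- function(cell_fits, exosome_fits) {
  shared <- intersect(cell_fits$transcript, exosome_fits$transcript)
  if (length(shared) < 3L) stop_config("need >= 3 transcripts tested in both compartments")
  a <- cell_fits[match(shared, cell_fits$transcript), ]
  b <- exosome_fits[match(shared, exosome_fits$transcript), ]
  one <- function(col) {
    ok <- is.finite(a[[col]]) & is.finite(b[[col]])
    if (sum(ok) < 3L) return(data.frame(coefficient = col, r = NA_real_,
                                        p = NA_real_, n = sum(ok)))
    ct <- stats::cor.test(a[[col]][ok], b[[col]][ok])
    data.frame(coefficient = col, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  }
  rbind(one("beta_p"), one("beta_m"))
}

#' Intersect significant eQTLs across compartments
#'
#' @param cell_fits,exosome_fits Outputs of [map_eqtls()] (with `q`).
#' @param fdr FDR threshold (default 0.20).
#' @return Data frame of transcripts with `q <= fdr` in both compartments,
#'   with both fits' effect sizes and q-values attached.
#' @export
shared_eqtls <- function(cell_fits, exosome_fits, fdr = 0.20) {
  sig_c <- cell_fits[!is.na(cell_fits$q) & cell_fits$q <= fdr, ]
  sig_e <- exosome_fits[!is.na(exosome_fits$q) & exosome_fits$q <= fdr, ]
  shared <- intersect(sig_c$transcript, sig_e$transcript)
  if (!length(shared))
    return(data.frame(transcript = character(), beta_p_cell = numeric(),
                      beta_p_exosome = numeric(), beta_m_cell = numeric(),
                      beta_m_exosome = numeric(), q_cell = numeric(),
                      q_exosome = numeric(), stringsAsFactors = FALSE))
  a <- sig_c[match(shared, sig_c$transcript), ]
  b <- sig_e[match(shared, sig_e$transcript), ]
  data.frame(transcript = shared,
             beta_p_cell = a$beta_p, beta_p_exosome = b$beta_p,
             beta_m_cell = a$beta_m, beta_m_exosome = b$beta_m,
             q_cell = a$q, q_exosome = b$q, stringsAsFactors = FALSE)
}

#' Rank haplotype blocks by genome-wide association counts
#'
#' Trans scan: fits the two-haplotype model of every block against every
#' transcript and counts, per block, the transcripts associated at nominal
#' `p <= alpha`. An unusually high count suggests the block's segregation
#' pattern is correlated with a technical factor.
#'
#' @param norm Normalized expression matrix restricted to the children
#'   (transcripts x children, columns in the blocks' child order).
#' @param blocks A `haplotype_blocks` object.
#' @param alpha Nominal significance level (default 0.05).
#' @return Data frame sorted by descending association count, with `rank`.
#' @export
rank_haplotypes_by_associations <- function(norm, blocks, alpha = 0.05) {
  children <- colnames(blocks$paternal)
  if (!all(children %in% colnames(norm)))
    stop_config("norm must have one column per child")
  Y <- t(log(norm[, children, drop = FALSE] + 1))  # children x transcripts
  n <- nrow(Y)
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  counts <- integer(nrow(blocks$blocks))
  for (bi in seq_len(nrow(blocks$blocks))) {
    p <- blocks$paternal[bi, ]
    m <- blocks$maternal[bi, ]
    if (anyNA(p) || anyNA(m)) { counts[bi] <- NA_integer_; next }
    keep <- c(length(unique(p)) > 1L, length(unique(m)) > 1L)
    k <- sum(keep)
    if (k == 0L) { counts[bi] <- 0L; next }
    X <- cbind(1, cbind(p, m)[, keep, drop = FALSE])
    Q <- qr.Q(qr(X))
    rss <- colSums((Y - Q %*% crossprod(Q, Y))^2)
    r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
    fstat <- (r2 / k) / ((1 - r2) / (n - k - 1L))
    pv <- stats::pf(fstat, k, n - k - 1L, lower.tail = FALSE)
    counts[bi] <- sum(!is.na(pv) & pv <= alpha)
  }
  out <- data.frame(block = blocks$blocks$block, chrom = blocks$blocks$chrom,
                    n_associated = counts, stringsAsFactors = FALSE)
  out <- out[order(-out$n_associated), ]
  out$rank <- rank(-out$n_associated, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Sex-confounding check for a candidate block
#'
#' Fisher's exact test of association between a block's paternal (or
#' maternal) codes and child sex.
#'
#' @param blocks A `haplotype_blocks` object.
#' @param block_id Block to test.
#' @param pedigree Pedigree data frame with child sex.
#' @param side "paternal" or "maternal".
#' @return List with the 2x2 table and the Fisher p-value.
#' @export
sex_confound_check <- function(blocks, block_id, pedigree,
                               side = c("paternal", "maternal")) {
  side <- match.arg(side)
  codes <- blocks[[side]][block_id, ]
  sex <- pedigree$sex[match(names(codes), pedigree$id)]
  tab <- table(code = codes, sex = sex)
  p <- if (all(dim(tab) == c(2, 2))) stats::fisher.test(tab)$p.value else NA_real_
  list(table = tab, p = p)
}
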