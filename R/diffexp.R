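# Differential expression between compartments with a simplified
# negative-binomial engine: median-of-ratios size factors, per-transcript
# method-of-moments dispersion (floored, no empirical-Bayes shrinkage, no
# independent filtering), NB log-link GLM with size-factor offsets, Wald test
# on the compartment coefficient, Benjamini-Hochberg adjustment.

#' Median-of-ratios size factors
#'
#' `s_j = median over transcripts t (with positive geometric mean) of
#' count_tj / geomean_t`.
#'
#' @param counts A [count_matrix()] or bare count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  gm <- row_geomeans(x)
  use <- gm > 0
  if (!any(use))
    stop_config(paste("no transcript has positive counts in every sample;",
                      "consider a pseudo-reference fallback"))
  ratios <- x[use, , drop = FALSE] / gm[use]
  apply(ratios, 2L, stats::median)
}

#' Normalize counts by size factors
#' @param counts A [count_matrix()] or matrix.
#' @param sf Size factors (default computed from `counts`).
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  sf <- sf %||% size_factors(x)
  sweep(x, 2L, sf, `/`)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1); input validated to lie in
#' [0, 1]. `NA` entries are preserved and excluded from the denominator.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_config("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Within-group method-of-moments dispersion on normalized counts:
# alpha = (Var - mu) / mu^2, averaged over condition groups, floored.
mom_dispersion <- function(norm, condition, floor = 1e-8) {
  alphas <- vapply(levels(condition), function(lv) {
    y <- norm[, condition == lv, drop = FALSE]
    mu <- rowMeans(y)
    v <- apply(y, 1L, stats::var)
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- 0
    a
  }, numeric(nrow(norm)))
  alphas <- matrix(alphas, nrow = nrow(norm))
  pmax(rowMeans(alphas), floor)
}

#' Negative-binomial differential expression test
#'
#' Per transcript: NB GLM of counts on the condition (log link, log size
#' factor offset, dispersion fixed at the method-of-moments estimate), Wald
#' test of the condition coefficient, BH adjustment over tested transcripts.
#' All-zero transcripts are excluded from testing and from the BH
#' denominator. Fold changes are oriented as the second condition level over
#' the first (with the default labels, exosome over cell).
#'
#' @param counts A [count_matrix()].
#' @param condition Factor of length n samples with two levels (defaults to
#'   the metadata `compartment` with levels cell, exosome).
#' @param covariates Optional data frame of categorical covariates (e.g.
#'   sequencing run); a covariate fully confounded with the condition is an
#'   error.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @return Data frame (one row per tested transcript): `baseMean`, `log2fc`,
#'   `se`, `stat`, `p`, `padj`, `direction`, `engine` (glm or moment
#'   fallback), plus an attribute `untested` naming all-zero transcripts.
#' @export
nb_differential_test <- function(counts, condition = NULL, covariates = NULL,
                                 dispersion_floor = 1e-8) {
  stopifnot(inherits(counts, "count_matrix"))
  condition <- condition %||% factor(counts$samples$compartment,
                                     levels = c("cell", "exosome"))
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2L) stop_config("condition must have two levels")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      tab <- table(covariates[[nm]], condition)
      if (all(rowSums(tab > 0) == 1L))
        stop_config("covariate '%s' is fully confounded with the condition", nm)
    }
  }
  x <- counts$counts
  untested <- rownames(x)[rowSums(x) == 0]
  x <- x[rowSums(x) > 0, , drop = FALSE]
  sf <- size_factors(counts)
  norm <- sweep(x, 2L, sf, `/`)
  alpha <- mom_dispersion(norm, condition, dispersion_floor)

  dat <- data.frame(cond = condition)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  form <- stats::as.formula(paste("y ~", paste(colnames(dat), collapse = " + ")))
  off <- log(sf)

  res <- matrix(NA_real_, nrow(x), 4,
                dimnames = list(rownames(x), c("log2fc", "se", "stat", "p")))
  engine <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    fit <- tryCatch({
      d <- cbind(y = x[i, ], dat)
      g <- suppressWarnings(stats::glm(form, data = d,
             family = MASS::negative.binomial(theta = 1 / alpha[i]),
             offset = off))
      co <- summary(g)$coefficients
      row <- grep("^cond", rownames(co))[1]
      est <- co[row, 1]; se <- co[row, 2]
      if (!is.finite(est) || !is.finite(se) || se > 10 || !g$converged)
        stop("unstable fit")
      c(est, se, "glm")
    }, error = function(e) NULL)
    if (is.null(fit)) {
      # moment fallback for degenerate fits (e.g. an all-zero group):
      # Wald on the difference of log group means with a half-count floor,
      # delta-method variance Var(log mean) ~ (1/mu + alpha) / n
      m1 <- norm[i, condition == levels(condition)[1]]
      m2 <- norm[i, condition == levels(condition)[2]]
      mu1 <- max(mean(m1), 0.5 / mean(sf))
      mu2 <- max(mean(m2), 0.5 / mean(sf))
      v1 <- (1 / mu1 + alpha[i]) / length(m1)
      v2 <- (1 / mu2 + alpha[i]) / length(m2)
      fit <- c(log(mu2 / mu1), sqrt(v1 + v2), "moment")
    }
    est <- as.numeric(fit[1]); se <- as.numeric(fit[2])
    z <- est / se
    res[i, ] <- c(est / log(2), se / log(2), z, 2 * stats::pnorm(-abs(z)))
    engine[i] <- fit[3]
  }
  out <- data.frame(
    transcript = rownames(x),
    baseMean = rowMeans(norm),
    log2fc = res[, "log2fc"],
    se = res[, "se"],
    stat = res[, "stat"],
    p = res[, "p"],
    padj = bh_adjust(res[, "p"]),
    engine = engine,
    stringsAsFactors = FALSE
  )
  out$direction <- ifelse(out$log2fc > 0, levels(condition)[2],
                          levels(condition)[1])
  rownames(out) <- NULL
  attr(out, "untested") <- untested
  attr(out, "size_factors") <- sf
  out
}

#' MA table of a differential-expression result
#'
#' @param results Data frame from [nb_differential_test()].
#' @param fdr Significance threshold on `padj` (default 0.01).
#' @return Data frame with `transcript`, `baseMean`, `log2fc`,
#'   `significant`.
#' @export
ma_table <- function(results, fdr = 0.01) {
  if (!nrow(results)) stop_config("empty results")
  data.frame(transcript = results$transcript, baseMean = results$baseMean,
             log2fc = results$log2fc,
             significant = !is.na(results$padj) & results$padj < fdr,
             stringsAsFactors = FALSE)
}
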