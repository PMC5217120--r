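# Two-haplotype linear model: filters, closed-form behavior, invariances,
# cross-compartment sharing, and the confounder QC utilities.

test_that("expression filter applies threshold, multi-locus and variant rules", {
  tx <- data.frame(chrom = "chr1", start = c(100, 300, 500, 700, 900),
                   end = c(130, 330, 530, 730, 930),
                   multi_locus = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                   row.names = paste0("t", 1:5))
  norm <- matrix(rep(c(9.9, 10, 10.1, 50, 50), 3), 5, 3,
                 dimnames = list(paste0("t", 1:5), paste0("k", 1:3)))
  # t1 fails the median threshold (9.9 < 10); t2, t3 pass at the boundary
  # (>= 10); t4 is multi-locus; t5 overlaps a variant
  keep <- eqtl_expression_filter(norm, paste0("k", 1:3), tx,
                                 variants = data.frame(chrom = "chr1", pos = 910))
  expect_equal(keep, c("t2", "t3"))
  expect_error(eqtl_expression_filter(norm[, , drop = FALSE], paste0("k", 1:3),
                                      tx[1:3, ]), "annotation interval")
})

test_that("an exact linear relationship is flagged as a perfect fit", {
  p <- c(0, 0, 1, 1); m <- c(0, 1, 0, 1)
  y <- exp(2 + 1 * p) - 1
  fit <- fit_haplotype_model(y, p, m)
  expect_equal(fit$beta_p, 1, tolerance = 1e-10)
  expect_equal(fit$beta_m, 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_equal(fit$flag, "perfect_fit")
})

test_that("the F-test matches the closed form for k = 2, n = 11", {
  # engineer R^2 = 0.5: residual variance equals explained variance
  # closed form: p = (1 + 2F/8)^(-4); R^2 = .5 -> F = 4 -> p = 1/16
  expect_equal(pf(4, 2, 8, lower.tail = FALSE), 1 / 16)
  set.seed(55)
  # verify the fit's (R^2 -> F -> p) mapping on arbitrary data
  for (i in 1:20) {
    p <- rbinom(11, 1, 0.5); m <- rbinom(11, 1, 0.5)
    if (length(unique(p)) < 2 || length(unique(m)) < 2) next
    y <- rlnorm(11, 3, 1)
    fit <- fit_haplotype_model(y, p, m)
    expect_equal(fit$k, 2)
    want_f <- (fit$r2 / 2) / ((1 - fit$r2) / 8)
    expect_equal(fit$fstat, want_f, tolerance = 1e-12)
    expect_equal(fit$p, (1 + 2 * want_f / 8)^(-4), tolerance = 1e-10)
  }
})

test_that("constant regressors are dropped or flagged untestable", {
  y <- rlnorm(11, 3, 1)
  p <- rbinom(11, 1, 0.5); p[1] <- 1 - p[1]  # guarantee both levels? ensure below
  p <- c(0, 1, rep(0:1, length.out = 9))
  fit <- fit_haplotype_model(y, p, rep(0, 11))
  expect_equal(fit$k, 1)
  expect_true(is.na(fit$beta_m))
  fit0 <- fit_haplotype_model(y, rep(1, 11), rep(0, 11))
  expect_equal(fit0$flag, "untestable")
  expect_error(fit_haplotype_model(y[1:2], c(0, 1), c(0, 1)), "children")
  expect_error(fit_haplotype_model(y, rep(2, 11), rep(0, 11)), "0/1")
})

test_that("flipping a block's encoding flips betas but not fit quality", {
  set.seed(77)
  for (i in 1:10) {
    p <- rbinom(11, 1, 0.5); m <- rbinom(11, 1, 0.5)
    if (length(unique(p)) < 2 || length(unique(m)) < 2) next
    y <- rlnorm(11, 4, 0.8)
    a <- fit_haplotype_model(y, p, m)
    b <- fit_haplotype_model(y, 1 - p, m)
    expect_equal(b$beta_p, -a$beta_p, tolerance = 1e-10)
    expect_equal(b$r2, a$r2, tolerance = 1e-12)
    expect_equal(b$p, a$p, tolerance = 1e-12)
    expect_equal(b$fstat, a$fstat, tolerance = 1e-10)
  }
})

test_that("switching log base rescales betas and preserves p-values", {
  set.seed(78)
  p <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  m <- c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1)
  y <- rlnorm(11, 4, 0.8)
  nat <- fit_haplotype_model(y, p, m)
  # log2 model fitted directly
  X <- cbind(1, p, m)
  fit2 <- lm.fit(X, log2(y + 1))
  expect_equal(unname(fit2$coefficients[2]), nat$beta_p / log(2),
               tolerance = 1e-10)
  r2_2 <- 1 - sum(fit2$residuals^2) /
    sum((log2(y + 1) - mean(log2(y + 1)))^2)
  expect_equal(r2_2, nat$r2, tolerance = 1e-9)
})

test_that("null fits are calibrated: type-I error and p-value uniformity", {
  set.seed(91)
  n_fit <- 2000
  pvals <- vapply(seq_len(n_fit), function(i) {
    p <- rbinom(11, 1, 0.5); m <- rbinom(11, 1, 0.5)
    y <- rlnorm(11, 3, 0.6)
    fit_haplotype_model(y, p, m)$p
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("planted effects are recovered without bias", {
  set.seed(93)
  beta <- 1.0
  est <- vapply(1:200, function(i) {
    p <- rbinom(11, 1, 0.5); m <- rbinom(11, 1, 0.5)
    while (length(unique(p)) < 2) p <- rbinom(11, 1, 0.5)
    y <- exp(3 + beta * p + rnorm(11, 0, 0.3)) - 1
    fit_haplotype_model(y, p, m)$beta_p
  }, numeric(1))
  expect_lt(abs(mean(est) - beta), 0.15)
})

test_that("map_eqtls ties fits to blocks and detects planted cis effects", {
  res <- run_pipeline(sim_config(seed = 31), stages = c("haplotypes", "eqtl"))
  planted <- res$sim$truth$eqtl$transcript
  cf <- res$eqtl$fits$cell
  expect_true(all(planted %in% cf$transcript))
  hits <- cf[cf$transcript %in% planted, ]
  # most planted effects detected at 20% FDR in cells (the low-noise side)
  expect_gte(sum(hits$q <= 0.2), 3)
  expect_equal(sign(hits$beta_p[hits$q <= 0.2]),
               rep(1, sum(hits$q <= 0.2)))
  # identical counts in both compartments give identical fit tables
  blocks <- res$haplotypes$blocks
  variants <- res$sim$genotypes$markers[, c("chrom", "pos")]
  cm <- res$sim$counts
  cell_idx <- cm$samples$compartment == "cell"
  mir_counts <- cbind(cm$counts[, cell_idx], cm$counts[, cell_idx])
  colnames(mir_counts) <- c(colnames(cm$counts)[cell_idx],
                            sub("_cell", "_exosome",
                                colnames(cm$counts)[cell_idx]))
  mirrored <- count_matrix(
    mir_counts,
    data.frame(sample = colnames(mir_counts),
               individual = rep(cm$samples$individual[cell_idx], 2),
               compartment = rep(c("cell", "exosome"),
                                 each = sum(cell_idx))))
  f1 <- map_eqtls(mirrored, blocks, res$sim$annotation, variants, "cell",
                  res$sim$pedigree)
  f2 <- map_eqtls(mirrored, blocks, res$sim$annotation, variants, "exosome",
                  res$sim$pedigree)
  expect_equal(f1[, setdiff(names(f1), "compartment")],
               f2[, setdiff(names(f2), "compartment")])
})

test_that("effect correlation and the shared-eQTL intersection behave", {
  fits <- data.frame(transcript = paste0("t", 1:6),
                     beta_p = c(1, -2, 0.5, 3, -1, 2),
                     beta_m = c(0.2, 0.1, -0.3, 0, 0.4, -0.2),
                     q = c(0.01, 0.5, 0.1, 0.01, 0.9, 0.15))
  # identical effects -> r = 1 for both coefficients
  cc <- effect_correlation(fits, fits)
  expect_equal(cc$r, c(1, 1), tolerance = 1e-12)
  expect_error(effect_correlation(fits[1:2, ], fits[1:2, ]), ">= 3")
  sh <- shared_eqtls(fits, fits, fdr = 0.10)
  expect_setequal(sh$transcript, c("t1", "t3", "t4"))
  other <- fits; other$q <- 1
  expect_equal(nrow(shared_eqtls(fits, other, fdr = 0.10)), 0)
  expect_equal(nrow(shared_eqtls(fits, fits, fdr = 0)), 0)
})

test_that("shared effects correlate across compartments over seeds", {
  set.seed(101)
  shared_r <- replicate(20, {
    beta <- rnorm(30, 0, 1)
    a <- data.frame(transcript = paste0("t", 1:30),
                    beta_p = beta + rnorm(30, 0, 0.4),
                    beta_m = rnorm(30, 0, 0.4))
    b <- data.frame(transcript = paste0("t", 1:30),
                    beta_p = beta + rnorm(30, 0, 0.4),
                    beta_m = rnorm(30, 0, 0.4))
    effect_correlation(a, b)$r
  })
  expect_gt(mean(shared_r[1, ] > 0), 0.95)       # shared beta_p
  expect_lt(abs(mean(shared_r[2, ])), 0.25)      # independent beta_m
})

test_that("haplotype ranking counts associations and flags planted confounders", {
  set.seed(107)
  children <- sprintf("c%02d", 1:11)
  nb <- 30
  pat <- matrix(rbinom(nb * 11, 1, 0.5), nb, 11,
                dimnames = list(sprintf("block_%04d", 1:nb), children))
  mat <- matrix(rbinom(nb * 11, 1, 0.5), nb, 11,
                dimnames = list(sprintf("block_%04d", 1:nb), children))
  pat[2, ] <- pat[1, ]; mat[2, ] <- mat[1, ]  # duplicated block
  blocks <- structure(list(
    blocks = data.frame(block = rownames(pat), chrom = "chr1",
                        start = seq(0, by = 10, length.out = nb),
                        end = seq(10, by = 10, length.out = nb)),
    paternal = pat, maternal = mat), class = "haplotype_blocks")
  # expression: 100 null transcripts + 40 driven by block 5's paternal codes
  # (a technical factor shared across many transcripts)
  norm <- rbind(
    matrix(rlnorm(100 * 11, 3, 0.5), 100, 11),
    t(sapply(1:40, function(i) exp(3 + 2 * pat[5, ] + rnorm(11, 0, 0.3)))))
  dimnames(norm) <- list(sprintf("t%03d", 1:140), children)
  rk <- rank_haplotypes_by_associations(norm, blocks)
  expect_equal(rk$block[1], "block_0005")
  # identical blocks get identical counts
  expect_equal(rk$n_associated[rk$block == "block_0001"],
               rk$n_associated[rk$block == "block_0002"])
})

test_that("k-mer counting enumerates sliding windows", {
  got <- count_kmers("ACGTACGTACG", k = 10)
  expect_equal(sort(names(got)), c("ACGTACGTAC", "CGTACGTACG"))
  expect_equal(unname(got[c("ACGTACGTAC", "CGTACGTACG")]), c(1L, 1L))
  expect_equal(length(count_kmers(character(0))), 0)
  expect_equal(length(count_kmers("ACGT", k = 10)), 0)  # too short
})

test_that("k-mer bias check passes identical groups and catches planted bias", {
  set.seed(113)
  children <- sprintf("c%02d", 1:10)
  codes <- setNames(rep(c(0, 1), each = 5), children)
  total <- setNames(rep(1e5, 10), children)
  base_reads <- replicate(40, paste(sample(c("A", "C", "G", "T"), 30,
                                           replace = TRUE), collapse = ""))
  same <- setNames(rep(list(base_reads), 10), children)
  res <- kmer_bias_check(same, total, codes, beta = 1.2)
  expect_equal(res$verdict, "pass")
  # plant a 10-mer enriched in the low group (codes 0) opposing beta > 0
  planted <- "AAAAACCCCC"
  biased <- same
  for (ch in children[codes == 0])
    biased[[ch]] <- c(biased[[ch]], rep(paste0(planted, "GGGGGTTTTT"), 25))
  res2 <- kmer_bias_check(biased, total, codes, beta = 1.2)
  expect_equal(res2$verdict, "fail")
  expect_true(planted %in% res2$offending)
  expect_error(kmer_bias_check(list(), total, codes, 1), "empty")
})

test_that("sex confounding check reports a Fisher table", {
  res <- run_pipeline(sim_config(seed = 37), stages = "haplotypes")
  bl <- res$haplotypes$blocks
  chk <- sex_confound_check(bl, bl$blocks$block[1], res$sim$pedigree)
  expect_true(is.na(chk$p) || (chk$p > 0 && chk$p <= 1))
})
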