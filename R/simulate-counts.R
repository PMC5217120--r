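# Synthetic count matrices: negative-binomial counts for 17 individuals x 2
# compartments with a massively exported cluster, random compartment effects
# on a subset of transcripts, compartment-specific dispersion, and
# haplotype-driven cis effects in the children.

#' Simulate transcript counts for the paired cell/exosome design
#'
#' For transcript t in sample s the count is NB with mean
#' `L_s * q_t * 2^(LFC_t * I[exosome]) * exp(beta_p p + beta_m m)` (the
#' haplotype term applies only to children at planted eQTL transcripts) and
#' compartment-specific dispersion. Members of the planted exported cluster
#' receive `exported_cluster_lfc`.
#'
#' @param pedigree Pedigree data frame from [simulate_pedigree_genotypes()].
#' @param annotation A `mirna_annotation`.
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_pedigree_genotypes()]; required when
#'   `n_eqtl_mirnas > 0` (supplies the children's haplotype origins).
#' @return List with `counts` (a [count_matrix()]) and `truth` (the input
#'   truth augmented with `lfc`, `eqtl` and `exported_cluster` entries).
#' @export
simulate_counts <- function(pedigree, annotation, config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "mirna_annotation"))
  exported_matures <- annotation$matures$name[
    annotation$matures$parent %in% annotation$exported_cluster]
  if (length(annotation$exported_cluster) < config$exported_cluster_size)
    stop_config("annotation lacks a qualifying exported cluster")
  if (config$n_eqtl_mirnas > 0L && is.null(truth))
    stop_config("truth (haplotype origins) required to plant eQTL effects")

  with_seed(stream_seed(config, "counts"), {
    tx <- annotation$transcripts
    n_tx <- nrow(tx)
    samples <- data.frame(
      sample = c(paste0(pedigree$id, "_cell"), paste0(pedigree$id, "_exosome")),
      individual = rep(pedigree$id, 2L),
      compartment = rep(c("cell", "exosome"), each = nrow(pedigree)),
      stringsAsFactors = FALSE
    )

    # baseline relative abundance; the exported cluster is anchored at a
    # moderate exosome-side abundance (baseline q scaled by 2^-LFC), so it is
    # nearly undetectable in cells while leaving the rest of the exosome
    # library uncompressed
    q <- stats::rlnorm(n_tx, meanlog = 0, sdlog = 1.5)
    names(q) <- tx$name
    q[exported_matures] <- stats::rlnorm(length(exported_matures),
                                         meanlog = 3, sdlog = 0.3) *
      2^(-config$exported_cluster_lfc)
    q <- q / sum(q)

    # compartment log2 fold changes
    lfc <- stats::setNames(numeric(n_tx), tx$name)
    class_lfc <- c(miRNA = -0.5, snoRNA = -1, piRNA = 1, rRNA = 1,
                   lincRNA = 0, misc = 0)
    lfc[] <- class_lfc[tx$biotype]
    lfc[exported_matures] <- config$exported_cluster_lfc

    # planted eQTLs: mature miRNAs outside the exported cluster, reasonably
    # abundant so they pass the median-expression filter
    eqtl <- data.frame(transcript = character(), beta_p = numeric(),
                       beta_m = numeric(), stringsAsFactors = FALSE)
    eqtl_mult <- matrix(1, n_tx, nrow(samples),
                        dimnames = list(tx$name, samples$sample))
    eq_tx <- character(0)
    if (config$n_eqtl_mirnas > 0L) {
      mi <- setdiff(tx$name[tx$biotype == "miRNA"], exported_matures)
      cand <- mi[order(q[mi], decreasing = TRUE)][seq_len(min(30L, length(mi)))]
      eq_tx <- sample(cand, min(config$n_eqtl_mirnas, length(cand)))
      children <- pedigree$id[pedigree$generation == 3L]
      mk <- rownames(truth$origins$paternal)
      mk_chrom <- sub("_[0-9]+$", "", mk)
      mk_pos <- as.numeric(sub("^.*_", "", mk))
      for (t in eq_tx) {
        mid <- (tx[t, "start"] + tx[t, "end"]) / 2
        sel <- which(mk_chrom == tx[t, "chrom"])
        near <- sel[which.min(abs(mk_pos[sel] - mid))]
        p <- truth$origins$paternal[near, children]
        m <- truth$origins$maternal[near, children]
        mult <- exp(config$eqtl_beta * p + config$eqtl_beta_m * m)
        for (comp in c("cell", "exosome"))
          eqtl_mult[t, paste0(children, "_", comp)] <- mult
        eqtl <- rbind(eqtl, data.frame(
          transcript = t, beta_p = config$eqtl_beta,
          beta_m = config$eqtl_beta_m, marker = mk[near],
          stringsAsFactors = FALSE))
      }
    }

    # random compartment effects on a subset of the remaining transcripts
    # (planted eQTL transcripts excluded to keep effects orthogonal)
    free <- setdiff(tx$name, c(exported_matures, eq_tx))
    n_de <- round(config$frac_de * length(free))
    de_tx <- sample(free, n_de)
    lfc[de_tx] <- lfc[de_tx] + stats::rnorm(n_de, 0, config$de_lfc_sd)

    lib <- round(stats::runif(nrow(samples), config$library_size_range[1],
                              config$library_size_range[2]))
    is_exo <- samples$compartment == "exosome"
    # rescale q per compartment so column totals stay near the library size
    # despite the planted fold changes
    q_mat <- matrix(0, n_tx, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      qq <- q * 2^(lfc * is_exo[j])
      q_mat[, j] <- qq / sum(qq)
    }
    mu <- sweep(q_mat * eqtl_mult, 2L, lib, `*`)
    size_c <- 1 / config$nb_dispersion_cell
    size_e <- 1 / config$nb_dispersion_exosome
    counts <- matrix(0L, n_tx, nrow(samples),
                     dimnames = list(tx$name, samples$sample))
    for (j in seq_len(nrow(samples))) {
      counts[, j] <- stats::rnbinom(n_tx, mu = mu[, j],
                                    size = if (is_exo[j]) size_e else size_c)
    }

    truth <- truth %||% list()
    truth$lfc <- lfc
    truth$eqtl <- eqtl
    truth$exported_cluster <- list(hairpins = annotation$exported_cluster,
                                   matures = exported_matures,
                                   lfc = config$exported_cluster_lfc)
    list(counts = count_matrix(counts, samples), truth = truth)
  })
}
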