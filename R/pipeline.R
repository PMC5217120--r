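# End-to-end orchestration over the synthetic study: simulation ->
# clusters -> composition -> differential expression (mature / cluster /
# piRNA) -> variability -> haplotypes -> eQTL (+ QC) -> NTA.

#' Run the full synthetic pipeline
#'
#' Simulates the study (pedigree, genotypes, annotation, counts, alignments),
#' runs every analysis stage, writes per-stage TSVs and a JSON summary under
#' `out_dir`, and returns all intermediate objects.
#'
#' @param config A [sim_config()] (its `seed` drives every stage).
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param de_fdr FDR threshold for differential expression (default 0.01).
#' @param eqtl_fdr FDR threshold for the shared-eQTL intersection (default
#'   0.20).
#' @param min_median eQTL expression filter threshold (default 10).
#' @param cluster_gap Clustering gap in bp (default 10000).
#' @param min_aligned Minimum matched length for NTA extraction (default 16).
#' @param stages Character vector of stages to run (default all):
#'   "composition", "diffexp", "variability", "haplotypes", "eqtl", "nta".
#' @return List of class `pipeline_result` with the per-stage outputs and a
#'   `summary` list.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         de_fdr = 0.01, eqtl_fdr = 0.20, min_median = 10,
                         cluster_gap = 10000, min_aligned = 16L,
                         stages = c("composition", "diffexp", "variability",
                                    "haplotypes", "eqtl", "nta")) {
  stopifnot(inherits(config, "sim_config"))
  if (de_fdr <= 0 || de_fdr > 1 || eqtl_fdr <= 0 || eqtl_fdr > 1)
    stop_config("FDR thresholds must be in (0, 1]")
  t0 <- Sys.time()
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("R version: %s", getRversion()))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- simulation -----------------------------------------------------------
  sim <- run_stage("simulate", {
    pg <- simulate_pedigree_genotypes(config)
    ann <- simulate_annotation(config, avoid = pg$genotypes$markers)
    cnt <- simulate_counts(pg$pedigree, ann, config, pg$truth)
    list(pedigree = pg$pedigree, genotypes = pg$genotypes, truth = cnt$truth,
         annotation = ann, counts = cnt$counts)
  })
  emit("genotypes.vcf", function(p) write_genotypes_vcf(sim$genotypes, p))
  emit("annotation.gff3", function(p) write_mirna_annotation(sim$annotation, p))
  emit("counts.tsv", function(p)
    write_counts_tsv(sim$counts, p, file.path(dirname(p), "samples.tsv")))
  biotype <- stats::setNames(sim$annotation$transcripts$biotype,
                             sim$annotation$transcripts$name)
  summary <- list(seed = config$seed, stages = list())
  out <- list(config = config, sim = sim)

  # --- clusters (needed by diffexp; always built) ---------------------------
  cl <- run_stage("clusters", build_clusters(sim$annotation, max_gap = cluster_gap))
  emit("clusters.tsv", function(p) write_cluster_table(cl, sim$annotation, p))
  out$clusters <- cl

  if ("composition" %in% stages) {
    comp <- run_stage("composition", {
      prop <- biotype_proportions(sim$counts, biotype)
      list(proportions = prop, tests = compare_compositions(prop))
    })
    emit("composition_tests.tsv", function(p)
      utils::write.table(comp$tests, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    out$composition <- comp
    summary$stages$composition <- "ok"
  }

  mirna_tx <- names(biotype)[biotype == "miRNA"]
  pirna_tx <- names(biotype)[biotype == "piRNA"]
  subset_tx <- function(cm, tx)
    count_matrix(cm$counts[rownames(cm$counts) %in% tx, , drop = FALSE],
                 cm$samples)

  if ("diffexp" %in% stages) {
    de <- run_stage("diffexp", {
      mature <- nb_differential_test(subset_tx(sim$counts, mirna_tx))
      pirna <- nb_differential_test(subset_tx(sim$counts, pirna_tx))
      clc <- aggregate_cluster_counts(subset_tx(sim$counts, mirna_tx), cl)
      cluster <- nb_differential_test(clc)
      list(mature = mature, pirna = pirna, cluster = cluster,
           cluster_counts = clc)
    })
    for (lvl in c("mature", "pirna", "cluster"))
      emit(sprintf("diffexp_%s.tsv", lvl), function(p)
        utils::write.table(de[[lvl]], p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    out$diffexp <- de
    summary$stages$diffexp <- "ok"
    summary$n_de <- lapply(de[c("mature", "pirna", "cluster")], function(r)
      sum(!is.na(r$padj) & r$padj < de_fdr))
    exported_cluster_id <- unique(cl$hairpin_cluster[
      sim$truth$exported_cluster$hairpins])
    ec <- de$cluster[de$cluster$transcript == exported_cluster_id, ]
    summary$exported_cluster <- list(
      cluster = exported_cluster_id,
      log2fc = if (nrow(ec)) ec$log2fc else NA_real_,
      padj = if (nrow(ec)) ec$padj else NA_real_,
      significant = nrow(ec) > 0 && !is.na(ec$padj) && ec$padj < de_fdr)
  }

  if ("variability" %in% stages) {
    vb <- run_stage("variability", {
      norm <- normalize_counts(subset_tx(sim$counts, mirna_tx))
      rho <- spearman_matrix(norm, sim$counts$samples$compartment)
      list(rho = rho, hc = cluster_samples(rho),
           test = compare_within_compartment_variability(rho))
    })
    emit("spearman_mirna.tsv", function(p)
      utils::write.table(unclass(vb$rho), p, sep = "\t", quote = FALSE))
    emit("dendrogram_mirna.nwk", function(p) write_dendrogram_newick(vb$hc, p))
    out$variability <- vb
    summary$stages$variability <- "ok"
    summary$variability <- list(mean_within_cell = vb$test$mean_cell,
                                mean_within_exosome = vb$test$mean_exosome,
                                p = vb$test$p)
  }

  blocks <- NULL
  if (any(c("haplotypes", "eqtl") %in% stages)) {
    hap <- run_stage("haplotypes", {
      mf <- mendelian_filter(sim$genotypes, sim$pedigree)
      ph <- phase_parents(mf$genotypes, sim$pedigree)
      tr <- infer_transmissions(mf$genotypes, ph, sim$pedigree)
      bl <- segment_blocks(tr, sim$truth$chrom_lengths)
      list(filtered = mf, phased = ph, transmissions = tr, blocks = bl)
    })
    blocks <- hap$blocks
    emit("blocks.bed", function(p)
      write_blocks(blocks, p, file.path(dirname(p), "block_codes.tsv")))
    out$haplotypes <- hap
    summary$stages$haplotypes <- "ok"
    summary$n_blocks <- nrow(blocks$blocks)
    summary$n_markers_dropped <- nrow(hap$filtered$report)
  }

  if ("eqtl" %in% stages) {
    eq <- run_stage("eqtl", {
      variants <- sim$genotypes$markers[, c("chrom", "pos")]
      fits <- lapply(c(cell = "cell", exosome = "exosome"), function(comp)
        map_eqtls(sim$counts, blocks, sim$annotation, variants, comp,
                  sim$pedigree, min_median = min_median,
                  biotypes = c("miRNA", "piRNA")))
      corr <- effect_correlation(fits$cell, fits$exosome)
      shared <- shared_eqtls(fits$cell, fits$exosome, fdr = eqtl_fdr)
      list(fits = fits, effect_correlation = corr, shared = shared)
    })
    for (comp in c("cell", "exosome"))
      emit(sprintf("eqtl_%s.tsv", comp), function(p)
        utils::write.table(eq$fits[[comp]], p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    out$eqtl <- eq
    summary$stages$eqtl <- "ok"
    summary$eqtl <- list(
      n_tested_cell = nrow(eq$fits$cell),
      n_tested_exosome = nrow(eq$fits$exosome),
      shared = eq$shared$transcript,
      beta_p_correlation = eq$effect_correlation$r[1])
  }

  if ("nta" %in% stages) {
    nta <- run_stage("nta", {
      sam_path <- tempfile(fileext = ".sam")
      aln <- simulate_hairpin_alignments(config)
      write_sam(aln$sam, sam_path)
      ntas <- extract_ntas(sam_path, min_aligned = min_aligned)
      prof <- nta_frequency_table(ntas)
      unlink(sam_path)
      list(alignments = aln, records = ntas, profile = prof)
    })
    out$nta <- nta
    summary$stages$nta <- "ok"
    summary$nta_free_percent <- nta$profile$nta_free_percent
  }

  summary$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$summary <- summary
  if (!is.null(out_dir)) {
    s <- summary; s$elapsed_sec <- NULL  # keep summary.json run-invariant
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  class(out) <- "pipeline_result"
  out
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result; stages run:",
      paste(names(x$summary$stages), collapse = ", "), "\n")
  invisible(x)
}
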