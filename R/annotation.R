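# miRNA annotation I/O and genomic clustering.
#
# An miRNA cluster is a set of hairpins in which every member lies within
# `max_gap` bp (default 10 kb) of at least one other member, i.e. the
# single-linkage connected components of the proximity graph per chromosome.
# Mature miRNAs whose parent hairpins span more than one cluster are excluded
# from cluster-level counting.

EXCLUDED_MULTI_CLUSTER <- "EXCLUDED_MULTI_CLUSTER"

#' Read a miRBase-style GFF3 annotation
#'
#' Expects `miRNA_primary_transcript` records (hairpins) and `miRNA` records
#' (matures) whose `Derives_from` attribute names the parent hairpin's ID.
#' GFF3 1-based inclusive coordinates are converted to internal 0-based
#' half-open.
#'
#' @param path GFF3 file.
#' @return A `mirna_annotation` object with `hairpins` and `matures` data
#'   frames.
#' @export
read_mirna_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_config("GFF3 parse error in %s: %s",
                                                 path, conditionMessage(e)))
  if (length(gr) == 0L) {
    return(structure(list(
      hairpins = data.frame(name = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            strand = character(), stringsAsFactors = FALSE),
      matures = data.frame(name = character(), chrom = character(),
                           start = numeric(), end = numeric(),
                           strand = character(), parent = character(),
                           stringsAsFactors = FALSE)),
      class = "mirna_annotation"))
  }
  df <- as.data.frame(gr)
  get_col <- function(d, col) if (col %in% names(d)) as.character(d[[col]]) else
    rep(NA_character_, nrow(d))
  df$ID <- get_col(df, "ID")
  df$Name <- get_col(df, "Name")
  df$Derives_from <- get_col(df, "Derives_from")
  df$label <- ifelse(is.na(df$Name), df$ID, df$Name)

  hp <- df[df$type == "miRNA_primary_transcript", , drop = FALSE]
  mt <- df[df$type == "miRNA", , drop = FALSE]
  hairpins <- data.frame(name = hp$label, chrom = as.character(hp$seqnames),
                         start = hp$start - 1L, end = hp$end,
                         strand = as.character(hp$strand),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(hairpins$name))
    stop_config("duplicate hairpin names in %s", path)
  id_to_name <- stats::setNames(hp$label, hp$ID)
  parent <- id_to_name[mt$Derives_from]
  bad <- is.na(parent)
  if (any(bad))
    stop_config("mature record(s) with unresolvable parent: %s",
                paste(mt$label[bad], collapse = ", "))
  matures <- data.frame(name = mt$label, chrom = as.character(mt$seqnames),
                        start = mt$start - 1L, end = mt$end,
                        strand = as.character(mt$strand),
                        parent = unname(parent), stringsAsFactors = FALSE)
  structure(list(hairpins = hairpins, matures = matures),
            class = "mirna_annotation")
}

#' Write a miRBase-style GFF3 annotation
#'
#' @param annotation A `mirna_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mirna_annotation <- function(annotation, path) {
  hp <- annotation$hairpins
  mt <- annotation$matures
  lines <- c("##gff-version 3",
             sprintf("%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     hp$chrom, hp$start + 1L, hp$end, hp$strand, hp$name, hp$name),
             sprintf("%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
                     mt$chrom, mt$start + 1L, mt$end, mt$strand, mt$name,
                     mt$name, mt$parent))
  writeLines(lines, path)
  invisible(path)
}

#' Build miRNA clusters under the proximity rule
#'
#' Single-linkage connected components over hairpins on the same chromosome,
#' where two hairpins are linked iff the gap between their intervals,
#' `max(0, laterStart - earlierEnd)`, is at most `max_gap`. Matures whose
#' parent hairpins fall in more than one cluster are marked
#' `EXCLUDED_MULTI_CLUSTER`.
#'
#' @param annotation A `mirna_annotation`.
#' @param max_gap Maximum inter-interval gap in bp (default 10000).
#' @param by_strand If `TRUE`, cluster each strand separately (default
#'   `FALSE`: strand ignored).
#' @return A `cluster_map`: list with `clusters` (named list: cluster id ->
#'   hairpin names), `hairpin_cluster` (named vector hairpin -> cluster id)
#'   and `mature_cluster` (named vector mature -> cluster id or
#'   `EXCLUDED_MULTI_CLUSTER`).
#' @export
build_clusters <- function(annotation, max_gap = 10000, by_strand = FALSE) {
  hp <- annotation$hairpins
  if (any(hp$start >= hp$end))
    stop_config("hairpin interval(s) with start >= end")
  hairpin_cluster <- stats::setNames(character(nrow(hp)), hp$name)
  cid <- 0L
  groups <- if (by_strand) split(hp, paste(hp$chrom, hp$strand)) else
    split(hp, hp$chrom)
  clusters <- list()
  for (g in groups) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    if (nrow(g) == 0L) next
    # sorted sweep: a new component starts when the gap to the furthest end
    # seen so far exceeds max_gap (equivalent to single linkage on intervals)
    run_end <- g$end[1]
    comp <- list(g$name[1])
    for (i in seq_len(nrow(g))[-1]) {
      gap <- max(0, g$start[i] - run_end)
      if (gap <= max_gap) {
        comp[[length(comp)]] <- c(comp[[length(comp)]], g$name[i])
      } else {
        comp[[length(comp) + 1L]] <- g$name[i]
      }
      run_end <- max(run_end, g$end[i])
      if (gap > max_gap) run_end <- g$end[i]
    }
    for (members in comp) {
      cid <- cid + 1L
      id <- sprintf("cluster_%04d", cid)
      clusters[[id]] <- members
      hairpin_cluster[members] <- id
    }
  }
  mature_cluster <- character(0)
  if (!is.null(annotation$matures) && nrow(annotation$matures)) {
    mt <- annotation$matures
    mature_cluster <- vapply(split(mt$parent, mt$name), function(parents) {
      cls <- unique(hairpin_cluster[parents])
      if (length(cls) > 1L) EXCLUDED_MULTI_CLUSTER else cls
    }, character(1))
    mature_cluster <- mature_cluster[unique(mt$name)]  # original order
  }
  structure(list(clusters = clusters, hairpin_cluster = hairpin_cluster,
                 mature_cluster = mature_cluster, max_gap = max_gap),
            class = "cluster_map")
}

#' @exportS3Method base::print
print.cluster_map <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("cluster_map: %d clusters over %d hairpins (largest %d); %d matures assigned, %d excluded\n",
              length(x$clusters), length(x$hairpin_cluster), max(sizes, 0),
              sum(x$mature_cluster != EXCLUDED_MULTI_CLUSTER),
              sum(x$mature_cluster == EXCLUDED_MULTI_CLUSTER)))
  invisible(x)
}

#' Aggregate mature-level counts to cluster level
#'
#' Cluster count = per-sample sum of the counts of matures assigned to the
#' cluster; excluded matures contribute nothing; clusters with no counted
#' mature appear with zero counts.
#'
#' @param counts A [count_matrix()] over mature miRNAs.
#' @param cluster_map A `cluster_map` from [build_clusters()].
#' @return A [count_matrix()] over cluster ids.
#' @export
aggregate_cluster_counts <- function(counts, cluster_map) {
  stopifnot(inherits(counts, "count_matrix"), inherits(cluster_map, "cluster_map"))
  tx <- rownames(counts$counts)
  missing <- setdiff(tx, names(cluster_map$mature_cluster))
  if (length(missing))
    stop_config("matures absent from cluster_map: %s",
                paste(missing, collapse = ", "))
  assign <- cluster_map$mature_cluster[tx]
  keep <- assign != EXCLUDED_MULTI_CLUSTER
  out <- matrix(0L, length(cluster_map$clusters), ncol(counts$counts),
                dimnames = list(names(cluster_map$clusters),
                                colnames(counts$counts)))
  if (any(keep)) {
    agg <- rowsum(counts$counts[keep, , drop = FALSE], assign[keep])
    out[rownames(agg), ] <- agg
  }
  storage.mode(out) <- "integer"
  count_matrix(out, counts$samples)
}

#' Write a cluster table as TSV
#' @param cluster_map A `cluster_map`.
#' @param annotation The `mirna_annotation` it was built from.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cluster_map, annotation, path) {
  hp <- annotation$hairpins
  rows <- lapply(names(cluster_map$clusters), function(id) {
    members <- cluster_map$clusters[[id]]
    h <- hp[hp$name %in% members, , drop = FALSE]
    mats <- names(cluster_map$mature_cluster)[cluster_map$mature_cluster == id]
    excl <- if (!is.null(annotation$matures)) {
      mt <- annotation$matures
      excl_all <- names(cluster_map$mature_cluster)[
        cluster_map$mature_cluster == EXCLUDED_MULTI_CLUSTER]
      excl_all[excl_all %in% mt$name[mt$parent %in% members]]
    } else character(0)
    data.frame(cluster = id, chrom = h$chrom[1], start = min(h$start),
               end = max(h$end), n_hairpins = nrow(h),
               hairpins = paste(members, collapse = ","),
               matures = paste(mats, collapse = ","),
               excluded_matures = paste(unique(excl), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
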