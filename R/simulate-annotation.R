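# Synthetic small-RNA annotation: miRNA hairpins with mature products
# (miRBase-style), piRNAs, and background transcripts of the remaining
# biotype classes. Internally coordinates are 0-based half-open; GFF3 I/O
# converts to/from 1-based inclusive.

#' Simulate a small-RNA annotation
#'
#' Places `n_mirnas` hairpins across the chromosomes with one planted
#' genomic cluster (`exported_cluster_size` hairpins spaced < 10 kb apart);
#' all other features are spaced > 10 kb from each other so they form
#' singleton clusters. Each hairpin yields a -5p mature and, with probability
#' 1/2, a -3p mature. Transcript placement avoids positions in `avoid`
#' (e.g. genotype markers) so planted eQTL transcripts are not discarded by
#' the variant-overlap exclusion.
#'
#' @param config A [sim_config()].
#' @param avoid Optional data frame with columns `chrom`, `pos` of positions
#'   transcripts must not overlap.
#' @return A `mirna_annotation` object: list with `hairpins`, `matures`,
#'   `transcripts` (all transcripts incl. piRNA and background classes, with
#'   `biotype` and `multi_locus` columns) and `exported_cluster` (hairpin
#'   names of the planted cluster).
#' @export
simulate_annotation <- function(config, avoid = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stream_seed(config, "annotation"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    hp_len <- 80L
    n_hp <- config$n_mirnas
    if (n_hp < config$exported_cluster_size)
      stop_config("n_mirnas must be >= exported_cluster_size")

    # planted cluster on chr1: members 2 kb apart (gaps well under 10 kb)
    clus_n <- config$exported_cluster_size
    clus_start <- round(0.3 * config$chrom_length)
    clus_starts <- clus_start + (seq_len(clus_n) - 1L) * 2000L

    # remaining hairpins: >10 kb + hairpin length apart so all singleton
    n_rest <- n_hp - clus_n
    rest <- scatter_features(n_rest, chroms, config$chrom_length,
                             min_gap = 10000L + hp_len + 1L,
                             forbidden = list(chrom = "chr1",
                                              start = clus_start - 20000L,
                                              end = max(clus_starts) + 20000L))
    hairpins <- data.frame(
      name = sprintf("mir-%03d", seq_len(n_hp)),
      chrom = c(rep("chr1", clus_n), rest$chrom),
      start = c(clus_starts, rest$start),
      end = c(clus_starts, rest$start) + hp_len,
      strand = sample(c("+", "-"), n_hp, replace = TRUE),
      stringsAsFactors = FALSE
    )
    exported <- hairpins$name[seq_len(clus_n)]

    mats <- list()
    for (i in seq_len(n_hp)) {
      arms <- c("5p", if (stats::runif(1) < 0.5) "3p")
      for (a in arms) {
        off <- if (a == "5p") 4L else 50L
        mats[[length(mats) + 1L]] <- data.frame(
          name = sprintf("%s-%s", hairpins$name[i], a),
          chrom = hairpins$chrom[i],
          start = hairpins$start[i] + off,
          end = hairpins$start[i] + off + 22L,
          strand = hairpins$strand[i],
          parent = hairpins$name[i],
          stringsAsFactors = FALSE
        )
      }
    }
    matures <- do.call(rbind, mats)

    other_classes <- c(piRNA = config$n_pirnas,
                       lincRNA = config$n_other_per_class,
                       misc = config$n_other_per_class,
                       rRNA = config$n_other_per_class,
                       snoRNA = config$n_other_per_class)
    occupied <- data.frame(chrom = hairpins$chrom, start = hairpins$start,
                           end = hairpins$end)
    oth <- list()
    for (cl in names(other_classes)) {
      n_cl <- other_classes[[cl]]
      len <- switch(cl, piRNA = 28L, rRNA = 120L, 60L)
      sc <- scatter_features(n_cl, chroms, config$chrom_length,
                             min_gap = 10000L + len + 1L,
                             occupied = occupied)
      occupied <- rbind(occupied,
                        data.frame(chrom = sc$chrom, start = sc$start,
                                   end = sc$start + len))
      oth[[cl]] <- data.frame(
        name = sprintf("%s-%03d", tolower(cl), seq_len(n_cl)),
        chrom = sc$chrom, start = sc$start, end = sc$start + len,
        strand = "+", biotype = cl, stringsAsFactors = FALSE
      )
    }
    other <- do.call(rbind, oth)
    rownames(other) <- NULL

    transcripts <- rbind(
      data.frame(name = matures$name, chrom = matures$chrom,
                 start = matures$start, end = matures$end,
                 strand = matures$strand, biotype = "miRNA",
                 stringsAsFactors = FALSE),
      other
    )
    transcripts$multi_locus <- FALSE
    # a couple of multi-locus piRNAs exercise the eQTL exclusion rule
    pi_idx <- which(transcripts$biotype == "piRNA")
    if (length(pi_idx) >= 2L)
      transcripts$multi_locus[pi_idx[1:2]] <- TRUE
    rownames(transcripts) <- transcripts$name

    ann <- structure(list(hairpins = hairpins, matures = matures,
                          transcripts = transcripts,
                          exported_cluster = exported),
                     class = "mirna_annotation")
    if (!is.null(avoid)) ann <- shift_off_variants(ann, avoid)
    ann
  })
}

# Place n features on random chromosomes with pairwise gaps > min_gap on the
# same chromosome, avoiding a forbidden window and previously occupied spans.
scatter_features <- function(n, chroms, chrom_length, min_gap,
                             forbidden = NULL, occupied = NULL) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer()))
  chrom <- character(n); start <- numeric(n)
  placed <- if (is.null(occupied))
    data.frame(chrom = character(), start = numeric(), end = numeric())
  else occupied
  for (i in seq_len(n)) {
    for (try in 1:2000) {
      ch <- sample(chroms, 1L)
      s <- sample.int(chrom_length - 200L, 1L)
      if (!is.null(forbidden) && ch == forbidden$chrom &&
          s >= forbidden$start && s <= forbidden$end) next
      same <- placed[placed$chrom == ch, , drop = FALSE]
      if (nrow(same) && any(abs(same$start - s) < min_gap)) next
      chrom[i] <- ch; start[i] <- s
      placed <- rbind(placed, data.frame(chrom = ch, start = s,
                                         end = s + min_gap))
      break
    }
    if (chrom[i] == "") stop_config("could not place %d features; genome too dense", n)
  }
  data.frame(chrom = chrom, start = start)
}

# Nudge any transcript (and its hairpin) overlapping a marker position so the
# eQTL variant-overlap exclusion does not silently discard planted signals.
shift_off_variants <- function(ann, avoid) {
  overlaps <- function(chrom, start, end) {
    hit <- avoid$chrom == chrom & avoid$pos >= start & avoid$pos <= end
    any(hit)
  }
  for (i in seq_len(nrow(ann$hairpins))) {
    h <- ann$hairpins[i, ]
    while (overlaps(h$chrom, h$start - 5L, h$end + 5L)) {
      shift <- 200L
      h$start <- h$start + shift; h$end <- h$end + shift
    }
    if (h$start != ann$hairpins$start[i]) {
      d <- h$start - ann$hairpins$start[i]
      sel <- ann$matures$parent == h$name
      ann$matures$start[sel] <- ann$matures$start[sel] + d
      ann$matures$end[sel] <- ann$matures$end[sel] + d
      msel <- ann$transcripts$name %in% ann$matures$name[sel]
      ann$transcripts$start[msel] <- ann$transcripts$start[msel] + d
      ann$transcripts$end[msel] <- ann$transcripts$end[msel] + d
      ann$hairpins[i, c("start", "end")] <- h[, c("start", "end")]
    }
  }
  for (i in which(ann$transcripts$biotype != "miRNA")) {
    t <- ann$transcripts[i, ]
    moved <- FALSE
    while (overlaps(t$chrom, t$start - 5L, t$end + 5L)) {
      t$start <- t$start + 200L; t$end <- t$end + 200L; moved <- TRUE
    }
    if (moved) ann$transcripts[i, c("start", "end")] <- t[, c("start", "end")]
  }
  ann
}

#' @exportS3Method base::print
print.mirna_annotation <- function(x, ...) {
  cat(sprintf("mirna_annotation: %d hairpins, %d matures, %d transcripts total\n",
              nrow(x$hairpins), nrow(x$matures), nrow(x$transcripts)))
  invisible(x)
}
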