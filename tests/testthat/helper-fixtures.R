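# Shared fixture builders (all generated in code; nothing on disk).

# Minimal annotation from a hairpin table; optional explicit matures.
make_annotation <- function(hairpins, matures = NULL) {
  if (is.null(matures)) {
    matures <- data.frame(
      name = paste0(hairpins$name, "-5p"), chrom = hairpins$chrom,
      start = hairpins$start + 4, end = hairpins$start + 26,
      strand = hairpins$strand, parent = hairpins$name,
      stringsAsFactors = FALSE)
  }
  structure(list(hairpins = hairpins, matures = matures),
            class = "mirna_annotation")
}

hp_row <- function(name, chrom, start, end, strand = "+") {
  data.frame(name = name, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

# Random annotation of up to max_n hairpins on a couple of chromosomes,
# used by the clustering oracle suite.
random_annotation <- function(max_n = 50, max_pos = 2e5) {
  n <- sample(2:max_n, 1)
  hp <- data.frame(
    name = sprintf("h%02d", seq_len(n)),
    chrom = sample(c("cA", "cB"), n, replace = TRUE),
    start = sample.int(max_pos, n),
    strand = "+", stringsAsFactors = FALSE)
  hp$end <- hp$start + sample(50:120, n, replace = TRUE)
  make_annotation(hp)
}

# Brute-force single-linkage clustering oracle: union-find over all hairpin
# pairs linked when same chromosome and interval gap <= max_gap.
oracle_clusters <- function(hairpins, max_gap = 10000) {
  n <- nrow(hairpins)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (hairpins$chrom[i] != hairpins$chrom[j]) next
    gap <- max(0, max(hairpins$start[i], hairpins$start[j]) -
                 min(hairpins$end[i], hairpins$end[j]))
    if (hairpins$start[i] <= hairpins$end[j] &&
        hairpins$start[j] <= hairpins$end[i]) gap <- 0
    if (gap <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(hairpins$name, roots)
}

# Canonical form of a hairpin partition for set comparison.
canon_partition <- function(groups) {
  s <- lapply(groups, function(g) sort(g))
  unname(s[order(vapply(s, `[`, character(1), 1))])
}

# Small count matrix with paired cell/exosome samples for n individuals.
make_paired_counts <- function(mat, n_ind) {
  samples <- data.frame(
    sample = colnames(mat),
    individual = rep(sprintf("i%02d", seq_len(n_ind)), 2),
    compartment = rep(c("cell", "exosome"), each = n_ind),
    stringsAsFactors = FALSE)
  count_matrix(mat, samples)
}
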