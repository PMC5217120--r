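# GFF3 I/O, the 10-kb proximity clustering, and cluster-level counting.

test_that("miRBase-style GFF3 round-trips through read_mirna_annotation", {
  hp <- rbind(hp_row("hpA", "chr1", 1000, 1080), hp_row("hpB", "chr1", 9000, 9080, "-"))
  mt <- data.frame(name = c("hpA-5p", "hpA-3p", "hpB-5p"),
                   chrom = "chr1", start = c(1004, 1050, 9004),
                   end = c(1026, 1072, 9026), strand = c("+", "+", "-"),
                   parent = c("hpA", "hpA", "hpB"), stringsAsFactors = FALSE)
  ann <- make_annotation(hp, mt)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_mirna_annotation(ann, f)
  got <- read_mirna_annotation(f)
  expect_equal(nrow(got$hairpins), 2)
  expect_equal(nrow(got$matures), 3)
  got$hairpins[] <- lapply(got$hairpins, function(c) if (is.integer(c)) as.numeric(c) else c)
  got$matures[] <- lapply(got$matures, function(c) if (is.integer(c)) as.numeric(c) else c)
  expect_equal(got$hairpins, ann$hairpins)
  expect_equal(got$matures, ann$matures)
})

test_that("empty GFF3 yields an empty annotation without error", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  ann <- read_mirna_annotation(f)
  expect_equal(nrow(ann$hairpins), 0)
  expect_equal(nrow(ann$matures), 0)
})

test_that("a record with end < start is rejected", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tmiRNA_primary_transcript\t500\t100\t.\t+\t.\tID=bad;Name=bad"),
             f)
  expect_error(read_mirna_annotation(f), "parse error")
})

test_that("a mature with an unresolvable parent is rejected by name", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tmiRNA_primary_transcript\t100\t180\t.\t+\t.\tID=hpA;Name=hpA",
               "chr1\t.\tmiRNA\t104\t126\t.\t+\t.\tID=orphan;Name=orphan;Derives_from=ghost"),
             f)
  expect_error(read_mirna_annotation(f), "orphan")
})

test_that("hand-derived single-linkage example clusters correctly", {
  hp <- rbind(hp_row("h1", "chr1", 1000, 1080),
              hp_row("h2", "chr1", 9000, 9080),
              hp_row("h3", "chr1", 25000, 25080))
  cm <- build_clusters(make_annotation(hp))
  # gaps: 9000-1080 = 7920 (linked), 25000-9080 = 15920 (not)
  got <- canon_partition(cm$clusters)
  expect_equal(got, list(c("h1", "h2"), "h3"))
})

test_that("a lone hairpin forms a singleton cluster keeping its matures", {
  hp <- hp_row("solo", "chr2", 100, 180)
  cm <- build_clusters(make_annotation(hp))
  expect_length(cm$clusters, 1)
  expect_equal(unname(cm$mature_cluster["solo-5p"]),
               unname(cm$hairpin_cluster["solo"]))
})

test_that("a mature derived from hairpins in two clusters is excluded", {
  hp <- rbind(hp_row("hpX", "chr1", 1000, 1080),
              hp_row("hpY", "chr1", 500000, 500080))
  mt <- data.frame(name = c("shared-mat", "shared-mat"),
                   chrom = "chr1", start = c(1004, 500004),
                   end = c(1026, 500026), strand = "+",
                   parent = c("hpX", "hpY"), stringsAsFactors = FALSE)
  cm <- build_clusters(make_annotation(hp, mt))
  expect_length(cm$clusters, 2)
  expect_equal(unname(cm$mature_cluster["shared-mat"]), "EXCLUDED_MULTI_CLUSTER")
})

test_that("a 42-hairpin cluster block is recovered as one cluster", {
  # synthetic locus shaped like the large exported cluster: 42 hairpins a few
  # kb apart yielding 74 matures, plus distant singletons
  starts <- 101000000 + cumsum(c(0, sample(2000:6000, 41, replace = TRUE)))
  hp <- do.call(rbind, lapply(1:42, function(i)
    hp_row(sprintf("c14-%02d", i), "chr14", starts[i], starts[i] + 90)))
  n_mat <- c(rep(2, 32), rep(1, 10))  # 74 matures
  mt <- do.call(rbind, lapply(1:42, function(i) {
    arms <- c("5p", "3p")[seq_len(n_mat[i])]
    data.frame(name = sprintf("%s-%s", hp$name[i], arms), chrom = "chr14",
               start = hp$start[i] + c(4, 50)[seq_len(n_mat[i])],
               end = hp$start[i] + c(26, 72)[seq_len(n_mat[i])],
               strand = "+", parent = hp$name[i], stringsAsFactors = FALSE)
  }))
  far <- rbind(hp_row("far1", "chr14", 200000000, 200000090),
               hp_row("far2", "chr2", 5000, 5090))
  ann <- make_annotation(rbind(hp, far),
                         rbind(mt, data.frame(name = c("far1-5p", "far2-5p"),
                                              chrom = c("chr14", "chr2"),
                                              start = far$start + 4,
                                              end = far$start + 26, strand = "+",
                                              parent = far$name,
                                              stringsAsFactors = FALSE)))
  cm <- build_clusters(ann)
  sizes <- sort(lengths(cm$clusters), decreasing = TRUE)
  expect_equal(unname(sizes), c(42, 1, 1))
  big <- names(cm$clusters)[which.max(lengths(cm$clusters))]
  expect_equal(sum(cm$mature_cluster == big), 74)
})

test_that("clustering is a partition and respects max_gap extremes", {
  set.seed(31)
  for (rep in 1:20) {
    ann <- random_annotation()
    cm <- build_clusters(ann)
    expect_equal(sum(lengths(cm$clusters)), nrow(ann$hairpins))
    expect_false(anyDuplicated(unlist(cm$clusters)) > 0)
    # max_gap = Inf: one cluster per chromosome
    cm_inf <- build_clusters(ann, max_gap = Inf)
    expect_equal(length(cm_inf$clusters), length(unique(ann$hairpins$chrom)))
    # max_gap = 0: only touching/overlapping hairpins share a cluster
    cm0 <- build_clusters(ann, max_gap = 0)
    for (members in cm0$clusters) {
      if (length(members) == 1) next
      h <- ann$hairpins[ann$hairpins$name %in% members, ]
      h <- h[order(h$start), ]
      expect_true(all(h$start[-1] <= cummax(h$end)[-nrow(h)]))
    }
  }
})

test_that("clustering matches a brute-force union-find oracle", {
  set.seed(17)
  for (rep in 1:100) {
    ann <- random_annotation()
    gap <- sample(c(0, 100, 5000, 10000, 50000), 1)
    got <- canon_partition(build_clusters(ann, max_gap = gap)$clusters)
    want <- canon_partition(oracle_clusters(ann$hairpins, max_gap = gap))
    expect_equal(got, want)
  }
})

test_that("cluster counts sum assigned matures and conserve totals", {
  hp <- rbind(hp_row("hA", "chr1", 1000, 1080),
              hp_row("hB", "chr1", 2000, 2080),
              hp_row("hC", "chr1", 900000, 900080))
  mt <- data.frame(name = c("m1", "m2", "m3", "dup", "dup"),
                   chrom = "chr1",
                   start = c(1004, 2004, 900004, 1050, 900050),
                   end = c(1026, 2026, 900026, 1072, 900072),
                   strand = "+",
                   parent = c("hA", "hB", "hC", "hA", "hC"),
                   stringsAsFactors = FALSE)
  ann <- make_annotation(hp, mt)
  cm <- build_clusters(ann)
  x <- rbind(m1 = c(5L, 1L), m2 = c(7L, 2L), m3 = c(2L, 3L), dup = c(9L, 9L))
  colnames(x) <- c("s1", "s2")
  counts <- count_matrix(x, data.frame(sample = c("s1", "s2"),
                                       individual = c("i1", "i1"),
                                       compartment = c("cell", "exosome")))
  agg <- aggregate_cluster_counts(counts, cm)
  ab <- unname(cm$hairpin_cluster["hA"])
  cc <- unname(cm$hairpin_cluster["hC"])
  expect_equal(unname(agg$counts[ab, ]), c(12L, 3L))   # m1 + m2
  expect_equal(unname(agg$counts[cc, ]), c(2L, 3L))    # m3; dup excluded
  # conservation over non-excluded matures
  keep <- names(cm$mature_cluster)[cm$mature_cluster != "EXCLUDED_MULTI_CLUSTER"]
  expect_equal(colSums(agg$counts), colSums(x[keep, ]))
  # unknown mature is an error naming it
  bad <- count_matrix(rbind(x, mystery = c(1L, 1L)), counts$samples)
  expect_error(aggregate_cluster_counts(bad, cm), "mystery")
})

test_that("all matures excluded yields an all-zero cluster row", {
  hp <- rbind(hp_row("h1", "chr1", 100, 180),
              hp_row("h2", "chr1", 700000, 700080))
  mt <- data.frame(name = c("only", "only"), chrom = "chr1",
                   start = c(104, 700004), end = c(126, 700026), strand = "+",
                   parent = c("h1", "h2"), stringsAsFactors = FALSE)
  cm <- build_clusters(make_annotation(hp, mt))
  counts <- count_matrix(matrix(5L, 1, 2, dimnames = list("only", c("a", "b"))),
                         data.frame(sample = c("a", "b"), individual = "i1",
                                    compartment = c("cell", "exosome")))
  agg <- aggregate_cluster_counts(counts, cm)
  expect_true(all(agg$counts == 0))
  expect_equal(nrow(agg$counts), 2)
})
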