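# Mendelian filtering, grandparent-anchored phasing, transmission inference
# with smoothing, and block segmentation.

# tiny hand-built pedigree + genotypes helper
tiny_gt <- function(dosage_rows, positions = NULL) {
  n <- nrow(dosage_rows)
  positions <- positions %||% (seq_len(n) * 1000)
  mk <- data.frame(chrom = "chr1", pos = positions, ref = "A", alt = "G",
                   id = sprintf("chr1_%d", positions), stringsAsFactors = FALSE)
  rownames(mk) <- mk$id
  rownames(dosage_rows) <- mk$id
  structure(list(markers = mk, dosage = dosage_rows),
            class = "genotype_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_ped <- function(n_children = 1) {
  kids <- sprintf("child%02d", seq_len(n_children))
  data.frame(
    id = c("gf_p", "gm_p", "gf_m", "gm_m", "father", "mother", kids),
    father = c(NA, NA, NA, NA, "gf_p", "gf_m", rep("father", n_children)),
    mother = c(NA, NA, NA, NA, "gm_p", "gm_m", rep("mother", n_children)),
    sex = c("M", "F", "M", "F", "M", "F", rep("M", n_children)),
    generation = c(1, 1, 1, 1, 2, 2, rep(3, n_children)),
    stringsAsFactors = FALSE)
}

test_that("impossible trios are dropped and possible ones kept", {
  ped <- tiny_ped()
  # marker 1: parents 0/0 x 0/0, child 0/1 -> impossible
  # marker 2: parents 0/1 x 0/1, child 0/0 -> possible
  # marker 3: father 2, mother 0, child 0 -> impossible (child must be het)
  dos <- cbind(gf_p = c(0L, 1L, 2L), gm_p = c(0L, 1L, 2L),
               gf_m = c(0L, 1L, 0L), gm_m = c(0L, 1L, 0L),
               father = c(0L, 1L, 2L), mother = c(0L, 1L, 0L),
               child01 = c(1L, 0L, 0L))
  mf <- mendelian_filter(tiny_gt(dos), ped)
  expect_equal(sort(unique(mf$report$marker)), c("chr1_1000", "chr1_3000"))
  expect_equal(rownames(mf$genotypes$dosage), "chr1_2000")
  dos2 <- dos[, setdiff(colnames(dos), "mother")]
  expect_error(mendelian_filter(tiny_gt(dos2), ped), "mother")
})

test_that("phasing anchors alleles to homozygous grandparents", {
  ped <- tiny_ped()
  # father het at all three markers:
  # m1: gf 0/0, gm 1/1 -> hap0 = 0, hap1 = 1
  # m2: gf 1/1, gm 0/1 -> hap0 = 1, hap1 = 0
  # m3: both grandparents het -> uninformative
  dos <- cbind(gf_p = c(0L, 2L, 1L), gm_p = c(2L, 1L, 1L),
               gf_m = c(0L, 0L, 0L), gm_m = c(0L, 0L, 0L),
               father = c(1L, 1L, 1L), mother = c(0L, 0L, 0L),
               child01 = c(0L, 1L, 0L))
  ph <- phase_parents(tiny_gt(dos), ped)
  expect_equal(ph$father$hap0, c(0L, 1L, NA))
  expect_equal(ph$father$hap1, c(1L, 0L, NA))
  expect_equal(ph$father$informative, c(TRUE, TRUE, FALSE))
  expect_false(any(ph$mother$informative))  # mother homozygous everywhere
})

test_that("forced transmissions map to the phased haplotype origin", {
  ped <- tiny_ped()
  # father het with hap0 = allele 0 (gf hom 0, gm hom 1); child genotypes
  # force the transmitted allele
  dos <- cbind(gf_p = c(0L, 0L, 0L, 0L, 0L), gm_p = c(2L, 2L, 2L, 2L, 2L),
               gf_m = 0L, gm_m = 0L,
               father = 1L, mother = 0L,
               child01 = c(0L, 0L, 2L, 0L, 0L))
  gt <- tiny_gt(dos)
  ph <- phase_parents(gt, ped)
  tr <- infer_transmissions(gt, ph, ped, w = 3)
  pat <- tr[tr$side == "paternal", ]
  # child 0 -> transmitted allele 0 -> origin 0; child 2 -> allele 1 -> origin 1
  expect_equal(pat$origin_raw, c(0L, 0L, 1L, 0L, 0L))
  # the isolated switch is smoothed away by the majority vote
  expect_equal(pat$origin, rep(0L, 5))
  expect_error(infer_transmissions(gt, ph, ped, w = 4), "odd")
  expect_error(infer_transmissions(gt, ph, ped, w = 1), "odd")
})

test_that("majority vote smooths [0,0,1,0,0] to all zeros and keeps clean steps", {
  expect_equal(exosmir:::majority_smooth(c(0L, 0L, 1L, 0L, 0L), 5L),
               rep(0L, 5))
  step <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_equal(exosmir:::majority_smooth(step, 5L), step)
})

test_that("single switch yields the midpoint breakpoint and two blocks", {
  ped <- tiny_ped()
  # father informative at many markers; child switches origin between
  # markers at 1.0 Mb and 1.2 Mb
  pos <- c(2e5, 4e5, 6e5, 8e5, 1e6, 1.2e6, 1.4e6, 1.6e6, 1.8e6, 2e6)
  child <- c(0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L)
  dos <- cbind(gf_p = 0L, gm_p = 2L, gf_m = 0L, gm_m = 0L,
               father = 1L, mother = 0L, child01 = child)
  gt <- tiny_gt(dos, pos)
  ph <- phase_parents(gt, ped)
  tr <- infer_transmissions(gt, ph, ped, w = 3)
  bl <- segment_blocks(tr, c(chr1 = 2.2e6))
  expect_equal(nrow(bl$blocks), 2)
  expect_equal(bl$blocks$end[1], 1.1e6)
  expect_equal(bl$blocks$start[2], 1.1e6)
  expect_equal(unname(bl$paternal[, "child01"]), c(0L, 1L))
  # tiling: contiguous, covering [0, chrom length)
  expect_equal(bl$blocks$start[1], 0)
  expect_equal(bl$blocks$end[2], 2.2e6)
})

test_that("zero-recombination simulation gives one block per chromosome", {
  cfg <- sim_config(recomb_rate = 0, seed = 13)
  pg <- simulate_pedigree_genotypes(cfg)
  mf <- mendelian_filter(pg$genotypes, pg$pedigree)
  ph <- phase_parents(mf$genotypes, pg$pedigree)
  tr <- infer_transmissions(mf$genotypes, ph, pg$pedigree)
  bl <- segment_blocks(tr, pg$truth$chrom_lengths)
  expect_equal(nrow(bl$blocks), cfg$n_chromosomes)
})

test_that("parental phase and per-marker origins are recovered from synthetic data", {
  pg <- simulate_pedigree_genotypes(sim_config(seed = 8))
  mf <- mendelian_filter(pg$genotypes, pg$pedigree)
  ph <- phase_parents(mf$genotypes, pg$pedigree)
  # phase recovery vs the generator's parental haplotypes
  for (par in c("father", "mother")) {
    truth <- pg$truth$parent_haplotypes[[par]]
    inf <- ph[[par]]$informative
    expect_gt(mean(inf), 0.15)  # enough informative markers to work with
    expect_gt(mean(ph[[par]]$hap0[inf] == truth[inf, 1]), 0.99)
  }
  # transmission recovery
  tr <- infer_transmissions(mf$genotypes, ph, pg$pedigree)
  hit <- mapply(function(mk, ch, side, o) pg$truth$origins[[side]][mk, ch] == o,
                tr$marker, tr$child, tr$side, tr$origin)
  expect_gt(mean(hit), 0.99)
})

test_that("blocks tile chromosomes and block codes match the truth", {
  pg <- simulate_pedigree_genotypes(sim_config(seed = 15))
  mf <- mendelian_filter(pg$genotypes, pg$pedigree)
  ph <- phase_parents(mf$genotypes, pg$pedigree)
  tr <- infer_transmissions(mf$genotypes, ph, pg$pedigree)
  bl <- segment_blocks(tr, pg$truth$chrom_lengths)
  for (ch in unique(bl$blocks$chrom)) {
    b <- bl$blocks[bl$blocks$chrom == ch, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], unname(pg$truth$chrom_lengths[ch]))
    if (nrow(b) > 1) expect_equal(b$start[-1], b$end[-nrow(b)])
  }
  # per-(child, block) codes vs truth at the marker nearest each block center
  mk <- mf$genotypes$markers
  total <- 0; good <- 0
  for (bi in seq_len(nrow(bl$blocks))) {
    b <- bl$blocks[bi, ]
    center <- (b$start + b$end) / 2
    sel <- which(mk$chrom == b$chrom)
    near <- sel[which.min(abs(mk$pos[sel] - center))]
    inside <- mk$pos[near] >= b$start && mk$pos[near] < b$end
    if (!inside) next
    for (side in c("paternal", "maternal")) {
      truth <- pg$truth$origins[[side]][mk$id[near], colnames(bl[[side]])]
      codes <- bl[[side]][bi, ]
      ok <- !is.na(codes)
      total <- total + sum(ok)
      good <- good + sum(codes[ok] == truth[ok])
    }
  }
  expect_gt(good / total, 0.99)
})
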