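# Synthetic three-generation pedigree and genotypes.
#
# Grandparental haplotypes are drawn i.i.d. per marker with minor-allele
# frequency Uniform(0.2, 0.5); each meiosis recombines the transmitting
# individual's two haplotypes with Poisson(recomb_rate) crossovers placed
# uniformly over marker intervals. All markers are autosomal.

#' Simulate a three-generation pedigree with genotypes
#'
#' Generates four grandparents, two parents and `n_children` children
#' (17 individuals at the default), biallelic marker genotypes as unphased
#' dosages in \{0, 1, 2\}, and a truth set recording every gamete's
#' grandparental origin and recombination breakpoints.
#'
#' @param config A [sim_config()].
#' @return List with elements `pedigree` (data frame: id, father, mother,
#'   sex, generation), `genotypes` (a `genotype_table`: `$markers` data frame
#'   and `$dosage` marker-by-individual matrix) and `truth` (list with
#'   `origins` — per-side marker-by-child 0/1 matrices, 0 meaning that
#'   parent's grandpaternal haplotype — `breakpoints`, and the phased
#'   parental haplotypes).
#' @export
simulate_pedigree_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(stream_seed(config, "pedigree"), {
    ped <- make_pedigree(config$n_children)
    mk <- make_markers(config)
    n_mark <- nrow(mk)

    # grandparent haplotypes: list id -> matrix [marker, 2] of ALT counts
    gp_ids <- c("gf_p", "gm_p", "gf_m", "gm_m")
    haps <- list()
    for (id in gp_ids) {
      haps[[id]] <- cbind(stats::rbinom(n_mark, 1L, mk$maf),
                          stats::rbinom(n_mark, 1L, mk$maf))
    }

    # parents: haplotype 1 = gamete from their father (grandpaternal anchor),
    # haplotype 2 = gamete from their mother
    father_g1 <- make_gamete(haps[["gf_p"]], mk, config$recomb_rate)
    father_g2 <- make_gamete(haps[["gm_p"]], mk, config$recomb_rate)
    mother_g1 <- make_gamete(haps[["gf_m"]], mk, config$recomb_rate)
    mother_g2 <- make_gamete(haps[["gm_m"]], mk, config$recomb_rate)
    haps[["father"]] <- cbind(father_g1$hap, father_g2$hap)
    haps[["mother"]] <- cbind(mother_g1$hap, mother_g2$hap)

    children <- ped$id[ped$generation == 3L]
    orig_p <- matrix(NA_integer_, n_mark, length(children),
                     dimnames = list(mk$id, children))
    orig_m <- orig_p
    bps <- list()
    for (ch in children) {
      gp <- make_gamete(haps[["father"]], mk, config$recomb_rate)
      gm <- make_gamete(haps[["mother"]], mk, config$recomb_rate)
      haps[[ch]] <- cbind(gp$hap, gm$hap)
      orig_p[, ch] <- gp$origin
      orig_m[, ch] <- gm$origin
      if (nrow(gp$breaks))
        bps[[paste0(ch, "_p")]] <- cbind(child = ch, side = "paternal", gp$breaks)
      if (nrow(gm$breaks))
        bps[[paste0(ch, "_m")]] <- cbind(child = ch, side = "maternal", gm$breaks)
    }
    breakpoints <- if (length(bps)) do.call(rbind, bps) else
      data.frame(child = character(), side = character(),
                 chrom = character(), pos = numeric())
    rownames(breakpoints) <- NULL

    dosage <- vapply(ped$id, function(id) rowSums(haps[[id]]),
                     numeric(n_mark))
    dimnames(dosage) <- list(mk$id, ped$id)
    storage.mode(dosage) <- "integer"

    gt <- structure(list(markers = mk, dosage = dosage),
                    class = "genotype_table")
    truth <- list(
      origins = list(paternal = orig_p, maternal = orig_m),
      breakpoints = breakpoints,
      parent_haplotypes = list(father = haps[["father"]],
                               mother = haps[["mother"]]),
      chrom_lengths = stats::setNames(rep(config$chrom_length,
                                          config$n_chromosomes),
                                      unique(mk$chrom))
    )
    list(pedigree = ped, genotypes = gt, truth = truth)
  })
}

make_pedigree <- function(n_children) {
  kids <- sprintf("child%02d", seq_len(n_children))
  data.frame(
    id = c("gf_p", "gm_p", "gf_m", "gm_m", "father", "mother", kids),
    father = c(NA, NA, NA, NA, "gf_p", "gf_m", rep("father", n_children)),
    mother = c(NA, NA, NA, NA, "gm_p", "gm_m", rep("mother", n_children)),
    sex = c("M", "F", "M", "F", "M", "F",
            sample(c("M", "F"), n_children, replace = TRUE)),
    generation = c(1L, 1L, 1L, 1L, 2L, 2L, rep(3L, n_children)),
    stringsAsFactors = FALSE
  )
}

make_markers <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  out <- lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_length - 1L, config$n_markers_per_chrom))
    data.frame(chrom = ch, pos = pos, ref = "A", alt = "G",
               maf = stats::runif(config$n_markers_per_chrom, 0.2, 0.5),
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, out)
  mk$id <- sprintf("%s_%d", mk$chrom, mk$pos)
  rownames(mk) <- mk$id
  mk
}

# One meiosis: recombine an individual's two haplotypes (columns of `haps`)
# with Poisson(rate) crossovers at uniformly chosen marker boundaries.
# Returns the transmitted haplotype, the per-marker origin (1 or 2 mapped to
# 0/1), and breakpoint midpoints.
make_gamete <- function(haps, markers, rate) {
  n <- nrow(markers)
  origin <- integer(n)
  breaks <- list()
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    m <- length(idx)
    cur <- stats::rbinom(1L, 1L, 0.5)
    o <- rep(cur, m)
    n_x <- stats::rpois(1L, rate)
    n_x <- min(n_x, m - 1L)
    if (n_x > 0L && m > 1L) {
      cut <- sort(sample.int(m - 1L, n_x))  # crossover after marker `cut`
      for (cu in cut) {
        cur <- 1L - cur
        o[(cu + 1L):m] <- cur
        breaks[[length(breaks) + 1L]] <- data.frame(
          chrom = ch,
          pos = (markers$pos[idx[cu]] + markers$pos[idx[cu + 1L]]) / 2
        )
      }
    }
    origin[idx] <- o
  }
  hap <- haps[cbind(seq_len(n), origin + 1L)]
  br <- if (length(breaks)) do.call(rbind, breaks) else
    data.frame(chrom = character(), pos = numeric())
  list(hap = hap, origin = origin, breaks = br)
}
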