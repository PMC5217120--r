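# Pedigree haplotype inference: Mendelian filtering, grandparent-anchored
# parental phasing, per-child transmission inference with majority-vote
# smoothing, and segmentation into haplotype blocks between recombination
# points. Origin code 0 = that parent's grandpaternal haplotype,
# 1 = grandmaternal.

#' Remove markers with Mendelian inconsistencies
#'
#' A marker is dropped if any (child, father, mother) trio shows a child
#' dosage impossible under biallelic transmission from the parental dosages.
#' Missing dosages are treated as compatible.
#'
#' @param genotypes A `genotype_table` (`$markers`, `$dosage`).
#' @param pedigree Pedigree data frame (columns id, father, mother).
#' @return List with `genotypes` (filtered) and `report` (data frame of
#'   dropped marker / child pairs).
#' @export
mendelian_filter <- function(genotypes, pedigree) {
  dos <- genotypes$dosage
  trios <- pedigree[!is.na(pedigree$father) & !is.na(pedigree$mother), ]
  missing_ids <- setdiff(unique(c(trios$id, trios$father, trios$mother)),
                         colnames(dos))
  if (length(missing_ids))
    stop_config("individuals missing from genotypes: %s",
                paste(missing_ids, collapse = ", "))
  # allowed gamete alleles per dosage: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  lo <- function(d) ifelse(d == 0L, 0L, ifelse(d == 1L, 0L, 1L))
  hi <- function(d) ifelse(d == 0L, 0L, 1L)
  bad <- matrix(FALSE, nrow(dos), nrow(trios))
  for (k in seq_len(nrow(trios))) {
    cd <- dos[, trios$id[k]]
    fd <- dos[, trios$father[k]]
    md <- dos[, trios$mother[k]]
    min_c <- lo(fd) + lo(md)
    max_c <- hi(fd) + hi(md)
    bad[, k] <- !is.na(cd) & !is.na(fd) & !is.na(md) &
      (cd < min_c | cd > max_c)
  }
  drop <- rowSums(bad) > 0
  report <- if (any(drop)) {
    idx <- which(bad, arr.ind = TRUE)
    data.frame(marker = rownames(dos)[idx[, 1]],
               child = trios$id[idx[, 2]], stringsAsFactors = FALSE)
  } else data.frame(marker = character(), child = character())
  filtered <- structure(list(markers = genotypes$markers[!drop, , drop = FALSE],
                             dosage = dos[!drop, , drop = FALSE]),
                        class = "genotype_table")
  list(genotypes = filtered, report = report)
}

#' Phase the parents against their own parents
#'
#' At markers where a parent is heterozygous and the grandparental genotypes
#' determine each allele's origin (i.e. not both grandparents heterozygous),
#' assigns the parent's alleles to haplotype 0 (grandpaternal) and haplotype
#' 1 (grandmaternal). Other markers are uninformative.
#'
#' @param genotypes A `genotype_table`.
#' @param pedigree Pedigree data frame; the two generation-2 individuals and
#'   all four grandparents must be present.
#' @return List with one element per parent id: data frame with columns
#'   `hap0`, `hap1` (transmitted ALT counts, NA when uninformative) and
#'   `informative`.
#' @export
phase_parents <- function(genotypes, pedigree) {
  dos <- genotypes$dosage
  parents <- pedigree$id[pedigree$generation == 2L]
  out <- list()
  for (pid in parents) {
    gf <- pedigree$father[pedigree$id == pid]
    gm <- pedigree$mother[pedigree$id == pid]
    if (is.na(gf) || is.na(gm) || !all(c(gf, gm) %in% colnames(dos)))
      stop_config("grandparents of %s not genotyped", pid)
    pd <- dos[, pid]; fd <- dos[, gf]; md <- dos[, gm]
    hap0 <- rep(NA_integer_, length(pd))
    hap1 <- rep(NA_integer_, length(pd))
    het <- !is.na(pd) & pd == 1L & !is.na(fd) & !is.na(md)
    # grandfather homozygous fixes the grandpaternal allele
    sel <- het & fd == 0L & md >= 1L
    hap0[sel] <- 0L; hap1[sel] <- 1L
    sel <- het & fd == 2L & md <= 1L
    hap0[sel] <- 1L; hap1[sel] <- 0L
    # otherwise grandmother homozygous fixes the grandmaternal allele
    sel <- het & fd == 1L & md == 0L
    hap0[sel] <- 1L; hap1[sel] <- 0L
    sel <- het & fd == 1L & md == 2L
    hap0[sel] <- 0L; hap1[sel] <- 1L
    out[[pid]] <- data.frame(hap0 = hap0, hap1 = hap1,
                             informative = !is.na(hap0),
                             row.names = rownames(dos))
  }
  out
}

#' Infer grandparental transmissions per child
#'
#' At each marker informative for a parent, deduces which parental allele the
#' child received (from the child's and the other parent's genotypes;
#' skipped when ambiguous) and maps it to haplotype origin 0/1. Raw calls
#' are smoothed by a sliding majority vote over `w` consecutive informative
#' calls per child/side/chromosome.
#'
#' @param genotypes A `genotype_table`.
#' @param phased Output of [phase_parents()].
#' @param pedigree Pedigree data frame.
#' @param w Odd smoothing window width >= 3 (number of informative calls);
#'   default 3, the smallest window that still removes isolated single-call
#'   artifacts without erasing short double-recombination segments.
#' @return Data frame of class `transmissions` with columns `chrom`, `pos`,
#'   `marker`, `child`, `side`, `origin_raw`, `origin`.
#' @export
infer_transmissions <- function(genotypes, phased, pedigree, w = 3L) {
  if (w < 3L || w %% 2L == 0L) stop_config("w must be odd and >= 3")
  dos <- genotypes$dosage
  mk <- genotypes$markers
  father <- pedigree$id[pedigree$generation == 2L & pedigree$sex == "M"]
  mother <- pedigree$id[pedigree$generation == 2L & pedigree$sex == "F"]
  children <- pedigree$id[pedigree$generation == 3L]
  rows <- list()
  for (side in c("paternal", "maternal")) {
    par <- if (side == "paternal") father else mother
    oth <- if (side == "paternal") mother else father
    ph <- phased[[par]]
    info <- which(ph$informative)
    pd_o <- dos[, oth]
    for (ch in children) {
      cd <- dos[, ch]
      # transmitted allele from `par`, NA when not deducible
      t <- rep(NA_integer_, nrow(dos))
      t[cd == 0L] <- 0L
      t[cd == 2L] <- 1L
      amb <- cd == 1L
      t[amb & pd_o == 0L] <- 1L
      t[amb & pd_o == 2L] <- 0L
      idx <- info[!is.na(t[info])]
      if (!length(idx)) next
      raw <- ifelse(t[idx] == ph$hap0[idx], 0L, 1L)
      sm <- raw
      for (chr in unique(mk$chrom[idx])) {
        sel <- mk$chrom[idx] == chr
        sm[sel] <- majority_smooth(raw[sel], w)
      }
      rows[[paste(side, ch)]] <- data.frame(
        chrom = mk$chrom[idx], pos = mk$pos[idx],
        marker = rownames(dos)[idx], child = ch, side = side,
        origin_raw = raw, origin = sm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("transmissions", class(out))
  attr(out, "children") <- children
  attr(out, "w") <- w
  out
}

# Sliding majority vote over windows of `w` consecutive calls (clamped at the
# ends); ties keep the original call.
majority_smooth <- function(v, w) {
  n <- length(v)
  if (n == 0L) return(v)
  h <- (w - 1L) %/% 2L
  out <- v
  for (i in seq_len(n)) {
    win <- v[max(1L, i - h):min(n, i + h)]
    s <- sum(win)
    if (2L * s > length(win)) out[i] <- 1L
    else if (2L * s < length(win)) out[i] <- 0L
  }
  out
}

#' Segment smoothed transmissions into haplotype blocks
#'
#' Breakpoints are the midpoints between the flanking informative markers of
#' every origin switch, pooled over all children and both parental sides;
#' blocks are the intervals between consecutive breakpoints and the
#' chromosome ends (0-based half-open). Per-child paternal/maternal codes
#' are the constant origins within each block (nearest-call fill when a
#' child has no informative marker inside a block).
#'
#' @param transmissions A `transmissions` data frame.
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   last informative position + 1 per chromosome.
#' @return A `haplotype_blocks` object: list with `blocks` (data frame:
#'   block, chrom, start, end, n_informative per side), `paternal` and
#'   `maternal` (block x child 0/1 code matrices).
#' @export
segment_blocks <- function(transmissions, chrom_lengths = NULL) {
  tr <- transmissions
  children <- attr(tr, "children") %||% sort(unique(tr$child))
  chroms <- unique(tr$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      max(tr$pos[tr$chrom == ch]) + 1, numeric(1))
  }
  blocks <- list(); pat <- list(); mat <- list()
  bid <- 0L
  for (ch in chroms) {
    sub <- tr[tr$chrom == ch, ]
    bps <- numeric(0)
    for (key in split(sub, paste(sub$child, sub$side))) {
      key <- key[order(key$pos), ]
      if (nrow(key) < 2L) next
      sw <- which(diff(key$origin) != 0L)
      if (length(sw))
        bps <- c(bps, (key$pos[sw] + key$pos[sw + 1L]) / 2)
    }
    bps <- sort(unique(bps))
    edges <- c(0, bps, chrom_lengths[[ch]])
    for (b in seq_len(length(edges) - 1L)) {
      bid <- bid + 1L
      s <- edges[b]; e <- edges[b + 1L]
      inb <- sub[sub$pos >= s & sub$pos < e, ]
      codes <- list(paternal = rep(NA_integer_, length(children)),
                    maternal = rep(NA_integer_, length(children)))
      n_inf <- c(paternal = 0L, maternal = 0L)
      for (side in c("paternal", "maternal")) {
        ss <- inb[inb$side == side, ]
        n_inf[side] <- nrow(ss)
        for (ci in seq_along(children)) {
          v <- ss$origin[ss$child == children[ci]]
          if (length(v)) {
            if (length(unique(v)) > 1L)
              stop_config("internal error: child %s switches %s origin inside block %d",
                          children[ci], side, bid)
            codes[[side]][ci] <- v[1]
          } else {
            # nearest informative call on either flank
            sc <- sub[sub$side == side & sub$child == children[ci], ]
            if (nrow(sc)) {
              d <- pmin(abs(sc$pos - s), abs(sc$pos - e))
              codes[[side]][ci] <- sc$origin[which.min(d)]
            }
          }
        }
      }
      blocks[[bid]] <- data.frame(block = sprintf("block_%04d", bid),
                                  chrom = ch, start = s, end = e,
                                  n_informative_paternal = n_inf[["paternal"]],
                                  n_informative_maternal = n_inf[["maternal"]],
                                  stringsAsFactors = FALSE)
      pat[[bid]] <- codes$paternal
      mat[[bid]] <- codes$maternal
    }
  }
  btab <- do.call(rbind, blocks)
  rownames(btab) <- NULL
  pmat <- do.call(rbind, pat)
  mmat <- do.call(rbind, mat)
  dimnames(pmat) <- dimnames(mmat) <- list(btab$block, children)
  structure(list(blocks = btab, paternal = pmat, maternal = mmat),
            class = "haplotype_blocks")
}

#' @exportS3Method base::print
print.haplotype_blocks <- function(x, ...) {
  cat(sprintf("haplotype_blocks: %d blocks over %d chromosomes, %d children\n",
              nrow(x$blocks), length(unique(x$blocks$chrom)),
              ncol(x$paternal)))
  invisible(x)
}

#' Write haplotype blocks as BED plus a per-child code table
#' @param blocks A `haplotype_blocks` object.
#' @param bed_path BED output (0-based half-open).
#' @param codes_path TSV output of per-child paternal/maternal codes.
#' @return Invisibly, the two paths.
#' @export
write_blocks <- function(blocks, bed_path, codes_path) {
  b <- blocks$blocks
  writeLines(sprintf("%s\t%d\t%d\t%s", b$chrom, as.integer(b$start),
                     as.integer(b$end), b$block), bed_path)
  codes <- data.frame(block = rep(b$block, 2),
                      side = rep(c("paternal", "maternal"), each = nrow(b)),
                      rbind(blocks$paternal, blocks$maternal),
                      check.names = FALSE)
  utils::write.table(codes, codes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed_path, codes_path))
}
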