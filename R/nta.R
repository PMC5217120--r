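# Nontemplated nucleotide addition (NTA) profiling from hairpin-local
# alignments: soft-clipped bases in the CIGAR are the candidate tails
# (leading clip = 5' on forward-aligned reads, trailing clip = 3').
# Labels are normalized as "-XY" (3') and "XY-" (5'), bases uppercased.

#' Extract NTAs from a SAM/BAM file
#'
#' Reads with fewer than `min_aligned` matched bases are skipped, as are
#' reverse-strand and unmapped records (hairpins are single-stranded
#' references). Reads without soft clips count toward the aligned total as
#' NTA-free. A read clipped on both ends contributes one record per side.
#'
#' @param path SAM or BAM file of hairpin-local alignments.
#' @param min_aligned Minimum total matched length (default 16).
#' @return List of class `nta_records`: `records` (data frame hairpin, side,
#'   nta, count), `total_aligned`, `nta_free`, `n_skipped_short`,
#'   `n_skipped_other`.
#' @export
extract_ntas <- function(path, min_aligned = 16L) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  }
  x <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar", "seq")))[[1]]
  flag <- x$flag
  cigar <- x$cigar
  seqs <- as.character(x$seq)
  rname <- as.character(x$rname)

  unmapped <- bitwAnd(flag, 4L) != 0L
  reverse <- bitwAnd(flag, 16L) != 0L
  no_cigar <- is.na(cigar) | cigar == "*"
  keep <- !unmapped & !reverse & !no_cigar
  n_skipped_other <- sum(!keep)

  ops <- lapply(cigar[keep], parse_cigar)
  matched <- vapply(ops, function(o) sum(o$len[o$op %in% c("M", "=", "X")]),
                    numeric(1))
  long_enough <- matched >= min_aligned
  n_skipped_short <- sum(!long_enough)

  recs <- list()
  nta_free <- 0L
  idx <- which(keep)[long_enough]
  ops <- ops[long_enough]
  for (j in seq_along(idx)) {
    o <- ops[[j]]
    i <- idx[j]
    lead <- if (o$op[1] == "S") o$len[1] else 0L
    trail <- if (o$op[length(o$op)] == "S" && length(o$op) > 1L)
      o$len[length(o$op)] else 0L
    if (lead == 0L && trail == 0L) { nta_free <- nta_free + 1L; next }
    if (lead > 0L) {
      clip <- toupper(substr(seqs[i], 1L, lead))
      recs[[length(recs) + 1L]] <- c(rname[i], "5p", paste0(clip, "-"))
    }
    if (trail > 0L) {
      len <- nchar(seqs[i])
      clip <- toupper(substr(seqs[i], len - trail + 1L, len))
      recs[[length(recs) + 1L]] <- c(rname[i], "3p", paste0("-", clip))
    }
  }
  records <- if (length(recs)) {
    m <- do.call(rbind, recs)
    agg <- stats::aggregate(list(count = rep(1L, nrow(m))),
                            by = list(hairpin = m[, 1], side = m[, 2],
                                      nta = m[, 3]), FUN = sum)
    agg[order(agg$hairpin, agg$side, agg$nta), ]
  } else data.frame(hairpin = character(), side = character(),
                    nta = character(), count = integer())
  rownames(records) <- NULL
  structure(list(records = records, total_aligned = length(idx),
                 nta_free = nta_free, n_skipped_short = n_skipped_short,
                 n_skipped_other = n_skipped_other),
            class = "nta_records")
}

parse_cigar <- function(cig) {
  len <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  op <- regmatches(cig, gregexpr("[A-Z=]", cig))[[1]]
  list(op = op, len = len)
}

#' NTA frequency profile of one sample
#'
#' Per NTA label of length <= `max_len`: 100 x (reads with that NTA) /
#' (total aligned reads). Longer clips are tallied under `"other"`; the
#' NTA-free percentage is also reported.
#'
#' @param ntas An `nta_records` object from [extract_ntas()].
#' @param max_len Maximum tail length reported individually (default 2).
#' @param sides Sides included (default 3' only, the headline analysis; use
#'   `c("3p","5p")` for both).
#' @return List of class `nta_profile`: `percent` (named vector per label),
#'   `nta_free_percent`, `other_percent`, `total_aligned`, `records`.
#' @export
nta_frequency_table <- function(ntas, max_len = 2L, sides = "3p") {
  stopifnot(inherits(ntas, "nta_records"))
  if (ntas$total_aligned == 0L) stop_config("zero aligned reads")
  rec <- ntas$records[ntas$records$side %in% sides, , drop = FALSE]
  tail_len <- nchar(gsub("-", "", rec$nta))
  short <- tail_len <= max_len
  pct <- if (any(short))
    100 * vapply(split(rec$count[short], rec$nta[short]), sum, numeric(1)) /
      ntas$total_aligned
  else stats::setNames(numeric(0), character(0))
  other <- 100 * sum(rec$count[!short]) / ntas$total_aligned
  structure(list(percent = pct,
                 nta_free_percent = 100 * ntas$nta_free / ntas$total_aligned,
                 other_percent = other,
                 total_aligned = ntas$total_aligned,
                 sides = sides,
                 records = rec),
            class = "nta_profile")
}

#' Per-hairpin contribution to one NTA
#'
#' 100 x (hairpin's reads with the NTA) / (all reads with the NTA).
#'
#' @param ntas An `nta_records` object.
#' @param nta NTA label (e.g. `"-A"`).
#' @return Named numeric vector of percentages summing to 100.
#' @export
nta_hairpin_contribution <- function(ntas, nta) {
  stopifnot(inherits(ntas, "nta_records"))
  rec <- ntas$records[ntas$records$nta == nta, , drop = FALSE]
  if (!nrow(rec)) stop_config("NTA '%s' absent from records", nta)
  tot <- sum(rec$count)
  out <- 100 * vapply(split(rec$count, rec$hairpin), sum, numeric(1)) / tot
  sort(out, decreasing = TRUE)
}

#' Compare NTA frequencies between compartments
#'
#' Paired two-sided t-test per NTA label on per-sample percentages across
#' individuals, BH-adjusted, plus a driver diagnostic: the largest single-
#' hairpin contribution share per compartment for each label (a high share
#' means a few abundant hairpins drive the compartment difference).
#'
#' @param cell_profiles,exosome_profiles Named lists (individual ->
#'   `nta_profile`), same individuals in both.
#' @return Data frame per label: mean percentages, t, raw and BH-adjusted p,
#'   top-hairpin contribution share per compartment.
#' @export
compare_nta_between_compartments <- function(cell_profiles, exosome_profiles) {
  ind <- names(cell_profiles)
  if (!setequal(ind, names(exosome_profiles)))
    stop_config("unpaired individuals between compartments")
  ind <- sort(ind)
  labels <- sort(unique(c(
    unlist(lapply(cell_profiles, function(p) names(p$percent))),
    unlist(lapply(exosome_profiles, function(p) names(p$percent))))))
  get_pct <- function(profiles, lab)
    vapply(profiles[ind], function(p) {
      v <- p$percent[lab]
      if (is.na(v)) 0 else unname(v)
    }, numeric(1))
  top_share <- function(profiles, lab) {
    rec <- do.call(rbind, lapply(profiles[ind], function(p)
      p$records[p$records$nta == lab, , drop = FALSE]))
    if (is.null(rec) || !nrow(rec)) return(NA_real_)
    by_hp <- vapply(split(rec$count, rec$hairpin), sum, numeric(1))
    100 * max(by_hp) / sum(by_hp)
  }
  rows <- lapply(labels, function(lab) {
    vc <- get_pct(cell_profiles, lab)
    ve <- get_pct(exosome_profiles, lab)
    d <- vc - ve
    if (stats::sd(d) < .Machine$double.eps^0.5) {
      t <- if (all(abs(d) < .Machine$double.eps^0.5)) 0 else NA_real_
      p <- NA_real_
    } else {
      tt <- stats::t.test(vc, ve, paired = TRUE)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(nta = lab, mean_cell = mean(vc), mean_exosome = mean(ve),
               t = t, p = p,
               top_hairpin_share_cell = top_share(cell_profiles, lab),
               top_hairpin_share_exosome = top_share(exosome_profiles, lab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
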