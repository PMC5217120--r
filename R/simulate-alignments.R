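# Synthetic hairpin-local alignments (SAM) and unmapped reads (FASTQ) for
# the NTA profiler and the k-mer QC stage. Reads are hairpin substrings of at
# least 16 matched bases; nontemplated tails are encoded as soft clips in the
# CIGAR (e.g. 20M2S for a 2-nt 3' tail). A read carries at most one tail.

#' Simulate hairpin-local alignments and unmapped reads
#'
#' @param config A [sim_config()]; `nta_rates` gives per-read tail
#'   probabilities ("-XY" = 3' tail, "XY-" = 5' tail, 1-2 nt).
#' @param kmer_rate Per-read probability that an unmapped read carries the
#'   planted 10-mer (defaults to `config$planted_kmer_rate`); vary it between
#'   samples to emulate group-dependent technical contamination.
#' @param seed_offset Integer added to the alignment stream seed so distinct
#'   samples get distinct reads.
#' @return List with `sam` (character vector of SAM lines incl. header),
#'   `hairpins` (named character vector of hairpin sequences), `unmapped`
#'   (character vector of unmapped read sequences), and `truth` (data frame
#'   of planted per-hairpin/side/NTA counts plus attributes `total_aligned`
#'   and `nta_free`).
#' @export
simulate_hairpin_alignments <- function(config, kmer_rate = NULL,
                                        seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  kmer_rate <- kmer_rate %||% config$planted_kmer_rate
  with_seed((stream_seed(config, "alignments") + seed_offset) %%
              .Machine$integer.max, {
    n_hp <- config$n_aln_hairpins
    hp_names <- sprintf("hp-mir-%02d", seq_len(n_hp))
    hp_len <- 70L
    hairpins <- vapply(hp_names, function(x)
      paste(sample(c("A", "C", "G", "T"), hp_len, replace = TRUE),
            collapse = ""), character(1))

    n_reads <- config$n_aln_reads
    # uneven hairpin abundance (first hairpin dominant) so contribution
    # analyses see realistic skew
    w <- c(8, rep(1, n_hp - 1L))
    hp_of <- sample(hp_names, n_reads, replace = TRUE, prob = w / sum(w))

    rates <- config$nta_rates
    labels <- c(names(rates), "")
    probs <- c(rates, 1 - sum(rates))
    tail_of <- sample(labels, n_reads, replace = TRUE, prob = probs)

    rec <- character(n_reads)
    truth_key <- character(n_reads)
    for (i in seq_len(n_reads)) {
      mlen <- sample(18:24, 1L)
      start <- sample.int(hp_len - mlen + 1L, 1L)
      core <- substr(hairpins[[hp_of[i]]], start, start + mlen - 1L)
      tl <- tail_of[i]
      if (tl == "") {
        seq <- core
        cigar <- sprintf("%dM", mlen)
      } else if (startsWith(tl, "-")) {       # 3' tail
        bases <- sub("^-", "", tl)
        seq <- paste0(core, bases)
        cigar <- sprintf("%dM%dS", mlen, nchar(bases))
      } else {                                # 5' tail
        bases <- sub("-$", "", tl)
        seq <- paste0(bases, core)
        cigar <- sprintf("%dS%dM", nchar(bases), mlen)
      }
      truth_key[i] <- paste(hp_of[i], tl, sep = "\r")
      rec[i] <- paste(sprintf("read%05d", i), 0L, hp_of[i], start, 255L,
                      cigar, "*", 0L, 0L, seq,
                      strrep("I", nchar(seq)), sep = "\t")
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", hp_names, hp_len))

    tallied <- table(truth_key[tail_of != ""])
    if (length(tallied)) {
      parts <- strsplit(names(tallied), "\r", fixed = TRUE)
      truth <- data.frame(
        hairpin = vapply(parts, `[`, character(1), 1L),
        nta = vapply(parts, `[`, character(1), 2L),
        count = as.integer(tallied),
        stringsAsFactors = FALSE
      )
      truth$side <- ifelse(startsWith(truth$nta, "-"), "3p", "5p")
    } else {
      truth <- data.frame(hairpin = character(), nta = character(),
                          count = integer(), side = character())
    }
    attr(truth, "total_aligned") <- n_reads
    attr(truth, "nta_free") <- sum(tail_of == "")

    unmapped <- vapply(seq_len(config$n_unmapped_reads), function(i) paste(
      sample(c("A", "C", "G", "T"), 30L, replace = TRUE), collapse = ""),
      character(1))
    plant <- stats::runif(config$n_unmapped_reads) < kmer_rate
    if (any(plant)) {
      k <- nchar(config$planted_kmer)
      at <- sample.int(30L - k + 1L, sum(plant), replace = TRUE)
      unmapped[plant] <- mapply(function(s, a) {
        paste0(substr(s, 1L, a - 1L), config$planted_kmer,
               substr(s, a + k, 30L))
      }, unmapped[plant], at, USE.NAMES = FALSE)
    }

    list(sam = c(header, rec), hairpins = hairpins,
         unmapped = unname(unmapped), truth = truth)
  })
}

#' Write SAM lines to a file
#' @param sam Character vector of SAM lines (with header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  writeLines(sam, path)
  invisible(path)
}

#' Write reads as FASTQ
#' @param reads Character vector of sequences.
#' @param path Output path.
#' @param ids Optional read names.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% sprintf("unmapped%05d", seq_along(reads))
  out <- character(4L * length(reads))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- reads
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- strrep("I", nchar(reads))
  writeLines(out, path)
  invisible(path)
}

#' Read sequences from a FASTQ file
#' @param path FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}
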