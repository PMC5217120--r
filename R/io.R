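# Plain-text I/O: genotypes as VCFv4.2 / TSV, counts as TSV, truth as JSON.

#' Write genotypes as VCFv4.2
#'
#' Unphased GT field ("0/1" style); dosage 1 is written as 0/1.
#'
#' @param genotypes A `genotype_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  mk <- genotypes$markers
  dos <- genotypes$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Biallelic records only; GT parsed to dosage in \{0, 1, 2\} (NA for
#' missing).
#'
#' @param path VCF file.
#' @return A `genotype_table`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) stop_config("multiallelic records not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  to_dosage <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  dos <- apply(gt, 2L, to_dosage)
  mk <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   id = ifelse(is.na(fix$ID) | fix$ID == ".",
                               sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID),
                   stringsAsFactors = FALSE)
  rownames(mk) <- mk$id
  dimnames(dos) <- list(mk$id, colnames(gt))
  structure(list(markers = mk, dosage = dos), class = "genotype_table")
}

#' Write genotypes as TSV
#' @param genotypes A `genotype_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  out <- cbind(genotypes$markers[, c("chrom", "pos", "id", "ref", "alt")],
               as.data.frame(genotypes$dosage))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from TSV (as written by [write_genotypes_tsv()])
#' @param path TSV file.
#' @return A `genotype_table`.
#' @export
read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("chrom", "pos", "id", "ref", "alt")
  mk <- tab[, meta_cols]
  rownames(mk) <- mk$id
  dos <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  rownames(dos) <- mk$id
  storage.mode(dos) <- "integer"
  structure(list(markers = mk, dosage = dos), class = "genotype_table")
}

#' Write a count matrix as TSV (rows = transcripts, columns = samples)
#' @param counts A [count_matrix()].
#' @param path Counts TSV path.
#' @param meta_path Optional sample-metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, meta_path = NULL) {
  out <- data.frame(transcript = rownames(counts$counts),
                    counts$counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(counts$samples, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#' @param path Counts TSV (first column `transcript`).
#' @param meta Sample metadata data frame or TSV path.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, meta) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab[[1]]
  if (is.character(meta))
    meta <- utils::read.table(meta, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  count_matrix(x, meta)
}

#' Write the simulation truth set as JSON
#' @param truth Truth list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}
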