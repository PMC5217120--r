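#' Simulation configuration
#'
#' Parameters of the synthetic study: a three-generation family (four
#' grandparents, two parents, eleven children) with paired cell and exosome
#' small-RNA libraries for all 17 members, biallelic autosomal markers with
#' recombination in the parental meioses, negative-binomial counts carrying a
#' massively exported miRNA cluster and haplotype-driven cis effects, and
#' hairpin-local alignments with nontemplated 3'/5' tails.
#'
#' @param n_children Number of children (default 11, giving a 17-member
#'   pedigree).
#' @param n_chromosomes Number of autosomes simulated.
#' @param n_markers_per_chrom Biallelic markers per chromosome.
#' @param chrom_length Chromosome length in bp; markers and transcripts are
#'   placed uniformly within it.
#' @param recomb_rate Expected crossovers per meiosis per chromosome
#'   (Poisson mean).
#' @param n_mirnas Number of miRNA hairpins (each yields one or two matures).
#' @param n_pirnas Number of piRNA transcripts.
#' @param n_other_per_class Transcripts per remaining biotype class
#'   (lincRNA, misc, rRNA, snoRNA).
#' @param exported_cluster_size Hairpins in the planted exported cluster
#'   (must be >= 2).
#' @param exported_cluster_lfc log2 fold change (exosome vs cell) of the
#'   exported cluster members.
#' @param frac_de Fraction of non-cluster transcripts given a random
#'   compartment effect.
#' @param de_lfc_sd Standard deviation of those random log2 fold changes.
#' @param n_eqtl_mirnas Number of mature miRNAs given a haplotype cis effect.
#' @param eqtl_beta Paternal-haplotype effect size on the natural-log scale.
#' @param eqtl_beta_m Maternal-haplotype effect size (default 0).
#' @param nb_dispersion_cell,nb_dispersion_exosome Negative-binomial
#'   dispersion alpha (Var = mu + alpha mu^2) per compartment; the exosome
#'   dispersion must not be smaller than the cell dispersion by default,
#'   emulating the greater between-exosome variability.
#' @param library_size_range Length-2 integer vector of total expected reads
#'   per library.
#' @param nta_rates Named numeric vector of per-read tail probabilities; names
#'   are 1-2 nt strings prefixed with "-" for 3' tails (e.g. "-A", "-AG") or
#'   suffixed with "-" for 5' tails (e.g. "T-"). Probabilities must sum to
#'   <= 1 (a read carries at most one tail).
#' @param n_aln_hairpins Hairpins used for the alignment simulation.
#' @param n_aln_reads Aligned reads per simulated sample.
#' @param n_unmapped_reads Unmapped reads per simulated sample.
#' @param planted_kmer 10-mer planted in unmapped reads for the k-mer QC.
#' @param planted_kmer_rate Per-read probability of carrying the planted
#'   10-mer.
#' @param seed Integer master seed; all per-artifact streams derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_children = 11L,
                       n_chromosomes = 4L,
                       n_markers_per_chrom = 800L,
                       chrom_length = 1e8,
                       recomb_rate = 1,
                       n_mirnas = 120L,
                       n_pirnas = 80L,
                       n_other_per_class = 8L,
                       exported_cluster_size = 5L,
                       exported_cluster_lfc = 10,
                       frac_de = 0.3,
                       de_lfc_sd = 2,
                       n_eqtl_mirnas = 4L,
                       eqtl_beta = 2,
                       eqtl_beta_m = 0,
                       nb_dispersion_cell = 0.1,
                       nb_dispersion_exosome = 0.3,
                       library_size_range = c(5e5, 2e6),
                       nta_rates = c("-A" = 0.10, "-T" = 0.04, "-AG" = 0.02, "T-" = 0.02),
                       n_aln_hairpins = 10L,
                       n_aln_reads = 2000L,
                       n_unmapped_reads = 400L,
                       planted_kmer = "ATCGGTACAA",
                       planted_kmer_rate = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_children = as.integer(n_children),
    n_chromosomes = as.integer(n_chromosomes),
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    chrom_length = chrom_length,
    recomb_rate = recomb_rate,
    n_mirnas = as.integer(n_mirnas),
    n_pirnas = as.integer(n_pirnas),
    n_other_per_class = as.integer(n_other_per_class),
    exported_cluster_size = as.integer(exported_cluster_size),
    exported_cluster_lfc = exported_cluster_lfc,
    frac_de = frac_de,
    de_lfc_sd = de_lfc_sd,
    n_eqtl_mirnas = as.integer(n_eqtl_mirnas),
    eqtl_beta = eqtl_beta,
    eqtl_beta_m = eqtl_beta_m,
    nb_dispersion_cell = nb_dispersion_cell,
    nb_dispersion_exosome = nb_dispersion_exosome,
    library_size_range = library_size_range,
    nta_rates = nta_rates,
    n_aln_hairpins = as.integer(n_aln_hairpins),
    n_aln_reads = as.integer(n_aln_reads),
    n_unmapped_reads = as.integer(n_unmapped_reads),
    planted_kmer = planted_kmer,
    planted_kmer_rate = planted_kmer_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_children < 1L) stop_config("n_children must be positive")
  if (cfg$n_markers_per_chrom < 1L) stop_config("n_markers_per_chrom must be positive")
  if (cfg$n_chromosomes < 1L) stop_config("n_chromosomes must be positive")
  if (cfg$recomb_rate < 0) stop_config("recomb_rate must be >= 0")
  if (cfg$exported_cluster_size < 2L) stop_config("exported_cluster_size must be >= 2")
  if (cfg$nb_dispersion_cell <= 0 || cfg$nb_dispersion_exosome <= 0)
    stop_config("NB dispersions must be > 0")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop_config("frac_de must be in [0,1]")
  if (length(cfg$library_size_range) != 2L || any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop_config("library_size_range must be an increasing positive pair")
  if (length(cfg$nta_rates)) {
    nm <- names(cfg$nta_rates)
    if (is.null(nm) || any(nm == ""))
      stop_config("nta_rates must be a named vector")
    bases <- gsub("-", "", nm)
    three <- startsWith(nm, "-")
    five <- endsWith(nm, "-")
    if (any(!(three | five)) || any(three & five))
      stop_config("nta_rates names must be '-XY' (3') or 'XY-' (5')")
    if (any(nchar(bases) < 1L | nchar(bases) > 2L))
      stop_config("NTA tails must be 1-2 nt")
    if (any(!strsplit(paste(bases, collapse = ""), "")[[1]] %in% c("A", "C", "G", "T")))
      stop_config("NTA tails must be ACGT strings")
    if (any(cfg$nta_rates < 0) || sum(cfg$nta_rates) > 1)
      stop_config("nta_rates must be probabilities summing to <= 1")
  }
  if (cfg$planted_kmer_rate < 0 || cfg$planted_kmer_rate > 1)
    stop_config("planted_kmer_rate must be in [0,1]")
  if (cfg$seed < 0 || cfg$seed > .Machine$integer.max - 1000L)
    stop_config("seed out of range")
  invisible(cfg)
}

# Derived sub-stream seeds so each artifact has its own reproducible stream.
stream_seed <- function(cfg, what) {
  offs <- c(pedigree = 101L, annotation = 211L, counts = 307L,
            alignments = 401L, unmapped = 503L)
  if (!what %in% names(offs)) stop_config("unknown RNG stream '%s'", what)
  (cfg$seed + offs[[what]]) %% .Machine$integer.max
}
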