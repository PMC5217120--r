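---
title: "Methods: cell versus exosome small RNA analysis in a three-generation family"
author: "exosmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell versus exosome small RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exosmir)
```

# The study design

`exosmir` analyzes paired small-RNA sequencing libraries from the
lymphoblastoid cell lines and secreted exosomes of a 17-member,
three-generation family: four grandparents, two parents and eleven children,
each contributing one cell and one exosome library (34 samples). The family
design is what makes the genetics tractable at this sample size: with both
parents and all four grandparents genotyped, each child's expression can be
regressed on *which grandparental haplotype* it inherited from each parent,
rather than on population-frequency variants that eleven children could
never power.

The package implements each analysis stage as ordinary R functions (the
`analysis/` scripts are thin drivers over them) and ships a synthetic-data
generator so that the entire pipeline runs end-to-end, deterministically,
with no external data.

# Models and procedures

## Genomic miRNA clusters

An miRNA cluster is the single-linkage connected component of hairpins on
the same chromosome in which every member lies within `max_gap` (default
10 kb) of at least one other member. `build_clusters()` measures the gap
between hairpin *intervals* — `max(0, laterStart − earlierEnd)` — the most
permissive reading consistent with hairpins being extended loci; a
midpoint-distance convention can be emulated by adjusting `max_gap`. Strand
is ignored by default (large natural clusters are co-stranded anyway);
`by_strand = TRUE` splits components per strand. Cluster-level counts are
the per-sample sums of member matures' counts, excluding matures derivable
from hairpins in more than one cluster (`EXCLUDED_MULTI_CLUSTER`), so a
singleton hairpin's cluster counts equal its mature counts exactly.
Internally all coordinates are 0-based half-open; GFF3 I/O converts from the
1-based inclusive convention.

## Biotype composition

Per-sample proportions are computed over the six classes (lincRNA, miRNA,
misc, piRNA, rRNA, snoRNA), closing the composition over those classes
(other annotations are dropped before normalization). Compartments are
compared per class with a paired two-sided t-test (pairing on individual),
Bonferroni-corrected over the six tests. Classes whose paired differences
have zero variance are reported `p = NA` with a `degenerate` flag rather
than forcing a p-value from an undefined t statistic.

## Differential expression

The engine is a deliberately simplified negative-binomial Wald test:

* size factors by median-of-ratios against the geometric-mean reference
  (rows with any zero are excluded from the reference, as usual);
* per-transcript dispersion by within-group method-of-moments on normalized
  counts, $\hat\alpha = (s^2 - \bar x)/\bar x^2$ averaged over the two
  compartments and floored at $10^{-8}$ — no empirical-Bayes shrinkage;
* an NB log-link GLM per transcript with the log size factor as offset and
  the compartment (plus optional categorical covariates such as sequencing
  run) as predictors, with a Wald test on the compartment coefficient;
* Benjamini–Hochberg adjustment over tested transcripts (all-zero
  transcripts are excluded from testing and from the BH denominator);
* no independent filtering: every nonzero transcript is tested.

Fold changes are oriented exosome over cell. When the GLM is degenerate
(typically a compartment with all-zero counts, as for a massively exported
cluster on the cell side), the engine falls back to a Wald test on the
difference of log group means with a half-count floor and delta-method
variance $(1/\mu + \alpha)/n$; the `engine` column records which path
produced each row. A covariate fully confounded with the compartment (the
one-lane-per-compartment scenario) is refused with an error.

Because dispersion estimation and filtering differ from shrinkage-based
engines, exact differentially-expressed counts on real data will differ
from such engines; the simplified engine is validated here by simulation
(type-I error calibration and planted-effect recovery) rather than by
numerical replication.

## Interindividual variability

Spearman correlation (average ranks for ties) between all sample pairs of a
biotype's normalized expression; hierarchical clustering with average
linkage on $1-\rho$; and a comparison of the $17 \cdot 16/2 = 136$
within-cell pairwise correlations against the 136 within-exosome ones with
a two-sided Wilcoxon rank-sum test (exact when both groups have at most 12
tie-free values, normal approximation with continuity correction
otherwise). The pairwise correlations share samples and are therefore
dependent; the test is reported as-is, as a descriptive statistic, and the
result object carries that caveat.

## Pedigree haplotypes

Four steps, all operating on unphased dosages in {0, 1, 2}:

1. **Mendelian filter** — a marker is dropped if any (child, father,
   mother) trio shows an impossible child dosage; missing genotypes are
   treated as compatible, never imputed.
2. **Parental phasing** — at markers where a parent is heterozygous and not
   both of its parents are, each allele is anchored to the grandpaternal
   (code 0) or grandmaternal (code 1) haplotype. The anchoring is arbitrary
   but fixed; all downstream fits are invariant to flipping any block's
   encoding (a tested property).
3. **Transmission inference** — at each informative marker the transmitted
   parental allele is deduced from the child's and the other parent's
   genotypes (skipped when ambiguous) and mapped to origin 0/1. Raw calls
   are smoothed by a sliding majority vote over `w` consecutive informative
   calls. The default is `w = 3`: a `w`-wide vote erases any true segment
   shorter than `ceiling(w/2)` informative calls, and short
   double-crossover segments are real, so the window is kept at the
   smallest width that still removes isolated single-call artifacts.
   Larger windows are appropriate when genotyping error is a bigger concern
   than resolution.
4. **Block segmentation** — breakpoints are the midpoints between the
   flanking informative markers of every origin switch, pooled over all
   children and both sides; blocks are the intervals between consecutive
   breakpoints (0-based half-open, tiling each chromosome). Children
   without an informative call inside a small block inherit the nearest
   call.

## cis-eQTL mapping

For each transcript passing the filters, expression of the eleven children
is regressed on the haplotype codes of the block containing the
transcript's locus midpoint (for matures, the parent hairpin's midpoint):

$$\log(Y_i + 1) \sim \mu + \beta_p\, p_i + \beta_m\, m_i$$

with $p_i, m_i \in \{0, 1\}$ the paternal and maternal codes. The natural
log is used; switching the base rescales the betas and changes nothing
else (a tested property). The model fit $R^2$ yields the p-value via the
overall F-test, $F = (R^2/k) / ((1-R^2)/(n-k-1))$ with $k$ the number of
non-degenerate regressors — a regressor constant across the children is
dropped, and with both constant the transcript is untestable. For $k = 2$,
$n = 11$ the F survival function has the closed form
$p = (1 + 2F/8)^{-4}$, so e.g. $R^2 = 0.5 \Rightarrow F = 4 \Rightarrow
p = 1/16$; the test suite pins this exactly.

Filters: median size-factor-normalized expression over the children of at
least `min_median = 10` in the tested compartment (size factors computed
from that compartment's 17 samples, children subset afterwards);
multi-locus transcripts excluded; transcripts whose interval contains a
retained variant excluded (short-read mapping bias). BH q-values are
computed within compartment; sharing is assessed by the Pearson correlation
of effect sizes across compartments and by intersecting the per-compartment
eQTLs at 20% FDR.

Three confounder checks accompany a shared candidate: a Fisher exact test
of block codes against child sex; a genome-wide trans scan ranking every
block by its number of transcripts associated at nominal $p \le 0.05$ (a
top-ranked block suggests correlation with a technical factor); and a
k-mer mapping-bias check — 10-mers counted in each child's unmapped reads,
normalized by total sequenced reads, each sufficiently prevalent k-mer
tested with a one-sided Wilcoxon rank-sum between haplotype groups in the
direction *opposing* the eQTL effect. Only k-mers present in at least half
the children are tested (rank tests on all-zero vectors are meaningless;
the floor is configurable). Note that the verdict uses nominal
$p \le 0.05$, so when tens of k-mers pass the prevalence floor, roughly 5%
nominal hits are expected even without any bias; the per-k-mer table is
returned so users can judge hits against that expectation.

## Nontemplated nucleotide additions

NTAs are read off the CIGAR strings of hairpin-local alignments: a leading
soft clip on a forward-aligned read is a 5′ addition (label `XY-`), a
trailing clip a 3′ addition (label `-XY`), with clipped bases taken from the
read and uppercased. Reads with fewer than `min_aligned = 16` matched bases
and reverse-strand records are skipped (hairpins are single-stranded
references); clip-free reads count as NTA-free. Frequencies are percentages
of all aligned reads per label (1–2 nt labels individually, longer clips
pooled as "other"); per-hairpin contributions for a label sum to 100%. 5′
and 3′ streams are kept separate end-to-end; headline tables use 3′ only.
Compartments are compared per label with a paired two-sided t-test across
individuals (BH-adjusted), together with a driver diagnostic: the largest
single-hairpin contribution share per compartment, which reveals when a
compartment difference is carried by a few abundant hairpins rather than a
broad shift. A read clipped on both ends contributes one event per side, so
event percentages are reported (a flag to count reads once would only
matter for double-clipped reads, which the generator never emits — its
percentage conservation tests rely on that).

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and were fixed while designing the generator, not adjusted
afterwards:

* **Pedigree and genotypes.** 4 + 2 + 11 individuals; four autosomes of
  100 Mb with 800 biallelic markers each (a computational scale-down of WGS
  variant density chosen so haplotype blocks stay densely covered by
  informative markers); minor-allele frequencies Uniform(0.2, 0.5) so
  parents are frequently heterozygous and phasing is informative;
  Poisson(1) crossovers per meiosis per chromosome placed uniformly over
  distinct marker intervals, independently per meiosis (no interference).
  Sex chromosomes are not simulated; the sex-confounding check is a
  covariate test, not X genetics.
* **Counts.** 34 libraries with totals Uniform(5×10⁵, 2×10⁶) reads.
  Transcript abundances are lognormal; each transcript's mean is
  `library × share × 2^(LFC·I[exosome]) × exp(β_p p + β_m m)` with NB noise
  of dispersion α = 0.1 in cells and 0.3 in exosomes (Var = μ + αμ²) — the
  exosome side is noisier by construction, reproducing the greater
  between-exosome variability. The distributional family of exosome noise
  is an assumption of the generator used for testing, not a claim about
  real exosomes. A planted cluster of 5 hairpins spaced 2 kb apart carries
  LFC = +10, *anchored at a moderate exosome-side abundance* (its baseline
  share is scaled by 2⁻¹⁰), so it is abundant in exosomes and nearly
  undetectable in cells without compressing the rest of the exosome
  library. 30% of the remaining transcripts get Normal(0, 2) log2 fold
  changes; biotype-level shifts (more piRNA/rRNA in exosomes, more
  miRNA/snoRNA in cells) shape the composition contrast. Four mature
  miRNAs outside the cluster carry a paternal cis effect of β_p = 2 on the
  natural-log scale (≈7-fold between haplotype groups, emulating clearly
  separated expression groups; β_m = 0 by default), applied identically in
  both compartments so the eQTLs are shared.
* **Alignments.** 2 000 reads per library over 10 hairpins (one 8-fold more
  abundant, so contribution analyses see realistic skew), matched cores of
  18–24 nt, and at most one nontemplated tail per read at rates
  `-A` 10%, `-T` 4%, `-AG` 2%, `T-` 2% — about 84% of reads tail-free,
  with adenylation the dominant 3′ addition. Unmapped reads (400 per
  library, 30 nt) carry a planted non-periodic 10-mer at a configurable
  per-read rate for the k-mer QC.
* **Reproducibility.** Every artifact draws from its own RNG stream derived
  from the single config seed, so fixtures are individually reproducible
  and stage toggles cannot shift one another's draws.

What the generator does **not** emulate: mapping and annotation errors,
multi-mapping piRNA ambiguity, GC/length biases, batch structure beyond the
compartment contrast, crossover interference, genotyping error, or
population-level linkage disequilibrium. Passing tests therefore
demonstrate the correctness and calibration of the implementations under
the stated model, not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$; GLM instability (non-convergence, |SE| > 10)
  triggers the documented moment fallback.
* Perfect eQTL fits ($R^2 = 1$ to machine precision) are flagged
  `perfect_fit` with the smallest positive double as p-value, keeping
  $p \in (0, 1]$.
* Zero-variance paired differences (composition, NTA comparison) give
  `p = NA` plus a flag.
* Constant expression vectors make Spearman undefined: flagged `NA`, and
  clustering refuses matrices containing `NA` rather than guessing.
* Majority-vote ties (even clamped windows at chromosome ends) keep the
  original call.
* Block-less transcripts are skipped with a log entry, never silently
  dropped into another block.

# Problem sizes

The shipped configuration — 34 libraries, ~290 transcripts, 3 200 markers,
2 000 alignments per library — was chosen so every stage, the full test
suite, and the acceptance script run in minutes on a laptop while leaving
all statistical checks (type-I calibration on thousands of null fits,
recovery rates pooled over replicate pedigrees, 20-seed cluster-recovery
rates) well-powered. All sizes scale through `sim_config()`.

# Known limitations

* The DE engine trades DESeq2-style shrinkage for transparency; on real
  data its significant-call counts will differ from shrinkage engines even
  though direction and strong effects agree.
* The haplotype-block inference is a stated-behavior-equivalent
  simplification of full pedigree phasing: it resolves blocks only up to
  the informative-marker grid and cannot see double crossovers between
  consecutive informative markers.
* The Wilcoxon comparison of correlation matrices ignores the dependence
  between pairs sharing a sample.
* The k-mer QC's pass/fail verdict at nominal α is noisy when many k-mers
  pass the prevalence floor; read it together with the returned per-k-mer
  table.
* cis assignment uses the hairpin midpoint; transcripts spanning a block
  boundary are assigned to the midpoint's block, and an alternative
  overlap-based assignment is not implemented.
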