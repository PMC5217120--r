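# exosmir

Cell versus exosome small RNA analysis in a three-generation family.

Exosomes — 30–100 nm extracellular vesicles — carry small RNAs between
cells, and their cargo differs systematically from the cells that secrete
them. `exosmir` implements the analysis stages of a paired cell/exosome
small-RNA sequencing study of a 17-member family (four grandparents, two
parents, eleven children), for analysts who want each stage as a plain,
tested R function:

* **Genomic miRNA clustering** — single-linkage components of hairpins
  within 10 kb of another member; mature counts aggregated to cluster
  counts (matures attributable to several clusters excluded), so that
  coordinated export of whole genomic clusters is testable.
* **Biotype composition** — per-sample proportions over six RNA classes,
  compared between compartments with paired t-tests, Bonferroni-corrected.
* **Differential expression** — a simplified negative-binomial Wald engine:
  median-of-ratios size factors, method-of-moments dispersion, NB GLM with
  offsets, BH FDR at 1%; plus binomial downsampling for depth-robustness
  checks.
* **Interindividual variability** — Spearman correlation matrices,
  average-linkage clustering on 1 − ρ, and a Wilcoxon comparison of
  within-cell versus within-exosome correlations.
* **Pedigree haplotypes** — Mendelian filtering, grandparent-anchored
  phasing, per-child transmission inference, and haplotype blocks between
  recombination points.
* **cis-eQTL mapping** — the two-haplotype linear model
  `log(Y + 1) ~ mu + beta_p * p + beta_m * m` over the eleven children
  (p, m ∈ {0,1} the inherited paternal/maternal haplotype codes), p-values
  from the model fit R² via the F-test, 20%-FDR cross-compartment
  intersection, and nongenetic-confounder checks (sex, genome-wide
  association ranking, k-mer mapping bias in unmapped reads).
* **NTA profiling** — 5′/3′ nontemplated nucleotide additions read from
  CIGAR soft clips of hairpin-local alignments (≥16 matched bases), with
  frequency tables, per-hairpin contributions, and compartment comparisons.

A synthetic-data generator (`sim_config()`, `simulate_*()`) reproduces the
study's statistical structure — a massively exported miRNA cluster,
noisier exosome libraries, haplotype-driven cis effects, planted
nontemplated tails — so the whole pipeline runs end-to-end with no
downloads, deterministically under one seed.

## Worked example

The `analysis/` directory holds numbered drivers for the full study; each
is a thin script over the package functions and writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R          # pedigree, genotypes, annotation, counts, alignments
Rscript analysis/02_clusters_composition.R
Rscript analysis/03_diffexp.R
Rscript analysis/04_variability.R
Rscript analysis/05_haplotypes_eqtl.R
Rscript analysis/06_nta.R
```

With the default seed this prints, among other lines:

```
clusters: 116 total; 115 singletons; largest has 5 hairpins
composition: 5/6 classes differ after Bonferroni (miRNA, misc, piRNA, rRNA, snoRNA)
mature level: 45/177 significant at 1% FDR (27 up in exosomes)
downsampling to 10%: 44/45 full-depth calls retained; 0 new calls
miRNA: mean within-cell rho 0.961 vs within-exosome 0.902 (Wilcoxon p = 4.12e-46)
haplotype blocks: 89 across 4 chromosomes
eQTL: 255 tested in cells, 253 in exosomes; beta_p correlation r = 0.42; 3 shared at 20% FDR
NTA-free: 82.0% of 2000 aligned reads; 3' tails seen: -A, -AG, -T
adenylation driver: hp-mir-01 carries 49.1% of '-A' reads
```

Reading these: the planted 5-hairpin cluster is the one non-singleton
cluster and is recovered as massively exosome-enriched; about a quarter of
miRNAs are differentially expressed between compartments at 1% FDR and the
calls survive 10× downsampling; exosome samples correlate less with each
other than cell samples do (the noisier-export signature); of four planted
haplotype cis effects, three pass the 20% FDR intersection in both
compartments at this seed; and ~82% of aligned reads carry no nontemplated
tail, with adenylation concentrated in the most abundant hairpin.

The same flow is available as a single call:

```r
library(exosmir)
res <- run_pipeline(sim_config(seed = 1), out_dir = "results/pipeline")
res$summary$exported_cluster
#> $cluster
#> [1] "cluster_0016"
#> $log2fc
#> [1] 10.59443
#> $padj
#> [1] 0
#> $significant
#> [1] TRUE
```

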