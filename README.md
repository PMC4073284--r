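# rbpreg

Tools for dissecting the regulatory program of an RNA-binding protein (RBP)
from CLIP-seq and RNA-seq evidence. The package is aimed at computational
biologists analyzing HITS-CLIP experiments paired with functional readouts:
it covers the full path from raw barcoded CLIP reads to filtered binding
sites, and from binding sites to three orthogonal measures of regulatory
consequence — cassette-exon splicing changes, dose-dependent mRNA-level
changes under an inducible expression system, and mRNA decay kinetics.

Every input and output is plain text (GTF, BED6+, FASTA/FASTQ, TSV), and a
synthetic-data module generates all inputs with known ground truth, so the
entire pipeline runs and is testable end to end without external data.

## What it computes

**CLIP tag processing.** Reads carry a known-sequence replicate index and a
degenerate barcode; after demultiplexing and polyA trimming, PCR duplicates
are collapsed on *(replicate, chrom, alignment start, strand, barcode)* into
unique tags, with crosslink-deletion evidence merged across duplicates.

**Clusters and stringency tiers.** Overlapping same-strand tags merge into
clusters scored by biological complexity (BC = number of replicates with
≥ 1 tag), total tags, peak height PH = max per-base depth with a gene-level
Poisson significance model, and a replicate-reproducibility chi-squared
score. Four nested tiers: BC2 & tags ≥ 2 → BC2 & tags ≥ 10 → + PH ≥ 10
(significant) → + reproducibility retained (p > 0.01).

**CIMS.** Crosslink-induced mutation sites from deletion evidence: per
position, k = tags with a deletion, m = coverage; FDR by within-tag
permutation, stratified by coverage; reproducible sites require k ≥ 5 and
FDR ≤ 0.01. Footprints (± 10 nt) feed a polyU composition test
(one-sided Mann–Whitney on per-window U fraction plus U-run counts).

**Splicing.** For a cassette exon with junction counts (inc_up, inc_down,
skip), the inclusion rate is

    I = (inc_up + inc_down) / 2,   IR = I / (I + skip)

averaged within condition; ΔI = IR(RBP-on) − IR(control). Events with
≥ 10 junction reads, |ΔI| ≥ 0.2 and Fisher exact p ≤ 0.05 are regulated;
CA exons are *bound* given ≥ 10 tags in BC2 tags ≥ 5 clusters over the
5'CE–3'CE span. A normalized complexity map profiles, per exon–intron
boundary and nucleotide offset, the fraction of events with tag coverage.

**Dose screen.** Median-of-ratios size factors, per-clone Pearson dose
correlations, and a three-criterion direct-target screen: p < 0.01 in both
wild-type clones, a ≥ 1.5-fold change already at the lowest nonzero dose in
both, and no significant correlation (p > 0.05) in the mutant clone; UP and
DOWN targets are then integrated with per-gene binding strength
(> 100 tags in BC2 tags ≥ 10 clusters = strong binder).

**Decay.** Half-lives from transcription-shutoff time courses by log-linear
fit through the origin (T½ = ln 2 / λ), with bootstrap CIs for half-life
ratios between conditions.

## Worked example

```r
library(rbpreg)

genome <- make_genome(n_genes = 30, seed = 11)
clip   <- simulate_clip(genome, seed = 12)
tags   <- collapse_duplicates(clip$reads)
nrow(clip$reads); nrow(tags)
#> 6977 reads -> 2287 unique tags
count_unique_tags(tags, genome$ann)$genic_fraction
#> 0.738

clusters <- apply_stringency_tiers(
  annotate_clusters(build_clusters(tags), genome$ann), n_replicates = 2)
colSums(clusters[, paste0("tier", 1:4)])
#> tier1 tier2 tier3 tier4
#>   109    27    27    26

sites <- cims_fdr(tags, n_permutations = 100, seed = 13)
sum(sites$reproducible)   # k >= 5, FDR <= 0.01
#> 25 of 29 candidate positions
fp  <- extract_footprints(sites[sites$reproducible, ], clip$seq)
bg  <- extract_footprints(data.frame(chrom = genome$chrom,
                                     pos = sample(1000:20000, 200),
                                     strand = "+"), clip$seq)
base_composition_enrichment(fp$seq, bg$seq)
#> footprint U fraction 0.56 vs background 0.24, p = 1.1e-16; 25/25 windows
#> contain a U-run

ctrl <- simulate_decay(2.3, seed = 14)   # control half-life 2.3 hr
dox  <- simulate_decay(9.8, seed = 15)   # stabilized half-life 9.8 hr
compare_half_lives(ctrl, dox, n_boot = 500, seed = 16)
#> half-life 2.3 -> 10.0 hr, ratio 4.29 (90% CI 4.10-4.50)
```

The tag counts and tier sizes say: of ~7k raw reads, a third survive
duplicate collapse as unique molecules, ~74% of them genic; 109 clusters
have two-replicate support, 27 of which are strong (≥ 10 tags) with
significant peaks, and 26 also pass the replicate-balance filter. The
planted crosslink sites are recovered at single-nucleotide resolution with
a strong polyU footprint signal, and the decay module recovers the planted
four-fold stabilization with a tight bootstrap CI.

`run_pipeline(out_dir, seed)` chains every stage on a synthetic bundle and
writes per-stage TSV/BED outputs plus a JSON manifest; identical seeds give
byte-identical outputs. A thin command-line wrapper with per-stage
subcommands is installed at `inst/scripts/rbpreg.R`.

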