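# eprinttools

Downstream analysis for **exonuclease-assisted protein–RNA interaction
profiling** (ePRINT-style assays). These assays capture the footprints of
RNA-binding proteins (RBPs) transcriptome-wide without antibodies: after UV
crosslinking, a 5'→3' exonuclease (XRN1) digests unprotected RNA and stalls
at the crosslinked protein, so the 5' end of each sequenced fragment marks
the start of a protein footprint. The package takes per-sample peak calls
(BED6), per-peak read counts for footprint and size-matched input libraries,
and a gene annotation, and carries them through to differential RBP-binding
events, motif-level RBP activity, and RBP regulatory networks — for users
comparing a knockdown against control, or one cell state against another.

## What it computes

**High-confidence peak cascade** (`run_cascade()`): merge peaks called in
≥ 2 samples (union of overlapping intervals, strand-aware), keep intragenic
peaks, test enrichment over the size-matched input with a one-sided binomial
test (`x` footprint reads of `n` total at null probability equal to the
footprint share of sequencing depth), then filter on cumulative peak counts
(≥ 50) and host-gene input expression (≥ 50).

**Differential binding** (`differential_binding()`): for each peak *p* and
sample *j*, footprint counts are modelled as

    K_pj ~ NB(mu_pj, alpha_p),
    log mu_pj = x_j' beta_p + log s_j + log max(q_{g(p),j}, 0.5)

where `s_j` is a median-of-ratios size factor, and `q_{g(p),j}` is the
normalised expression of the peak's host gene measured in the input library
matched to sample *j*. Host-gene expression therefore enters as a per-peak,
per-sample **offset**, so the condition coefficient `beta` estimates the
change in peak amplitude *beyond* the change in host-gene expression —
differential binding, not differential expression. Wald tests with
Benjamini–Hochberg adjustment; the signed Wald statistic ranks peaks from
most enhanced to most reduced. `deg_on_input()` runs conventional gene-level
differential expression on the inputs.

**Motif activity** (`positional_profile()`, `motif_peakset()`,
`directional_gsea()`): PWM scanning with relative log-odds scores in [0, 1]
(hit threshold 0.8), per-bp z-profiles in a 200-bp window centred on the
peak start, motif peaksets from a 50-bp window, and preranked GSEA of each
peakset over the ranked peak list (classic weighted Kolmogorov–Smirnov
running sum, membership permutations, NES against same-sign nulls).

**Feature context** (`classify_peaks()`, `feature_density()`,
`random_peak_background()`): strand-orientated classification of each peak
into 5' UTR / exon / intron / 3' UTR or junction categories (EX_IN, IN_EX,
EX_EX, IN_IN), peaks-per-100-kb densities, and matched random backgrounds.

**Overlap and networks** (`proximity_peakset()`, `gene_level_overlap()`,
`build_network()`): CLIP-proximity peaksets (within 200 bp), gene-level
hypergeometric overlap with UP/DOWN/UP-only/DOWN-only groups, and the
layered root-RBP → downstream-RBP → differentially-expressed-gene network
with a random-gene null (`random_gene_simulation()`).

**Unbiased 6-mers** (`kmer_presence()`, `cluster_peaks()`,
`cluster_kmer_enrichment()`, `partition_known_unknown()`): exact-substring
6-mer presence, Jaccard/average-linkage clustering of differential peaks,
per-cluster hypergeometric k-mer enrichment, and a known/unknown split
against a motif database with GSEA re-assessment of unknown k-mers.

**Synthetic experiments** (`simulate_experiment()`, `fixture_suite()`):
seeded generators of complete experiments — genome, annotation, jittered
per-sample peak calls, NB counts coupling binding to host expression,
planted effects/motifs/networks — with ground truth, so the whole pipeline
is testable without any download.

## Worked example

```r
library(eprinttools)

dir <- file.path(tempdir(), "demo")
sim <- fixture_suite("planted_motif", dir, seed = 42)   # 500 peaks, motif at anchors
cas <- run_cascade(sim$per_sample_peaks, sim$counts, sim$gene_expr, sim$genes)
cas$report
#> <cascade_report>
#>   per-sample calls         1869
#>   merged (support)          500
#>   intragenic                500
#>   input-enriched            500  (p < 0.001)
#>   peak-count filtered       498  (>= 50)
#>   final                     498  (host gene >= 50)
```

1,869 per-sample calls collapse to 500 replicate-supported peaks; two fall
below the cumulative count filter. Differential binding with host-gene
offsets, then the positional motif profile:

```r
ep <- sim$counts$samples$assay == "eprint"
ct <- count_table(cas$counts_matrix[S4Vectors::mcols(cas$peaks)$peak_id, ep],
                  sim$counts$samples[ep, ])
hosts <- setNames(S4Vectors::mcols(cas$peaks)$host_gene,
                  S4Vectors::mcols(cas$peaks)$peak_id)
res <- differential_binding(ct, sim$gene_expr, hosts)
head(res[order(res$padj), c("peak_id", "base_mean", "log2fc", "wald", "padj")], 3)
#>           peak_id base_mean    log2fc      wald         padj
#> 108 merged_000108 452.33716  2.190107  5.371283 3.893292e-05
#> 387 merged_000389 202.24945  1.980324  4.603438 5.824380e-04
#> 403 merged_000405  98.25969 -2.176463 -4.578724 5.824380e-04
nrow(significant_peaks(res, "fus"))    # padj < 0.05 & |log2FC| > 1
#> [1] 32

prof <- positional_profile(example_motifs()$GTGG, cas$peaks, sim$genome)
prof$position[which.max(prof$z)]; round(max(prof$z), 2)
#> [1] 7
#> [1] 5.37
```

The top peaks recover the planted ±1 log2 fold changes (the two strongest
are planted effects), and the planted GTGG-core motif produces a sharp
z ≈ 5.4 spike within a few bp of offset 0 — the residual +7 reflects the
±10 bp jitter of the simulated per-sample calls, whose merged unions shift
the anchor slightly. On null sequence the profile stays within |z| < 4.

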