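---
title: "Models and design choices in eprinttools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in eprinttools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprinttools)
```

# The measurement and its statistical structure

Exonuclease-assisted footprint profiling maps protein-RNA contacts without
antibodies. After UV crosslinking, a 5'→3' exonuclease digests RNA until it
stalls at a covalently bound protein, so the **5' end of a sequenced
fragment marks the footprint start** of whichever RBP was bound there. Two
consequences shape everything in this package:

* a peak's strand-orientated 5' anchor is its most informative coordinate
  (motifs concentrate there, so positional analyses centre on it), and
* peak read counts confound two biological quantities — how much the host
  transcript is expressed and how strongly the site is bound. An
  un-enriched, fragment-size-matched input library measures the first
  quantity alone, which is why every stage from filtering to differential
  testing is built around the footprint/input contrast.

# The peak cascade

`run_cascade()` applies, in order: replicate merging (union of transitively
overlapping same-strand calls, kept when supported by at least
`min_support = 2` distinct samples), an intragenic filter (same-strand
overlap with a gene span; ties to the gene with most overlapping bp, then
lexicographic id), an input-enrichment filter, a cumulative peak-count
filter, and a host-gene expression filter.

The input-enrichment statistic is not uniquely determined by the verbal
description "significantly enriched relative to the size-matched input";
we use a one-sided binomial test on replicate-summed counts: with $x$
footprint reads out of $n = x + x_{\mathrm{input}}$ reads on the peak, the
null success probability is the footprint share of total sequencing depth,
$p_0 = L_{\mathrm{fp}} / (L_{\mathrm{fp}} + L_{\mathrm{input}})$, and the
p-value is $P[X \ge x]$. This is exact at low counts, depth-aware, and
reduces to a fair-coin test at equal depths. Pooling replicates before the
test matches the cumulative-count semantics of the other filters; a
per-replicate-paired variant would be a straightforward extension but is
not implemented. Defaults ($p < 10^{-3}$, both count filters at 50) follow
the high-confidence preset; `expanded = TRUE` relaxes the input filter to
$p < 0.01$ for use with more permissive upstream peak calling.

# Differential binding with host-expression offsets

For peak $p$ in footprint sample $j$,

$$K_{pj} \sim \mathrm{NB}(\mu_{pj}, \alpha_p), \qquad
\log \mu_{pj} = x_j^\top \beta_p + \log s_j +
\log \max\!\big(q_{g(p),j},\ 0.5\big),$$

with $x_j$ the design row (intercept, condition, optionally batch), $s_j$
median-of-ratios size factors, and $q_{g(p),j}$ the normalised input
expression of the peak's host gene in the input sample matched to $j$ by
(condition, batch, replicate index). The "host expression as covariate"
idea cannot be a shared design column — its value differs per peak — so it
enters as a per-peak, per-sample log offset, the standard mechanism for
gene-specific normalisation factors. A peak whose counts merely track its
host gene's expression fits with $\beta_{\mathrm{cond}} \approx 0$; the
condition coefficient is therefore the change in binding beyond the change
in expression. The pseudocount floor 0.5 keeps offsets finite for silent
genes while preserving order among low values.

Fitting is IRLS maximum likelihood per peak with fixed dispersion
(convergence at $\max|\Delta\beta| < 10^{-8}$, at most 100 iterations),
covariance from the inverse Fisher information, two-sided normal Wald
p-values, and BH adjustment over all tested peaks. No independent
filtering and no fold-change shrinkage are applied; non-converged fits
propagate `NA` p-values. Ranking for set enrichment uses the signed Wald
statistic with ties broken by peak id, so the order is total and
reproducible.

## Dispersion

Dispersion is estimated per peak by method of moments on offset-normalised
counts: with per-row factors $f_j = e^{o_{pj} - \bar o_p}$ and
$q_j = K_{pj}/f_j$, the within-group residual variance $\hat v$ gives
$\hat\alpha_{\mathrm{mom}} = (\hat v - \hat\mu \overline{1/f})/\hat\mu^2$.
A mean-dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted across
peaks and each peak's estimate is shrunk toward it with weight

$$w = \frac{\mathrm{df}}{\mathrm{df} + 4}, \qquad
\mathrm{df} = n - \#\text{groups},$$

clamped to $[10^{-8}, 10]$. The df-based weight is the deliberate design
choice here: at the common 2+2 design the moment estimate has 2 residual
degrees of freedom and is nearly exponential-distributed; giving it half
the weight makes the plug-in Wald tests visibly anticonservative (measured
type-I ≈ 0.07 at nominal 0.05 on 5,000 null peaks), while $w = 2/6$
restores calibration (≈ 0.054). At df = 4 the rule coincides with an equal
50/50 blend, and as replication grows the per-peak estimate dominates, as
it should. This is a simple stabiliser, not an empirical-Bayes posterior;
it is the main approximation relative to a full DESeq2-style treatment
(no Cox–Reid adjustment, no outlier handling), and the package's tests
treat its calibration as a contract rather than an assumption.

# Motif scanning and activity

PWMs (database matrices, MEME minimal files, or plain k-mers expanded to
0.97/0.01 columns) are scored with base-2 log-odds against a uniform
background, probabilities floored at $10^{-3}$; scores are rescaled to
$[0,1]$ between the attainable minimum and maximum ("relative log-odds"),
so 1 is the consensus path. The hit threshold 0.8 follows common practice
for this score; both the base and the background are configurable, and the
known limitation — a single global threshold treats sharp and degenerate
motifs differently — argues for background-calibrated per-motif thresholds
as future work. Non-ACGT bases contribute zero (background-neutral), and U
is mapped to T at load so RNA-alphabet motifs and DNA-alphabet sequence
share one code path. Scanning is on the transcript strand only; RNA is
single-stranded, so reverse-complement hits are not meaningful.

Positional profiles scan a 200-bp window centred on the 5' anchor
(windows at contig edges are N-padded), average the per-offset relative
scores across peaks, and standardise **across offsets** — the z-score says
how unusual an offset is for that motif, not how strong the motif is
(standardising across motifs instead would be the other reading of
"converted to z-scores"; the per-offset choice is what makes the
anchor-proximal spike interpretable). Motif peaksets use a 50-bp window
and max-over-offsets ≥ 0.8.

Directional GSEA is the classic preranked running sum with weight
exponent 1. The null permutes set membership (not ranks), p-values are
one-sided within the observed ES sign with the +1 convention (flooring at
$1/(n_{\mathrm{perm}}+1)$ when no same-sign null exceeds the observed),
and NES divides by the mean |ES| of same-sign nulls. BH is applied across
all sets tested in one batch. A brute-force $O(N)$ full-walk recomputation
of the ES is kept in the test suite as an oracle, and the statistic is
cross-checked against the fgsea reference implementation.

# Feature classification and backgrounds

Peak start (the 5' anchor) and end sites are located in the host gene's
features; both-in-one-instance gives UTR5/EX/IN/UTR3, and mixed locations
give the junction categories, which are orientation-aware (EX_IN means the
*transcriptional* start is exonic). Conventions: a site exactly on an
exon/intron boundary is exonic (half-open tiling), UTR labels take
precedence over plain exon (the more specific label wins), and each gene
contributes a single flattened feature set — multi-isoform structure is
out of scope, and the generator emits one transcript per gene. Densities
are peaks per 100 kb of feature sequence with UTR bp excluded from the
exon denominator. Random backgrounds redraw, per feature class, a
configurable multiple (default 10×) of the observed peaks uniformly within
that class's intervals with lengths resampled from the observed class
lengths; a draw that cannot fit after 100 attempts is truncated, which
slightly favours short intervals but keeps the per-class counts exact.

# Networks and k-mers

The layered network takes: a root RBP; its direct targets (CLIP); the RBPs
whose motif peaksets changed in activity; and the differentially expressed
genes from the input libraries. Layer-1 edges connect the root to changed
RBPs that are also its direct targets; layer-2 edges connect those RBPs to
the DEGs they target under a pluggable `target_caller` (CLIP peaksets, or
motif-carrying differential peaks mapped to host genes, or k-mer
carriers). The random-gene null redraws the DEG set uniformly from the
expressed universe and rebuilds the network; its mean linked count equals
the hypergeometric expectation (draw size × target coverage), which the
tests verify.

For unbiased discovery, 6-mer presence is exact substring occurrence —
for k = 6 against much longer peaks, a maximal local alignment saturates
exactly at verbatim occurrence, and the clustering consumes the binary
matrix anyway. Distances are Jaccard on presence rows with average
linkage; rows are clustered in canonical id order because average-linkage
tie-breaking is order-dependent, which makes memberships invariant to
input order. The cluster count is a parameter (default 12) — no cut rule
is claimed to be canonical. Per-cluster k-mer enrichment is hypergeometric
against the analysed peak set with BH across the full cluster × k-mer
grid (one family of tests, conservative), skipping k-mers carried by
fewer than 5 peaks. K-mers are "known" if any database PWM scores ≥ 0.8
at the best alignment offset; unknown enriched k-mers are re-assessed by
the same directional GSEA.

# What the generator emulates — and what it does not

`simulate_experiment()` produces genomes with valid gene structure on both
strands, uniform background sequence, non-overlapping true peaks placed in
per-gene slots, per-sample calls jittered ±10 bp with 10% dropout (planted
effect peaks are always called, so ground truth survives replicate
filtering), and counts

$$K_{pj} \sim \mathrm{NB}\big(d_j \, e_{g(p),j} \, a_p \,
2^{\lambda_p [j \in B]},\ \alpha\big)$$

with lognormal depth factors $d_j$, per-gene relative expression with a
**shared per-replicate biological fluctuation** $e_{g,j}$ (sd 0.2 on the
log scale) that appears identically in the matched input library — this
shared component is precisely what the host-expression offsets exist to
absorb, so omitting it would make the offsets look useless by
construction — lognormal binding activities $a_p$, planted log2 effects
$\lambda_p$, and NB dispersions (0.1 for footprint counts; 0.01 for input
counts, which carry only counting/technical noise since biological
variation is explicit).

Fixture presets define the study conditions used by the tests and the
acceptance script, at sizes chosen to finish in minutes on one core:
`null` (5,000 peaks, 2+2 samples, no effects) for calibration;
`confounded` for the offset contrast; `planted_motif` (500 peaks,
consensus at the anchor in 90% with 5% per-base mutation, exercising the
0.8 threshold); `tiny` for end-to-end runs; `planted_network` for network
recovery. Two fixture-design points deserve note. First, the confounded
preset doubles host expression in **25%** of genes rather than all:
a global shift is absorbed entirely by median-of-ratios normalisation
(and ~40% of it is still absorbed when 40% of genes shift), so
whole-transcriptome confounding is undetectable by construction; with a
25% minority the normalisation stays anchored and the no-offset model
shows the expected high false-positive rate on confounded peaks (~30%)
versus ~5% with offsets. Second, planted fold changes are balanced up and
down; a one-sided global effect biases the size factors and dampens
recovery for the same reason.

What the generator does **not** emulate: realistic sequence composition
(GC structure, repeats), isoform mixtures, positional read-density shapes
within peaks, crosslink-site mutations, or overlapping true peaks.
Passing tests therefore demonstrate correctness of the algorithms and
calibration under the stated statistical structure — not robustness to
every artefact of real libraries.

# Numerical and degenerate-input conventions

Coordinates are 0-based half-open at file boundaries (BED convention) and
1-based closed inside `GRanges`; GTF input is converted on read. Overlap
means ≥ 1 shared bp; merely adjacent intervals do not merge, and CLIP
proximity uses inclusive edge-to-edge distance (a 200-bp gap is "within
200 bp"). The enrichment test returns p = 1 at zero totals; empty CLIP
site lists yield empty peaksets with a warning; peaksets that are empty or
cover the whole universe are errors for GSEA; genes absent from the
expression table fail the cascade's expression filter and are logged;
all-zero count rows get the trend dispersion and are flagged, and
zero-count genes are excluded from input DE with a report. All stochastic
stages take explicit seeds, and fixed seeds give byte-identical outputs
(bundles, permutations, backgrounds).
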