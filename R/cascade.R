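#' Merge replicate peak calls
#'
#' Per-sample peak calls are merged by taking the union of transitively
#' overlapping intervals (same chromosome; same strand when
#' `strand_aware`); each merged interval is retained only if it is
#' overlapped by calls from at least `min_support` distinct samples.
#' Overlap means at least one shared base; merely adjacent intervals are
#' not merged.
#'
#' @param per_sample_peaks list (one element per sample) of peak `GRanges`.
#' @param min_support minimum number of distinct supporting samples
#'   (default 2; must not exceed the number of samples).
#' @param strand_aware merge per strand (default `TRUE`; the assay is
#'   stranded).
#' @return merged peak `GRanges` with `support` counts.
#' @export
merge_replicate_peaks <- function(per_sample_peaks, min_support = 2L,
                                  strand_aware = TRUE) {
  n_samp <- length(per_sample_peaks)
  if (n_samp < 2) stop("need per-sample peaks from >= 2 samples")
  if (min_support > n_samp) {
    stop("min_support (", min_support, ") exceeds number of samples (",
         n_samp, ")")
  }
  all_gr <- unlist(methods::as(per_sample_peaks, "GRangesList"))
  sample_of <- rep(seq_len(n_samp), lengths(per_sample_peaks))
  if (!strand_aware) BiocGenerics::strand(all_gr) <- "*"
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = 0L,
                                  ignore.strand = !strand_aware)
  hits <- GenomicRanges::findOverlaps(merged, all_gr,
                                      ignore.strand = !strand_aware)
  support <- vapply(split(sample_of[S4Vectors::subjectHits(hits)],
                          factor(S4Vectors::queryHits(hits),
                                 levels = seq_along(merged))),
                    function(s) length(unique(s)), 0L)
  keep <- support >= min_support
  merged <- merged[keep]
  support <- support[keep]
  o <- order(as.character(seqnames(merged)), BiocGenerics::start(merged),
             BiocGenerics::end(merged), as.character(strand(merged)))
  merged <- merged[o]
  support <- support[o]
  # built directly (not via peaks()) so the strand-unaware mode may carry "*"
  out <- GenomicRanges::GRanges(seqnames(merged),
                                IRanges::IRanges(BiocGenerics::start(merged),
                                                 BiocGenerics::end(merged)),
                                strand = strand(merged))
  S4Vectors::mcols(out)$peak_id <- sprintf("merged_%06d", seq_along(out))
  S4Vectors::mcols(out)$support <- as.integer(support)
  S4Vectors::mcols(out)$host_gene <- NA_character_
  names(out) <- S4Vectors::mcols(out)$peak_id
  out
}

#' Assign host genes to peaks
#'
#' A peak is intragenic iff its interval overlaps a gene span on the same
#' strand. Ties (a peak overlapping several genes) are broken by maximal
#' base-pair overlap, then lexicographic gene id, so output is
#' deterministic.
#'
#' @param gr peak `GRanges`.
#' @param genes list of [gene_model()].
#' @return `gr` with the `host_gene` column filled (`NA` = intergenic).
#' @export
assign_host_gene <- function(gr, genes) {
  spans <- gene_spans(genes)
  hits <- GenomicRanges::findOverlaps(gr, spans)
  if (length(hits)) {
    ov <- BiocGenerics::width(IRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], spans[S4Vectors::subjectHits(hits)]))
    gid <- names(spans)[S4Vectors::subjectHits(hits)]
    df <- data.frame(q = S4Vectors::queryHits(hits), ov = ov, gid = gid)
    df <- df[order(df$q, -df$ov, df$gid), ]
    df <- df[!duplicated(df$q), ]
    host <- rep(NA_character_, length(gr))
    host[df$q] <- df$gid
  } else {
    host <- rep(NA_character_, length(gr))
  }
  S4Vectors::mcols(gr)$host_gene <- host
  gr
}

#' Keep intragenic peaks
#' @param gr peak `GRanges` with `host_gene` assigned.
#' @return subset of `gr` with a host gene.
#' @export
intragenic <- function(gr) gr[!is.na(S4Vectors::mcols(gr)$host_gene)]

#' Input-enrichment binomial test
#'
#' One-sided upper-tail binomial test of footprint-library enrichment over
#' the size-matched input: with `x` footprint reads out of `n = x + input`
#' total on a peak, the null success probability is the footprint share of
#' sequencing depth `p0 = lib_eprint / (lib_eprint + lib_input)`. Returns
#' `P[X >= x]`; `n = 0` returns 1 by convention. Vectorised over peaks.
#'
#' @param x_eprint,x_input replicate-summed counts per peak.
#' @param lib_eprint,lib_input summed library sizes per assay.
#' @return p-values.
#' @export
input_enrichment_test <- function(x_eprint, x_input, lib_eprint, lib_input) {
  stopifnot(lib_eprint > 0, lib_input > 0)
  n <- x_eprint + x_input
  p0 <- lib_eprint / (lib_eprint + lib_input)
  p <- stats::pbinom(x_eprint - 1, n, p0, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

#' Cascade configuration
#'
#' Default thresholds follow the high-confidence preset: input-enrichment
#' p < 0.001, cumulative footprint count per peak >= 50, cumulative input
#' count per host gene >= 50. The `expanded` preset relaxes the input
#' enrichment threshold to p < 0.01 (paired upstream with more permissive
#' per-sample peak calling, which is the caller's responsibility).
#'
#' @param min_support replicate support for merging.
#' @param enrich_p input-enrichment p-value threshold.
#' @param min_peak_count minimum cumulative footprint count per peak.
#' @param min_gene_count minimum cumulative input count per host gene.
#' @param strand_aware strand-aware merging and counting.
#' @param expanded use the expanded preset (`enrich_p = 0.01`).
#' @return named list of thresholds.
#' @export
cascade_config <- function(min_support = 2L, enrich_p = 0.001,
                           min_peak_count = 50, min_gene_count = 50,
                           strand_aware = TRUE, expanded = FALSE) {
  if (expanded) enrich_p <- 0.01
  list(min_support = as.integer(min_support), enrich_p = enrich_p,
       min_peak_count = min_peak_count, min_gene_count = min_gene_count,
       strand_aware = strand_aware, expanded = expanded)
}

#' Sum count rows onto peaks by interval overlap
#'
#' Count rows carry the interval they were measured on (`coords` of the
#' [count_table()]); each peak receives the column-wise sum of all
#' same-strand overlapping rows. Without coords, rows are matched to peaks
#' by id.
#'
#' @param gr peak `GRanges`.
#' @param ct `count_table`.
#' @return matrix `length(gr)` x samples.
#' @export
peak_counts_for <- function(gr, ct) {
  out <- matrix(0, nrow = length(gr), ncol = ncol(ct$counts),
                dimnames = list(S4Vectors::mcols(gr)$peak_id,
                                colnames(ct$counts)))
  if (is.null(ct$coords)) {
    idx <- match(S4Vectors::mcols(gr)$peak_id, rownames(ct$counts))
    ok <- !is.na(idx)
    out[ok, ] <- ct$counts[idx[ok], , drop = FALSE]
    return(out)
  }
  rows <- GenomicRanges::GRanges(ct$coords$chrom,
                                 IRanges::IRanges(ct$coords$start + 1L,
                                                  ct$coords$end),
                                 strand = ct$coords$strand)
  hits <- GenomicRanges::findOverlaps(gr, rows)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    for (j in seq_len(ncol(out))) {
      agg <- rowsum(ct$counts[s, j], q)
      out[as.integer(rownames(agg)), j] <- agg[, 1]
    }
  }
  out
}

#' Run the high-confidence peak cascade
#'
#' Stages, in order: (1) merge per-sample calls requiring replicate
#' support, (2) keep intragenic peaks (same-strand gene-span overlap),
#' (3) keep peaks significantly enriched over the size-matched input
#' (binomial test on replicate-summed counts), (4) keep peaks whose
#' cumulative footprint count reaches `min_peak_count`, (5) drop peaks
#' hosted by lowly expressed genes (cumulative input count below
#' `min_gene_count`; peaks whose host gene is absent from the expression
#' table fail this stage and are logged in the report).
#'
#' @param per_sample_peaks list of per-sample peak `GRanges`.
#' @param counts `count_table` with both `eprint` and `input` samples and
#'   row coordinates (or rows keyed by merged peak id).
#' @param gene_expr gene-level `count_table` of input samples.
#' @param genes list of [gene_model()].
#' @param config [cascade_config()].
#' @return list with `peaks` (survivors), `intragenic` (the merged
#'   intragenic universe with hosts), `merged` (all merged peaks),
#'   `eprint_counts` (survivor footprint count matrix) and `report`.
#' @export
run_cascade <- function(per_sample_peaks, counts, gene_expr, genes,
                        config = cascade_config()) {
  n_initial <- sum(vapply(per_sample_peaks, length, 0L))
  merged <- merge_replicate_peaks(per_sample_peaks, config$min_support,
                                  config$strand_aware)
  merged <- assign_host_gene(merged, genes)
  intra <- intragenic(merged)

  cnt <- peak_counts_for(intra, counts)
  is_ep <- counts$samples$assay == "eprint"
  x_ep <- rowSums(cnt[, is_ep, drop = FALSE])
  x_in <- rowSums(cnt[, !is_ep, drop = FALSE])
  lib_ep <- sum(counts$samples$library_size[is_ep])
  lib_in <- sum(counts$samples$library_size[!is_ep])
  p_enr <- input_enrichment_test(x_ep, x_in, lib_ep, lib_in)
  keep1 <- p_enr < config$enrich_p
  keep2 <- keep1 & x_ep >= config$min_peak_count

  gene_tot <- rowSums(gene_expr$counts)
  host <- S4Vectors::mcols(intra)$host_gene
  host_tot <- gene_tot[match(host, names(gene_tot))]
  missing_genes <- unique(host[keep2 & is.na(host_tot)])
  keep3 <- keep2 & !is.na(host_tot) & host_tot >= config$min_gene_count

  report <- structure(list(
    n_initial = n_initial, n_merged = length(merged),
    n_intragenic = length(intra), n_input_enriched = sum(keep1),
    n_count_filtered = sum(keep2), n_final = sum(keep3),
    thresholds = config, missing_expression_genes = missing_genes),
    class = "cascade_report")
  stages <- unlist(report[c("n_merged", "n_intragenic", "n_input_enriched",
                            "n_count_filtered", "n_final")])
  stopifnot(all(diff(stages) <= 0))
  if (length(missing_genes)) {
    message(length(missing_genes),
            " host gene(s) missing from the expression table; their peaks",
            " fail the expression filter")
  }
  list(peaks = intra[keep3], intragenic = intra, merged = merged,
       eprint_counts = cnt[keep3, is_ep, drop = FALSE],
       counts_matrix = cnt, enrichment_p = p_enr, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  cat(sprintf("  per-sample calls     %8d\n", x$n_initial))
  cat(sprintf("  merged (support)     %8d\n", x$n_merged))
  cat(sprintf("  intragenic           %8d\n", x$n_intragenic))
  cat(sprintf("  input-enriched       %8d  (p < %g)\n",
              x$n_input_enriched, x$thresholds$enrich_p))
  cat(sprintf("  peak-count filtered  %8d  (>= %g)\n",
              x$n_count_filtered, x$thresholds$min_peak_count))
  cat(sprintf("  final                %8d  (host gene >= %g)\n",
              x$n_final, x$thresholds$min_gene_count))
  invisible(x)
}
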