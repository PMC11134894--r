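#' Feature categories
#'
#' The nine peak categories: both sites in the same 5' UTR, exon, intron
#' or 3' UTR instance (`UTR5`, `EX`, `IN`, `UTR3`); junction-spanning
#' peaks with start/end in exons and introns (`EX_IN`, `IN_EX`), different
#' exons (`EX_EX`) or different introns (`IN_IN`); and `INTERGENIC`.
#' "Start" is the transcription-orientated 5' footprint anchor, so `EX_IN`
#' and `IN_EX` are distinct on the minus strand.
#'
#' @export
FEATURE_CATEGORIES <- c("UTR5", "EX", "IN", "UTR3",
                        "EX_EX", "EX_IN", "IN_EX", "IN_IN", "INTERGENIC")

# which interval of `iv` (0-based half-open matrix) contains 0-based pos;
# 0 when none
.interval_index <- function(pos, iv) {
  if (!nrow(iv)) return(0L)
  hit <- which(iv[, 1] <= pos & pos < iv[, 2])
  if (length(hit)) hit[1] else 0L
}

classify_one <- function(p_start0, p_end0, strand, gene) {
  # sites in transcription orientation: start = 5' anchor
  if (strand == "-") { s <- p_end0 - 1L; e <- p_start0 }
  else { s <- p_start0; e <- p_end0 - 1L }
  u5s <- .interval_index(s, gene$utr5); u5e <- .interval_index(e, gene$utr5)
  u3s <- .interval_index(s, gene$utr3); u3e <- .interval_index(e, gene$utr3)
  exs <- .interval_index(s, gene$exons); exe <- .interval_index(e, gene$exons)
  ins <- .interval_index(s, gene$introns); ine <- .interval_index(e, gene$introns)
  # UTR is exonic sequence; the more specific label wins when both sites
  # fall in the same UTR instance
  if (u5s > 0 && u5s == u5e) return("UTR5")
  if (u3s > 0 && u3s == u3e) return("UTR3")
  if (exs > 0 && exs == exe) return("EX")
  if (ins > 0 && ins == ine) return("IN")
  if (exs > 0 && exe > 0) return("EX_EX")
  if (exs > 0 && ine > 0) return("EX_IN")
  if (ins > 0 && exe > 0) return("IN_EX")
  if (ins > 0 && ine > 0) return("IN_IN")
  # a site outside the gene span (peak sticking out of the gene): fall back
  # on the classes of whichever sites are inside
  cls_s <- if (exs > 0) "EX" else if (ins > 0) "IN" else NA
  cls_e <- if (exe > 0) "EX" else if (ine > 0) "IN" else NA
  if (!is.na(cls_s) && is.na(cls_e)) return(if (cls_s == "EX") "EX" else "IN")
  if (is.na(cls_s) && !is.na(cls_e)) return(if (cls_e == "EX") "EX" else "IN")
  "INTERGENIC"
}

#' Classify peaks into gene-feature categories
#'
#' Each peak's start site (the 5' footprint anchor) and end site (the
#' other extremity) are located within its host gene's features; the
#' combination determines the category (see [FEATURE_CATEGORIES]). A
#' site exactly on an exon/intron boundary is exonic (half-open tiling).
#' Peaks without a host gene are `INTERGENIC`.
#'
#' @param gr peak `GRanges` with `host_gene` assigned.
#' @param genes named list of [gene_model()].
#' @return factor of categories, one per peak, named by peak id.
#' @export
classify_peaks <- function(gr, genes) {
  host <- S4Vectors::mcols(gr)$host_gene
  st0 <- BiocGenerics::start(gr) - 1L
  en0 <- BiocGenerics::end(gr)
  sd <- as.character(BiocGenerics::strand(gr))
  out <- vapply(seq_along(gr), function(i) {
    if (is.na(host[i]) || is.null(genes[[host[i]]])) return("INTERGENIC")
    classify_one(st0[i], en0[i], sd[i], genes[[host[i]]])
  }, "")
  factor(stats::setNames(out, S4Vectors::mcols(gr)$peak_id),
         levels = FEATURE_CATEGORIES)
}

feature_bp <- function(genes, what) {
  sum(vapply(genes, function(g) {
    iv <- g[[what]]
    if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0L
  }, 0L))
}

#' Peak density per feature class
#'
#' Peaks per 100 kb of feature sequence, for the four single-feature
#' classes. The denominator is the total bp of that feature across the
#' supplied (expressed) genes; UTR bp is not double-counted as exonic in
#' the `EX` denominator. Classes with zero total length are omitted.
#'
#' @param categories factor from [classify_peaks()].
#' @param genes gene models defining the feature space.
#' @return data.frame `feature`, `n_peaks`, `feature_bp`, `per_100kb`.
#' @export
feature_density <- function(categories, genes) {
  utr_bp <- function(g, which) {
    if (nrow(g[[which]])) sum(g[[which]][, 2] - g[[which]][, 1]) else 0L
  }
  ex_total <- feature_bp(genes, "exons") -
    feature_bp(genes, "utr5") - feature_bp(genes, "utr3")
  lens <- c(UTR5 = feature_bp(genes, "utr5"), EX = ex_total,
            IN = feature_bp(genes, "introns"),
            UTR3 = feature_bp(genes, "utr3"))
  cnt <- table(categories)[names(lens)]
  keep <- lens > 0
  data.frame(feature = names(lens)[keep],
             n_peaks = as.integer(cnt[keep]),
             feature_bp = as.integer(lens[keep]),
             per_100kb = 1e5 * as.integer(cnt[keep]) / lens[keep],
             row.names = NULL)
}

feature_intervals <- function(genes, class) {
  what <- switch(class, UTR5 = "utr5", UTR3 = "utr3", EX = "exons",
                 IN = "introns")
  rows <- lapply(genes, function(g) {
    iv <- g[[what]]
    if (!nrow(iv)) return(NULL)
    data.frame(chrom = g$chrom, start = iv[, 1], end = iv[, 2],
               strand = g$strand)
  })
  do.call(rbind, rows)
}

#' Matched random peak background
#'
#' Draws, for each single-feature class, `multiplier` times the observed
#' number of peaks of that class, uniformly within the class's intervals,
#' with lengths resampled from the observed length distribution of the
#' class. A drawn peak that does not fit its interval is redrawn (up to
#' 100 attempts) and finally truncated to the interval.
#'
#' @param genes gene models.
#' @param template_peaks observed peak `GRanges`.
#' @param categories their categories ([classify_peaks()]).
#' @param multiplier per-class count multiplier (>= 1; default 10).
#' @param seed RNG seed (mandatory: the background must be reproducible).
#' @return peak `GRanges` with a `class` column.
#' @export
random_peak_background <- function(genes, template_peaks, categories,
                                   multiplier = 10, seed) {
  stopifnot(multiplier >= 1, !missing(seed))
  set.seed(seed)
  out <- NULL
  for (cl in c("UTR5", "EX", "IN", "UTR3")) {
    obs <- which(categories == cl)
    if (!length(obs)) next
    iv <- feature_intervals(genes, cl)
    if (is.null(iv)) next
    lens_obs <- BiocGenerics::width(template_peaks[obs])
    n_draw <- round(multiplier * length(obs))
    widths <- iv$end - iv$start
    pick <- sample.int(nrow(iv), n_draw, replace = TRUE, prob = widths)
    len <- sample(lens_obs, n_draw, replace = TRUE)
    st <- integer(n_draw)
    for (i in seq_len(n_draw)) {
      ok <- FALSE
      for (att in seq_len(100L)) {
        room <- widths[pick[i]] - len[i]
        if (room >= 0) { ok <- TRUE; break }
        pick[i] <- sample.int(nrow(iv), 1, prob = widths)
        len[i] <- sample(lens_obs, 1)
      }
      if (!ok) len[i] <- widths[pick[i]]   # truncate to the interval
      room <- widths[pick[i]] - len[i]
      st[i] <- iv$start[pick[i]] + if (room > 0) sample.int(room + 1, 1) - 1 else 0
    }
    gr <- peaks(iv$chrom[pick], st, st + len, iv$strand[pick],
                peak_id = sprintf("rand_%s_%05d", cl, seq_len(n_draw)))
    S4Vectors::mcols(gr)$class <- cl
    out <- if (is.null(out)) gr else c(out, gr)
  }
  if (is.null(out)) {
    out <- peaks(character(), integer(), integer(), character())
    S4Vectors::mcols(out)$class <- character()
  }
  out
}
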