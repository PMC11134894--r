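#' k-mer presence matrix
#'
#' Binary peaks x 4^k matrix: entry 1 iff the k-mer occurs as an exact
#' substring of the peak sequence (U mapped to T first; windows containing
#' other letters match nothing). Sequences shorter than `k` give an
#' all-zero row with a warning.
#'
#' @param peak_sequences named character vector of peak sequences.
#' @param k k-mer length (default 6).
#' @return binary integer matrix with k-mers as column names.
#' @export
kmer_presence <- function(peak_sequences, k = 6L) {
  seqs <- toupper(chartr("U", "T", peak_sequences))
  if (any(nchar(seqs) < k)) {
    warning(sum(nchar(seqs) < k), " sequence(s) shorter than k = ", k,
            "; all-zero rows")
  }
  dss <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::oligonucleotideFrequency(dss, width = k)
  pres <- (cnt > 0) + 0L
  rownames(pres) <- names(peak_sequences)
  pres
}

#' Cluster peaks by shared k-mer content
#'
#' Agglomerative hierarchical clustering (average linkage) on the Jaccard
#' distance between binary k-mer presence rows, cut into `n_clusters`
#' groups. Deterministic for a given input (and invariant to row order up
#' to label permutation).
#'
#' @param presence matrix from [kmer_presence()].
#' @param n_clusters number of clusters (default 12).
#' @return integer cluster labels named by peak id; the dendrogram is
#'   attached as attribute `"hclust"`.
#' @export
cluster_peaks <- function(presence, n_clusters = 12L) {
  if (nrow(presence) < n_clusters) {
    stop("fewer peaks than requested clusters")
  }
  # canonical row order first: average-linkage tie-breaking depends on
  # input order, so clustering on id-sorted rows makes the memberships
  # invariant to how the peaks were supplied
  ord <- order(rownames(presence))
  sorted <- presence[ord, , drop = FALSE]
  d <- stats::dist(sorted, method = "binary")   # 1 - Jaccard similarity
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = n_clusters)[rownames(presence)]
  attr(labels, "hclust") <- hc
  labels
}

#' Per-cluster k-mer enrichment
#'
#' Upper-tail hypergeometric test of each k-mer's carrier count within
#' each cluster against its carrier count in the whole analysed peak set,
#' BH-adjusted across the full cluster x k-mer grid. k-mers carried by
#' fewer than `min_universe_count` peaks overall are skipped.
#'
#' @param presence matrix from [kmer_presence()].
#' @param labels cluster labels from [cluster_peaks()].
#' @param min_universe_count minimum carriers in the universe (default 5).
#' @return data.frame with one row per tested (cluster, k-mer).
#' @export
cluster_kmer_enrichment <- function(presence, labels,
                                    min_universe_count = 5L) {
  stopifnot(nrow(presence) == length(labels))
  N <- nrow(presence)
  univ_cnt <- colSums(presence)
  test_km <- which(univ_cnt >= min_universe_count)
  rows <- lapply(sort(unique(labels)), function(cl) {
    in_cl <- labels == cl
    k <- sum(in_cl)
    q <- colSums(presence[in_cl, test_km, drop = FALSE])
    m <- univ_cnt[test_km]
    data.frame(cluster = cl, kmer = colnames(presence)[test_km],
               in_cluster_count = as.integer(q), cluster_size = k,
               universe_count = as.integer(m), universe_size = N,
               p = stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Partition k-mers into known (motif-attributed) and unknown
#'
#' A k-mer is "known" iff its relative log-odds score against any motif
#' in the database reaches `threshold` at the best alignment offset
#' (shorter of k-mer/motif slid along the longer; the score is computed
#' over the aligned motif columns). Known k-mers carry the union of the
#' matching motifs' RBP attributions.
#'
#' @param kmers character vector of k-mers.
#' @param motif_db list of `motif_model` (empty: everything is unknown,
#'   with a warning).
#' @param threshold relative log-odds threshold (default 0.8; 1.0 keeps
#'   only exact consensus matches).
#' @return data.frame `kmer`, `known`, `rbps` (comma separated, "" if
#'   unknown), `best_motif`, `best_score`.
#' @export
partition_known_unknown <- function(kmers, motif_db, threshold = 0.8) {
  if (!length(motif_db)) {
    warning("empty motif database; all k-mers unknown")
    return(data.frame(kmer = kmers, known = FALSE, rbps = "",
                      best_motif = NA_character_, best_score = NA_real_,
                      stringsAsFactors = FALSE))
  }
  score_vs_motif <- function(kmer, motif) {
    b <- match(strsplit(chartr("U", "T", kmer), "")[[1]],
               c("A", "C", "G", "T"))
    lo <- motif_logodds(motif)
    L <- nrow(lo); k <- length(b)
    best <- -Inf
    if (L >= k) {
      for (off in 0:(L - k)) {
        cols <- (off + 1):(off + k)
        raw <- sum(lo[cbind(cols, b)], na.rm = TRUE)
        lo_sub <- lo[cols, , drop = FALSE]
        rel <- (raw - sum(apply(lo_sub, 1, min))) /
          (sum(apply(lo_sub, 1, max)) - sum(apply(lo_sub, 1, min)))
        best <- max(best, rel)
      }
    } else {
      for (off in 0:(k - L)) {
        raw <- sum(lo[cbind(seq_len(L), b[(off + 1):(off + L)])],
                   na.rm = TRUE)
        rel <- (raw - sum(apply(lo, 1, min))) /
          (sum(apply(lo, 1, max)) - sum(apply(lo, 1, min)))
        best <- max(best, rel)
      }
    }
    best
  }
  rows <- lapply(kmers, function(km) {
    sc <- vapply(motif_db, function(m) score_vs_motif(km, m), 0)
    best <- which.max(sc)
    hits <- sc >= threshold
    data.frame(kmer = km, known = any(hits),
               rbps = paste(sort(unique(unlist(
                 lapply(motif_db[hits], `[[`, "rbp_names")))),
                 collapse = ","),
               best_motif = motif_db[[best]]$motif_id,
               best_score = sc[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' GSEA of unknown k-mers over the ranked peak list
#'
#' Each unknown k-mer's carrier peaks (from the presence matrix) form a
#' peakset; [directional_gsea()] is run for each and results are
#' BH-adjusted together. k-mers without carriers in the ranked universe
#' are skipped. The `significant` attribute holds the set retained at
#' `padj < 0.05`.
#'
#' @param ranked ranked peak data.frame (`peak_id`, `stat`).
#' @param unknown_kmers k-mers to test.
#' @param presence matrix from [kmer_presence()].
#' @param n_perm,seed permutation settings.
#' @return `gsea_batch()`-style data.frame.
#' @export
unknown_kmer_gsea <- function(ranked, unknown_kmers, presence,
                              n_perm = 1000L, seed = 1L) {
  sets <- lapply(unknown_kmers, function(km) {
    carriers <- rownames(presence)[presence[, km] > 0]
    peak_set(km, carriers, "kmer_cluster")
  })
  names(sets) <- unknown_kmers
  keep <- vapply(sets, function(s) length(s$peak_ids) > 0, TRUE)
  res <- gsea_batch(ranked, sets[keep], n_perm = n_perm, seed = seed)
  attr(res, "significant") <- res$set_id[!is.na(res$padj) & res$padj < 0.05]
  res
}
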