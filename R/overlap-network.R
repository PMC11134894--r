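#' CLIP-proximity peakset
#'
#' Peaks within `max_gap` bases of any CLIP site on the same strand and
#' chromosome form the CLIP-proximity peakset (overlap counts as gap 0;
#' the boundary is inclusive, so a gap of exactly `max_gap` is in).
#'
#' @param query_peaks peak `GRanges`.
#' @param clip_sites CLIP site `GRanges` (same assembly).
#' @param max_gap maximum edge-to-edge distance in bp (default 200).
#' @param set_id name of the resulting set.
#' @return `peak_set` with provenance `clip_overlap`.
#' @export
proximity_peakset <- function(query_peaks, clip_sites, max_gap = 200L,
                              set_id = "clip_proximal") {
  if (!length(clip_sites)) {
    warning("empty CLIP site list; returning empty peakset")
    return(peak_set(set_id, character(), "clip_overlap"))
  }
  keep <- rep(FALSE, length(query_peaks))
  for (sd in c("+", "-")) {
    qi <- which(as.character(strand(query_peaks)) == sd)
    si <- as.character(strand(clip_sites)) == sd
    if (!length(qi) || !any(si)) next
    d <- GenomicRanges::distanceToNearest(query_peaks[qi],
                                          clip_sites[si],
                                          ignore.strand = TRUE)
    hit_q <- S4Vectors::queryHits(d)
    keep[qi[hit_q]] <- S4Vectors::mcols(d)$distance <= max_gap
  }
  peak_set(set_id, S4Vectors::mcols(query_peaks)$peak_id[keep],
           "clip_overlap")
}

#' Gene-level overlap of differential peaks with CLIP targets
#'
#' Genes hosting at least one enhanced peak form the UP group, reduced
#' the DOWN group; UP_ONLY/DOWN_ONLY exclude genes with peaks in both
#' directions. Each group is tested for over-representation of CLIP
#' target genes by an upper-tail hypergeometric test over the universe of
#' genes hosting at least one tested peak, and the fold enrichment
#' observed/expected is reported.
#'
#' @param res `differential_result` for peaks.
#' @param hosts named vector peak id -> host gene.
#' @param clip_target_genes character vector of CLIP target gene ids.
#' @param preset significance preset (see [significance_preset()]).
#' @param universe gene universe; default all genes hosting a tested peak.
#' @return data.frame, one row per group (`UP`, `DOWN`, `UP_ONLY`,
#'   `DOWN_ONLY`).
#' @export
gene_level_overlap <- function(res, hosts, clip_target_genes,
                               preset = "fus", universe = NULL) {
  if (is.null(universe)) universe <- unique(unname(hosts[res$peak_id]))
  universe <- unique(universe)
  sig <- significant_peaks(res, preset)
  up_genes <- unique(unname(hosts[sig$peak_id[sig$direction == "enhanced"]]))
  dn_genes <- unique(unname(hosts[sig$peak_id[sig$direction == "reduced"]]))
  groups <- list(UP = up_genes, DOWN = dn_genes,
                 UP_ONLY = setdiff(up_genes, dn_genes),
                 DOWN_ONLY = setdiff(dn_genes, up_genes))
  targets <- intersect(unique(clip_target_genes), universe)
  N <- length(universe); K <- length(targets)
  do.call(rbind, lapply(names(groups), function(g) {
    gg <- intersect(groups[[g]], universe)
    n <- length(gg)
    ov <- length(intersect(gg, targets))
    expected <- n * K / N
    data.frame(group = g, n_group_genes = n, n_clip_targets = K,
               n_overlap = ov, universe_size = N,
               fold_enrichment = if (expected > 0) ov / expected else NA_real_,
               p = if (n == 0) 1 else
                 stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
}

#' Build the layered root-RBP regulatory network
#'
#' Layer 1 connects the root RBP to downstream RBPs that both changed in
#' activity (motif/CLIP GSEA) and are direct CLIP targets of the root.
#' Layer 2 connects each such RBP to the differentially expressed genes
#' it targets, where targets are supplied by `target_caller` (CLIP
#' peaksets, motif-carrying differential peaks mapped to genes, or k-mer
#' carriers — the evidence label records which).
#'
#' @param root name of the root RBP.
#' @param root_clip_targets gene ids directly bound by the root (CLIP).
#' @param changed_rbps character vector of RBPs with changed activity.
#' @param degs differentially expressed gene ids.
#' @param target_caller function(rbp) -> character vector of target gene
#'   ids (may return `NULL` for RBPs without data: the node is kept with
#'   zero out-edges and a warning is issued).
#' @param evidence edge evidence label (`"clip"` or `"motif"`).
#' @return object of class `regulatory_network`: list with `nodes`,
#'   `edges`, `n_degs_linked`, `edge_count`.
#' @export
build_network <- function(root, root_clip_targets, changed_rbps, degs,
                          target_caller, evidence = c("clip", "motif")) {
  evidence <- match.arg(evidence)
  layer1 <- intersect(changed_rbps, root_clip_targets)
  edges <- data.frame(source = character(), target = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  if (length(layer1)) {
    edges <- data.frame(source = root, target = layer1, evidence = "clip",
                        stringsAsFactors = FALSE)
  }
  linked <- character()
  for (rbp in layer1) {
    tg <- target_caller(rbp)
    if (is.null(tg) || !length(tg)) {
      warning("no target data for RBP ", rbp, "; node kept with no out-edges")
      next
    }
    hit <- intersect(degs, tg)
    if (length(hit)) {
      edges <- rbind(edges, data.frame(source = rbp, target = hit,
                                       evidence = evidence,
                                       stringsAsFactors = FALSE))
      linked <- union(linked, hit)
    }
  }
  edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
  nodes <- data.frame(
    id = c(root, layer1, degs),
    layer = c("root", rep("rbp", length(layer1)), rep("gene", length(degs))),
    stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  structure(list(root = root, nodes = nodes, edges = edges,
                 n_degs = length(degs), n_degs_linked = length(linked),
                 linked_degs = linked, edge_count = nrow(edges)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> root=%s rbps=%d edges=%d DEGs linked %d/%d\n",
              x$root, sum(x$nodes$layer == "rbp"), x$edge_count,
              x$n_degs_linked, x$n_degs))
  invisible(x)
}

#' Write a network as edge-list TSV and JSON
#' @param net `regulatory_network`.
#' @param tsv_path,json_path output files (either may be `NULL`).
#' @export
write_network <- function(net, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(net[c("root", "nodes", "edges", "n_degs",
                               "n_degs_linked", "edge_count")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(net)
}

#' Random-gene null for the network DEG linkage
#'
#' Repeatedly draws `n_genes` genes from the expressed-transcriptome
#' universe (without replacement), rebuilds the network with the draw in
#' place of the observed differentially expressed genes, and records the
#' number of drawn genes linked to any downstream RBP. Gives the null
#' distribution of linked counts and an empirical p-value for the
#' observed count.
#'
#' @param universe gene ids to draw from.
#' @param observed_linked observed linked-DEG count.
#' @param network_builder function(genes) -> `regulatory_network`.
#' @param n_genes genes per draw (default 53).
#' @param n_reps draws (a warning is issued below 100: the empirical p is
#'   unstable).
#' @param seed RNG seed.
#' @return list with `linked_counts`, `null_mean`, `null_sd`,
#'   `empirical_p`.
#' @export
random_gene_simulation <- function(universe, observed_linked,
                                   network_builder, n_genes = 53L,
                                   n_reps = 1000L, seed = 1L) {
  stopifnot(n_genes <= length(universe))
  if (n_reps < 100) warning("n_reps < 100: empirical p-value is unstable")
  set.seed(seed)
  counts <- vapply(seq_len(n_reps), function(i) {
    draw <- sample(universe, n_genes)
    network_builder(draw)$n_degs_linked
  }, 0L)
  list(linked_counts = counts, null_mean = mean(counts),
       null_sd = stats::sd(counts),
       empirical_p = (1 + sum(counts >= observed_linked)) / (1 + n_reps))
}
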