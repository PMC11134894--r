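#' Peak interval sequences in transcription orientation
#'
#' @param gr peak `GRanges`.
#' @param genome named character vector or `DNAStringSet`.
#' @return named character vector (5'->3' along the transcript).
#' @export
peak_sequences <- function(gr, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  chroms <- as.character(seqnames(gr))
  out <- vapply(seq_along(gr), function(i) {
    s <- substr(genome[[chroms[i]]], BiocGenerics::start(gr)[i],
                BiocGenerics::end(gr)[i])
    if (as.character(strand(gr))[i] == "-") revcomp_chr(s) else s
  }, "")
  stats::setNames(out, S4Vectors::mcols(gr)$peak_id)
}

stage_dir <- function(out_dir, stage, overwrite) {
  d <- file.path(out_dir, stage)
  if (dir.exists(d)) {
    if (!overwrite) stop("stage directory exists (stages are write-once): ", d)
    unlink(d, recursive = TRUE)
  }
  dir.create(d, recursive = TRUE)
  d
}

#' Run the full analysis pipeline on an experiment bundle
#'
#' Executes cascade -> differential binding -> feature annotation ->
#' motif GSEA (when motifs are given and sequence is available) ->
#' CLIP overlap (when CLIP sites are given) -> k-mer discovery
#' (optional), writing per-stage outputs and a machine-readable run
#' manifest. Stage directories are write-once; on a stage failure the
#' stage name is reported and a `.partial` marker left in the output
#' directory.
#'
#' @param input_dir bundle directory (layout of [fixture_suite()]).
#' @param out_dir output directory.
#' @param motifs named list of [motif_model()] (or `NULL` to skip motif
#'   stages).
#' @param clip_sites `GRanges` of CLIP sites (or `NULL`).
#' @param preset significance preset for differential peaks.
#' @param cascade [cascade_config()].
#' @param n_perm GSEA permutations.
#' @param seed seed for all stochastic stages.
#' @param kmer run the k-mer discovery stage.
#' @param kmer_clusters clusters per direction for the k-mer stage.
#' @param overwrite allow overwriting existing stage directories.
#' @return (invisibly) list of stage results plus the manifest.
#' @export
run_full_pipeline <- function(input_dir, out_dir, motifs = NULL,
                              clip_sites = NULL, preset = "fus",
                              cascade = cascade_config(), n_perm = 500L,
                              seed = 1L, kmer = FALSE, kmer_clusters = 4L,
                              overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  marker <- file.path(out_dir, ".partial")
  file.create(marker)
  manifest <- list(package = "eprinttools",
                   version = as.character(utils::packageVersion("eprinttools")),
                   input_dir = input_dir, seed = seed, preset = preset,
                   thresholds = cascade, n_perm = n_perm, stages = list())
  res <- list()
  run_stage <- function(stage, fn) {
    out <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- out$files
    res[[stage]] <<- out$value
    invisible(NULL)
  }

  bundle <- load_fixture(input_dir)

  run_stage("cascade", function() {
    d <- stage_dir(out_dir, "cascade", overwrite)
    cas <- run_cascade(bundle$per_sample_peaks, bundle$counts,
                       bundle$gene_expr, bundle$genes, cascade)
    write_peaks(cas$peaks, file.path(d, "peaks_final.bed"))
    jsonlite::write_json(unclass(cas$report)[1:6],
                         file.path(d, "report.json"), auto_unbox = TRUE)
    list(value = cas, files = c("peaks_final.bed", "report.json"))
  })
  cas <- res$cascade

  run_stage("differential", function() {
    d <- stage_dir(out_dir, "differential", overwrite)
    ep_idx <- bundle$counts$samples$assay == "eprint"
    ct <- count_table(cas$counts_matrix[S4Vectors::mcols(cas$peaks)$peak_id,
                                        ep_idx, drop = FALSE],
                      bundle$counts$samples[ep_idx, , drop = FALSE])
    hosts <- stats::setNames(S4Vectors::mcols(cas$peaks)$host_gene,
                             S4Vectors::mcols(cas$peaks)$peak_id)
    dres <- differential_binding(ct, bundle$gene_expr, hosts)
    degs <- deg_on_input(bundle$gene_expr)
    utils::write.table(dres, file.path(d, "differential_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(degs, file.path(d, "input_deg.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rk <- ranked_peaks(dres)
    utils::write.table(rk, file.path(d, "ranked_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(peaks = dres, degs = degs, ranked = rk, hosts = hosts),
         files = c("differential_peaks.tsv", "input_deg.tsv",
                   "ranked_peaks.tsv"))
  })
  diffr <- res$differential

  run_stage("annotation", function() {
    d <- stage_dir(out_dir, "annotation", overwrite)
    cats <- classify_peaks(cas$peaks, bundle$genes)
    dens <- feature_density(cats, bundle$genes)
    utils::write.table(data.frame(peak_id = names(cats),
                                  category = as.character(cats)),
                       file.path(d, "peak_categories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dens, file.path(d, "feature_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(categories = cats, density = dens),
         files = c("peak_categories.tsv", "feature_density.tsv"))
  })

  if (!is.null(motifs) && !is.null(bundle$genome)) {
    run_stage("motif_gsea", function() {
      d <- stage_dir(out_dir, "motif_gsea", overwrite)
      sets <- lapply(motifs, motif_peakset, gr = cas$peaks,
                     genome = bundle$genome)
      gs <- gsea_batch(diffr$ranked, sets, n_perm = n_perm, seed = seed)
      utils::write.table(gs, file.path(d, "motif_gsea.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(value = list(peaksets = sets, gsea = gs),
           files = "motif_gsea.tsv")
    })
  }

  if (!is.null(clip_sites)) {
    run_stage("clip_overlap", function() {
      d <- stage_dir(out_dir, "clip_overlap", overwrite)
      ps <- proximity_peakset(cas$peaks, clip_sites)
      gs <- if (length(ps$peak_ids) &&
                length(ps$peak_ids) < nrow(diffr$ranked)) {
        directional_gsea(diffr$ranked, ps, n_perm = n_perm, seed = seed)
      } else NULL
      ov <- gene_level_overlap(diffr$peaks, diffr$hosts,
                               clip_target_genes = unique(
                                 diffr$hosts[ps$peak_ids]),
                               preset = preset)
      if (!is.null(gs)) {
        utils::write.table(gs, file.path(d, "clip_gsea.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      utils::write.table(ov, file.path(d, "gene_overlap.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(value = list(peakset = ps, gsea = gs, overlap = ov),
           files = c("clip_gsea.tsv", "gene_overlap.tsv"))
    })
  }

  if (kmer && !is.null(bundle$genome)) {
    run_stage("kmer", function() {
      d <- stage_dir(out_dir, "kmer", overwrite)
      sig <- significant_peaks(diffr$peaks, preset)
      out <- list()
      for (dir_lab in c("enhanced", "reduced")) {
        ids <- sig$peak_id[sig$direction == dir_lab]
        if (length(ids) < max(kmer_clusters, 2)) next
        seqs <- peak_sequences(cas$peaks[ids], bundle$genome)
        pres <- kmer_presence(seqs)
        labs <- cluster_peaks(pres, n_clusters = min(kmer_clusters,
                                                     nrow(pres)))
        enr <- cluster_kmer_enrichment(pres, labs)
        utils::write.table(
          data.frame(peak_id = names(labs), cluster = as.integer(labs)),
          file.path(d, paste0("clusters_", dir_lab, ".tsv")), sep = "\t",
          quote = FALSE, row.names = FALSE)
        utils::write.table(enr,
                           file.path(d, paste0("kmer_enrichment_", dir_lab,
                                               ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[dir_lab]] <- list(labels = labs, enrichment = enr)
      }
      list(value = out, files = list.files(d))
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  file.remove(marker)
  res$manifest <- manifest
  invisible(res)
}
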