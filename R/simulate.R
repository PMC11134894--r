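#' Simulation configuration
#'
#' Study conditions for a synthetic footprinting experiment. Defaults
#' mirror the real designs this workflow targets: two conditions with two
#' replicates each (footprint + matched input libraries), NB-distributed
#' counts whose means couple peak binding activity to host-gene
#' expression, per-sample peak calls jittered and thinned so replicate
#' merging is exercised, and optional planted condition effects,
#' host-expression shifts and sequence motifs at peak anchors.
#'
#' @param seed RNG seed (mandatory; one stream per bundle).
#' @param n_genes number of genes.
#' @param exons_per_gene,exon_len,intron_len,utr5_len,utr3_len,intergenic_gap
#'   integer ranges `c(min, max)` for gene structure.
#' @param peaks_per_gene,peak_len ranges for peak placement.
#' @param conditions two condition labels (first = reference).
#' @param reps replicates per condition.
#' @param batch add a batch label alternating across replicates.
#' @param depth_sd lognormal sd of per-sample depth factors.
#' @param peak_mean expected footprint count per peak at depth 1 and
#'   relative expression 1.
#' @param peak_mean_sd lognormal spread of per-peak binding activity.
#' @param input_peak_mean expected input count overlapping a peak (low:
#'   the input is un-enriched).
#' @param gene_expr_mean expected gene-level input count.
#' @param gene_expr_sd lognormal spread of relative gene expression.
#' @param expr_bio_sd lognormal sd of per-gene, per-replicate biological
#'   expression fluctuation, shared between a footprint library and its
#'   matched input (this shared component is what the host-expression
#'   offsets are meant to absorb).
#' @param dispersion,input_dispersion NB dispersions (alpha).
#' @param effect_frac fraction of peaks with a planted condition effect.
#' @param effect_log2fc planted log2 fold change magnitude.
#' @param effect_sign `"both"`, `"up"` or `"down"`.
#' @param host_shift_frac,host_shift_log2 fraction of genes whose
#'   expression (and, through the coupling, whose peaks' counts) shifts in
#'   the non-reference condition, and the shift magnitude.
#' @param decoy_frac fraction of peaks left un-enriched over input (they
#'   should fail the cascade's enrichment filter).
#' @param motif optional [motif_model()] planted at peak anchors.
#' @param motif_rate fraction of peaks carrying the planted motif.
#' @param motif_offset transcript-orientated offset of the instance start
#'   relative to the anchor.
#' @param motif_mut per-base mutation rate of planted instances (default
#'   0.05, giving realistic sub-consensus hits).
#' @param jitter per-sample peak boundary jitter in bp.
#' @param dropout per-sample probability of missing a true peak (planted
#'   effect peaks are always called so ground truth survives merging).
#' @param with_sequence generate the genome sequence (disable for
#'   counts-only fixtures).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 60L,
                       exons_per_gene = c(1L, 4L),
                       exon_len = c(120L, 300L),
                       intron_len = c(150L, 600L),
                       utr5_len = c(20L, 80L),
                       utr3_len = c(40L, 150L),
                       intergenic_gap = c(300L, 800L),
                       peaks_per_gene = c(2L, 4L),
                       peak_len = c(30L, 80L),
                       conditions = c("ctrl", "treat"),
                       reps = 2L,
                       batch = FALSE,
                       depth_sd = 0.15,
                       peak_mean = 150,
                       peak_mean_sd = 0.6,
                       input_peak_mean = 4,
                       gene_expr_mean = 300,
                       gene_expr_sd = 0.7,
                       expr_bio_sd = 0.2,
                       dispersion = 0.1,
                       input_dispersion = 0.01,
                       effect_frac = 0,
                       effect_log2fc = 1,
                       effect_sign = "both",
                       host_shift_frac = 0,
                       host_shift_log2 = 0,
                       decoy_frac = 0,
                       motif = NULL,
                       motif_rate = 0,
                       motif_offset = 0L,
                       motif_mut = 0.05,
                       jitter = 10L,
                       dropout = 0.1,
                       with_sequence = TRUE) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(length(conditions) == 2, reps >= 1,
            effect_frac >= 0, effect_frac <= 1,
            motif_rate >= 0, motif_rate <= 1,
            dropout >= 0, dropout < 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with gene annotation
#'
#' Genes with valid exon/intron/UTR structure are laid out along one
#' chromosome on both strands with i.i.d. uniform background sequence.
#' Seeded by `config$seed`.
#'
#' @param config [sim_config()].
#' @return list with `genome` (named character, `NULL` when
#'   `with_sequence = FALSE`), `genes` (named list of [gene_model()]),
#'   `chrom_len`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  rint <- function(rng) if (rng[1] >= rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1)
  cur <- 200L
  genes <- list()
  for (i in seq_len(config$n_genes)) {
    n_ex <- rint(config$exons_per_gene)
    ex_l <- vapply(seq_len(n_ex), function(j) rint(config$exon_len), 0L)
    in_l <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1), function(j) rint(config$intron_len), 0L)
    } else integer()
    if (any(ex_l <= 2)) stop("infeasible exon length constraints")
    strand <- sample(c("+", "-"), 1)
    starts <- cur + cumsum(c(0L, as.integer(ex_l[-n_ex] + in_l)))
    exons <- cbind(starts, starts + ex_l)
    u5l <- min(rint(config$utr5_len), min(ex_l) - 2L)
    u3l <- min(rint(config$utr3_len), min(ex_l) - 2L)
    if (strand == "+") {
      utr5 <- if (u5l > 0) cbind(exons[1, 1], exons[1, 1] + u5l) else NULL
      utr3 <- if (u3l > 0) cbind(exons[n_ex, 2] - u3l, exons[n_ex, 2]) else NULL
    } else {
      utr5 <- if (u5l > 0) cbind(exons[n_ex, 2] - u5l, exons[n_ex, 2]) else NULL
      utr3 <- if (u3l > 0) cbind(exons[1, 1], exons[1, 1] + u3l) else NULL
    }
    gid <- sprintf("gene_%04d", i)
    genes[[gid]] <- gene_model(gid, "chr1", strand, exons, utr5, utr3)
    cur <- exons[n_ex, 2] + rint(config$intergenic_gap)
  }
  chrom_len <- cur + 200L
  genome <- if (config$with_sequence) {
    c(chr1 = rand_dna(chrom_len))
  } else NULL
  list(genome = genome, genes = genes, chrom_len = chrom_len)
}

mutate_instance <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(b)) < rate
  if (any(hit)) {
    b[hit] <- vapply(b[hit], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, "")
  }
  paste(b, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate peaks, per-sample calls and NB count tables
#'
#' Places non-overlapping true peaks within genes, plants motif instances
#' at anchors when configured (mutating the genome sequence), draws
#' footprint and input counts with mean
#' `depth_j x hostExpr_{g, cond(j)} x activity_p x 2^(lfc_p [cond = B])`
#' and NB dispersion alpha, and emits per-sample peak calls jittered and
#' thinned so the replicate-merging stage is exercised. Seeded by
#' `config$seed + 1` (the bundle's second stream).
#'
#' @param sim result of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list: `per_sample_peaks` (list of `GRanges` per footprint
#'   sample), `true_peaks` (`GRanges`), `counts` ([count_table()] with
#'   coords; footprint + input samples), `gene_expr` (gene-level input
#'   `count_table`), `genome` (with motifs planted), `truth`.
#' @export
simulate_peaks_and_counts <- function(sim, config) {
  set.seed(config$seed + 1L)
  genes <- sim$genes
  genome <- sim$genome
  rint <- function(rng) if (rng[1] >= rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1)

  # ---- peak placement: one peak per non-overlapping slot inside the gene
  rows <- list()
  for (g in genes) {
    k <- rint(config$peaks_per_gene)
    span <- g$span[["end"]] - g$span[["start"]]
    w <- span %/% k
    margin <- config$jitter + 2L
    for (i in seq_len(k)) {
      len <- rint(config$peak_len)
      if (w < len + 2 * margin + 2) next
      lo <- g$span[["start"]] + (i - 1L) * w + margin
      hi <- g$span[["start"]] + i * w - margin - len
      st <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1) - 1L else lo
      rows[[length(rows) + 1]] <- data.frame(
        chrom = g$chrom, start = st, end = st + len, strand = g$strand,
        gene = g$gene_id, stringsAsFactors = FALSE)
    }
  }
  pk <- do.call(rbind, rows)
  n_pk <- nrow(pk)
  pk$peak_id <- sprintf("true_%05d", seq_len(n_pk))
  true_peaks <- peaks(pk$chrom, pk$start, pk$end, pk$strand,
                      peak_id = pk$peak_id, host_gene = pk$gene)

  # ---- planted condition effects and decoys
  is_effect <- rep(FALSE, n_pk)
  lfc <- rep(0, n_pk)
  if (config$effect_frac > 0) {
    eff <- sample.int(n_pk, round(config$effect_frac * n_pk))
    is_effect[eff] <- TRUE
    sign <- switch(config$effect_sign,
                   up = rep(1, length(eff)),
                   down = rep(-1, length(eff)),
                   both = sample(c(-1, 1), length(eff), replace = TRUE))
    lfc[eff] <- sign * config$effect_log2fc
  }
  is_decoy <- rep(FALSE, n_pk)
  if (config$decoy_frac > 0) {
    cand <- which(!is_effect)
    is_decoy[sample(cand, round(config$decoy_frac * n_pk))] <- TRUE
  }

  # ---- motif planting (mutates the genome)
  motif_truth <- NULL
  if (!is.null(config$motif) && config$motif_rate > 0) {
    if (is.null(genome)) stop("motif planting requires with_sequence = TRUE")
    carriers <- sort(sample.int(n_pk, round(config$motif_rate * n_pk)))
    cons <- motif_consensus(config$motif)
    L <- nchar(cons)
    anchors <- peak_anchor(true_peaks)
    chr <- genome[["chr1"]]
    for (i in carriers) {
      inst <- mutate_instance(cons, config$motif_mut)
      a <- anchors[i]
      off <- config$motif_offset
      if (pk$strand[i] == "+") {
        from <- a + off
        substr(chr, from + 1L, from + L) <- inst
      } else {
        to <- a - off
        substr(chr, to - L + 2L, to + 1L) <- revcomp_chr(inst)
      }
    }
    genome[["chr1"]] <- chr
    motif_truth <- data.frame(peak_id = pk$peak_id[carriers],
                              offset = config$motif_offset,
                              stringsAsFactors = FALSE)
  }

  # ---- samples
  n_ep <- length(config$conditions) * config$reps
  cond <- rep(config$conditions, each = config$reps)
  rep_i <- rep(seq_len(config$reps), times = 2)
  batch <- if (config$batch) paste0("b", rep_i) else NA_character_
  ep_names <- sprintf("eprint_%s_r%d", cond, rep_i)
  in_names <- sprintf("input_%s_r%d", cond, rep_i)
  depth_ep <- exp(stats::rnorm(n_ep, 0, config$depth_sd))
  depth_in <- exp(stats::rnorm(n_ep, 0, config$depth_sd))

  # ---- expression and activity
  gene_ids <- names(genes)
  rel_expr <- stats::setNames(exp(stats::rnorm(length(gene_ids), 0,
                                               config$gene_expr_sd)),
                              gene_ids)
  shifted <- rep(FALSE, length(gene_ids))
  if (config$host_shift_frac > 0) {
    shifted[sample.int(length(gene_ids),
                       round(config$host_shift_frac * length(gene_ids)))] <- TRUE
  }
  expr_mult <- function(j) {  # per-gene multiplier for sample j's condition
    ifelse(shifted & cond[j] == config$conditions[2],
           2^config$host_shift_log2, 1)
  }
  # biological expression fluctuation per gene x replicate pair, shared
  # between each footprint library and its matched input
  bio <- matrix(exp(stats::rnorm(length(gene_ids) * n_ep, 0,
                                 config$expr_bio_sd)),
                length(gene_ids), n_ep, dimnames = list(gene_ids, NULL))
  act <- config$peak_mean * exp(stats::rnorm(n_pk, 0, config$peak_mean_sd))
  gidx <- match(pk$gene, gene_ids)

  ep_counts <- matrix(0L, n_pk, n_ep, dimnames = list(pk$peak_id, ep_names))
  in_counts <- matrix(0L, n_pk, n_ep, dimnames = list(pk$peak_id, in_names))
  gene_counts <- matrix(0L, length(gene_ids), n_ep,
                        dimnames = list(gene_ids, in_names))
  true_mu <- matrix(0, n_pk, n_ep, dimnames = list(pk$peak_id, ep_names))
  for (j in seq_len(n_ep)) {
    em <- expr_mult(j)
    e_g <- rel_expr * em * bio[, j]
    fc <- if (cond[j] == config$conditions[2]) 2^lfc else rep(1, n_pk)
    base_act <- ifelse(is_decoy, config$input_peak_mean, act)
    mu_ep <- depth_ep[j] * e_g[gidx] * base_act * fc / mean(rel_expr)
    mu_in <- depth_in[j] * e_g[gidx] * config$input_peak_mean / mean(rel_expr)
    mu_gene <- depth_in[j] * e_g * config$gene_expr_mean / mean(rel_expr)
    true_mu[, j] <- mu_ep
    ep_counts[, j] <- stats::rnbinom(n_pk, mu = mu_ep,
                                     size = 1 / config$dispersion)
    in_counts[, j] <- stats::rnbinom(n_pk, mu = mu_in,
                                     size = 1 / config$input_dispersion)
    gene_counts[, j] <- stats::rnbinom(length(gene_ids), mu = mu_gene,
                                       size = 1 / config$input_dispersion)
  }

  samples <- data.frame(
    name = c(ep_names, in_names),
    assay = rep(c("eprint", "input"), each = n_ep),
    condition = rep(cond, 2), batch = rep(batch, 2),
    library_size = round(1e6 * c(depth_ep, depth_in)),
    stringsAsFactors = FALSE)
  coords <- pk[c("chrom", "start", "end", "strand")]
  counts <- count_table(cbind(ep_counts, in_counts), samples, coords)
  gene_expr <- count_table(gene_counts,
                           samples[samples$assay == "input", , drop = FALSE])

  # ---- per-sample peak calls (jitter + dropout; effect peaks always kept)
  per_sample <- stats::setNames(vector("list", n_ep), ep_names)
  for (j in seq_len(n_ep)) {
    keep <- stats::runif(n_pk) >= config$dropout | is_effect
    st <- pmax(pk$start[keep] +
                 sample(seq(-config$jitter, config$jitter), sum(keep),
                        replace = TRUE), 0L)
    en <- pmax(pk$end[keep] +
                 sample(seq(-config$jitter, config$jitter), sum(keep),
                        replace = TRUE), st + 5L)
    per_sample[[j]] <- peaks(pk$chrom[keep], st, en, pk$strand[keep],
                             peak_id = sprintf("%s_%s", ep_names[j],
                                               pk$peak_id[keep]))
  }

  truth <- list(
    peaks = data.frame(pk[c("peak_id", "chrom", "start", "end", "strand",
                            "gene")],
                       log2fc = lfc, is_effect = is_effect,
                       is_decoy = is_decoy, activity = act,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_ids, rel_expr = unname(rel_expr),
                       shifted = shifted, stringsAsFactors = FALSE),
    motif = motif_truth,
    true_mu = true_mu,
    seed = config$seed)
  list(per_sample_peaks = per_sample, true_peaks = true_peaks,
       counts = counts, gene_expr = gene_expr, genome = genome,
       truth = truth)
}

#' Run a full synthetic experiment
#'
#' [simulate_genome()] followed by [simulate_peaks_and_counts()] under
#' one configuration; same seed, byte-identical output.
#'
#' @param config [sim_config()].
#' @return the [simulate_peaks_and_counts()] list plus `genes`.
#' @export
simulate_experiment <- function(config) {
  g <- simulate_genome(config)
  out <- simulate_peaks_and_counts(g, config)
  out$genes <- g$genes
  out$config <- config
  out
}

#' Example motif models
#'
#' Three small synthetic PWMs used in documentation and fixtures: a
#' GTGG-core motif (GU-rich binders), an AU-rich element and a GA-rich
#' exonic enhancer-like motif. These are constructed in code, not copies
#' of any database.
#'
#' @return named list of `motif_model`.
#' @export
example_motifs <- function() {
  sharp <- function(bases, p = 0.85) {
    b <- strsplit(bases, "")[[1]]
    pwm <- matrix((1 - p) / 3, length(b), 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pwm[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- p
    pwm
  }
  list(
    GTGG = motif_model("SYN_GTGG", sharp("GTGGTG"), "synRBP_G"),
    ARE = motif_model("SYN_ARE", sharp("TATTTAT"), "synRBP_AU"),
    GAR = motif_model("SYN_GAR", sharp("GGAGGA"), "synRBP_GA"))
}

#' Write a synthetic experiment bundle to disk
#'
#' Presets: `tiny` (a dozen genes, full sequence, runs the whole pipeline
#' in seconds), `null` (5,000 peaks, no condition effects; calibration),
#' `confounded` (host expression doubled in the non-reference condition,
#' binding unchanged; the offset-model contrast fixture), `planted_motif`
#' (500 peaks, consensus planted at the anchor in 90% of peaks) and
#' `planted_network` (1 root RBP, 4 downstream RBPs, 30 target genes with
#' known edges). Each bundle directory holds the inputs in plain-text
#' formats plus `truth.json`.
#'
#' @param name preset name.
#' @param dir output directory (refused if it exists, unless `force`).
#' @param seed RNG seed.
#' @param force overwrite an existing directory.
#' @return (invisibly) the simulated objects with a `paths` element.
#' @export
fixture_suite <- function(name = c("tiny", "null", "confounded",
                                   "planted_motif", "planted_network"),
                          dir, seed = 1L, force = FALSE) {
  name <- match.arg(name)
  if (dir.exists(dir)) {
    if (!force) stop("directory exists (use force = TRUE): ", dir)
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)
  if (name == "planted_network") {
    return(invisible(.network_fixture(dir, seed)))
  }
  cfg <- switch(name,
    tiny = sim_config(seed = seed, n_genes = 12L,
                      peaks_per_gene = c(2L, 4L), effect_frac = 0.2,
                      decoy_frac = 0.1),
    null = sim_config(seed = seed, n_genes = 1250L,
                      peaks_per_gene = c(4L, 4L), exons_per_gene = c(1L, 1L),
                      exon_len = c(600L, 800L),
                      intergenic_gap = c(100L, 200L),
                      effect_frac = 0, with_sequence = FALSE,
                      peak_mean = 100),
    confounded = sim_config(seed = seed, n_genes = 500L,
                            peaks_per_gene = c(4L, 4L),
                            exons_per_gene = c(1L, 1L),
                            exon_len = c(600L, 800L),
                            intergenic_gap = c(100L, 200L),
                            effect_frac = 0, host_shift_frac = 0.25,
                            host_shift_log2 = 1, with_sequence = FALSE,
                            peak_mean = 100),
    planted_motif = sim_config(seed = seed, n_genes = 125L,
                               peaks_per_gene = c(4L, 4L),
                               exons_per_gene = c(1L, 1L),
                               peak_len = c(40L, 80L),
                               exon_len = c(700L, 900L),
                               intergenic_gap = c(200L, 400L),
                               motif = example_motifs()$GTGG,
                               motif_rate = 0.9, effect_frac = 0.3))
  sim <- simulate_experiment(cfg)
  paths <- list(dir = dir)
  if (!is.null(sim$genome)) {
    paths$genome <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genome), paths$genome)
  }
  paths$annotation <- file.path(dir, "annotation.gtf")
  write_gene_annotation(sim$genes, paths$annotation)
  paths$counts <- file.path(dir, "counts.tsv")
  paths$samples <- file.path(dir, "samples.tsv")
  write_count_table(sim$counts, paths$counts, paths$samples)
  paths$gene_expr <- file.path(dir, "gene_expression.tsv")
  utils::write.table(
    data.frame(feature_id = rownames(sim$gene_expr$counts),
               as.data.frame(sim$gene_expr$counts, check.names = FALSE)),
    paths$gene_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$peak_beds <- vapply(names(sim$per_sample_peaks), function(nm) {
    p <- file.path(dir, paste0("peaks_", nm, ".bed"))
    write_peaks(sim$per_sample_peaks[[nm]], p)
    p
  }, "")
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(preset = name, seed = seed,
         peaks = sim$truth$peaks, genes = sim$truth$genes,
         motif = sim$truth$motif),
    paths$truth, auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    c(list(preset = name), lapply(unclass(cfg), function(x) {
      if (methods::is(x, "motif_model")) x$motif_id else x
    })),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  sim$paths <- paths
  invisible(sim)
}

.network_fixture <- function(dir, seed) {
  set.seed(seed)
  universe <- sprintf("gene_%04d", 1:200)
  rbps <- sprintf("RBP_%d", 1:4)
  root <- "ROOT_RBP"
  # every downstream RBP is a direct target of the root; each has a
  # distinct target repertoire within the universe
  target_map <- stats::setNames(lapply(rbps, function(r) {
    sort(sample(universe, sample(20:40, 1)))
  }), rbps)
  degs <- sort(sample(universe, 30))
  edges <- do.call(rbind, lapply(rbps, function(r) {
    hit <- intersect(degs, target_map[[r]])
    if (!length(hit)) return(NULL)
    data.frame(source = r, target = hit, stringsAsFactors = FALSE)
  }))
  truth <- list(root = root, rbps = rbps, degs = degs,
                universe = universe, target_map = target_map,
                root_targets = rbps,   # all four RBPs are root targets
                planted_edges = rbind(
                  data.frame(source = root, target = rbps,
                             stringsAsFactors = FALSE),
                  edges),
                seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, paths = list(
    dir = dir, truth = file.path(dir, "truth.json"))))
}

#' Load a fixture bundle from disk
#'
#' @param dir directory written by [fixture_suite()].
#' @return list with `per_sample_peaks`, `counts`, `gene_expr`, `genes`,
#'   `genome` (when present) and `truth`.
#' @export
load_fixture <- function(dir) {
  genes <- read_gene_annotation(file.path(dir, "annotation.gtf"))
  counts <- read_count_table(file.path(dir, "counts.tsv"),
                             file.path(dir, "samples.tsv"))
  ge_tab <- utils::read.table(file.path(dir, "gene_expression.tsv"),
                              header = TRUE, sep = "\t",
                              check.names = FALSE)
  rownames(ge_tab) <- ge_tab$feature_id
  ge_tab$feature_id <- NULL
  in_samples <- counts$samples[counts$samples$assay == "input", ,
                               drop = FALSE]
  gene_expr <- count_table(as.matrix(ge_tab)[, in_samples$name,
                                             drop = FALSE], in_samples)
  beds <- list.files(dir, pattern = "^peaks_.*\\.bed$", full.names = TRUE)
  per_sample <- stats::setNames(lapply(beds, read_peaks),
                                sub("^peaks_(.*)\\.bed$", "\\1",
                                    basename(beds)))
  genome_path <- file.path(dir, "genome.fa")
  genome <- if (file.exists(genome_path)) {
    x <- Biostrings::readDNAStringSet(genome_path)
    stats::setNames(as.character(x), sub(" .*", "", names(x)))
  } else NULL
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(per_sample_peaks = per_sample, counts = counts,
       gene_expr = gene_expr, genes = genes, genome = genome,
       truth = truth)
}
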