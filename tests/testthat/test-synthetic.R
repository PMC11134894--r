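test_that("simulated annotation is structurally valid and round trips", {
  cfg <- sim_config(seed = 5, n_genes = 15)
  g <- simulate_genome(cfg)
  expect_length(g$genes, 15)
  for (gm in g$genes) {
    expect_true(all(gm$exons[, 2] > gm$exons[, 1]))
    if (nrow(gm$exons) > 1) {
      expect_equal(unname(gm$introns[, 1]),
                   unname(gm$exons[-nrow(gm$exons), 2]))
      expect_equal(unname(gm$introns[, 2]), unname(gm$exons[-1, 1]))
    } else {
      expect_equal(nrow(gm$introns), 0)
    }
  }
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gene_annotation(g$genes, f)
  back <- read_gene_annotation(f)
  expect_equal(length(back), length(g$genes))
  expect_equal(back$gene_0001$exons, g$genes$gene_0001$exons)
  # single-exon config emits no introns anywhere
  g1 <- simulate_genome(sim_config(seed = 6, n_genes = 5,
                                   exons_per_gene = c(1, 1)))
  expect_true(all(vapply(g1$genes, function(x) nrow(x$introns), 0L) == 0))
})

test_that("background sequence composition is near-uniform", {
  cfg <- sim_config(seed = 9, n_genes = 40, exons_per_gene = c(2, 3),
                    exon_len = c(800, 1200), intron_len = c(800, 1200))
  g <- simulate_genome(cfg)
  s <- g$genome[["chr1"]]
  expect_gt(nchar(s), 1.5e5)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("identical seeds give byte-identical bundles", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fixture_suite("tiny", file.path(d1, "fx"), seed = 12)
  fixture_suite("tiny", file.path(d2, "fx"), seed = 12)
  f1 <- sort(list.files(file.path(d1, "fx")))
  expect_equal(f1, sort(list.files(file.path(d2, "fx"))))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, "fx", f)),
                     readLines(file.path(d2, "fx", f)), label = f)
  }
  expect_error(fixture_suite("tiny", file.path(d1, "fx"), seed = 12),
               "exists")
})

test_that("counts track the generative means and planted effects have the right sign", {
  cfg <- sim_config(seed = 15, n_genes = 100, peaks_per_gene = c(4, 4),
                    exons_per_gene = c(1, 1), exon_len = c(600, 800),
                    effect_frac = 0.3, effect_log2fc = 1.5,
                    with_sequence = FALSE, reps = 6)
  sim <- simulate_experiment(cfg)
  ep <- sim$counts$counts[, sim$counts$samples$assay == "eprint"]
  mu <- sim$truth$true_mu
  # empirical counts match the recorded per-peak true means
  expect_gt(cor(as.vector(ep), as.vector(mu)), 0.9)
  rel_err <- abs(rowMeans(ep) - rowMeans(mu)) / rowMeans(mu)
  expect_lt(median(rel_err), 0.25)
  # planted enhanced/reduced peaks show the planted direction empirically
  cond <- sim$counts$samples$condition[sim$counts$samples$assay == "eprint"]
  ratio <- log2(rowMeans(ep[, cond == "treat"]) + 1) -
    log2(rowMeans(ep[, cond == "ctrl"]) + 1)
  tr <- sim$truth$peaks
  expect_gt(mean(ratio[tr$log2fc > 0]), 0.8)
  expect_lt(mean(ratio[tr$log2fc < 0]), -0.8)
  expect_lt(abs(mean(ratio[tr$log2fc == 0])), 0.2)
})

test_that("NB count noise is consistent with the configured dispersion", {
  cfg <- sim_config(seed = 25, n_genes = 500, peaks_per_gene = c(4, 4),
                    exons_per_gene = c(1, 1), exon_len = c(600, 800),
                    with_sequence = FALSE, depth_sd = 0, expr_bio_sd = 0,
                    gene_expr_sd = 0, peak_mean_sd = 0, dispersion = 0.2)
  sim <- simulate_experiment(cfg)
  ep <- sim$counts$counts[, sim$counts$samples$assay == "eprint"]
  # all peaks share one mean by construction; pool across peaks x samples
  x <- as.vector(ep)
  m <- mean(x); v <- var(x)
  alpha_hat <- (v - m) / m^2
  expect_lt(abs(alpha_hat - 0.2) / 0.2, 0.1)
})

test_that("ground-truth effect peaks survive the cascade", {
  sim <- fixture_suite("tiny", withr::local_tempfile(), seed = 33)
  cas <- run_cascade(sim$per_sample_peaks, sim$counts, sim$gene_expr,
                     sim$genes)
  eff <- sim$truth$peaks[sim$truth$peaks$is_effect, ]
  eff_gr <- peaks(eff$chrom, eff$start, eff$end, eff$strand,
                  peak_id = eff$peak_id)
  hits <- GenomicRanges::findOverlaps(eff_gr, cas$peaks)
  expect_equal(length(unique(S4Vectors::queryHits(hits))), nrow(eff))
})

test_that("planted motif instances sit at the anchor in carrier peaks", {
  sim <- fixture_suite("planted_motif", withr::local_tempfile(), seed = 44)
  carriers <- sim$truth$motif$peak_id
  expect_gt(length(carriers), 100)
  gr <- sim$true_peaks[S4Vectors::mcols(sim$true_peaks)$peak_id %in% carriers]
  seqs <- anchor_window_sequences(gr, sim$genome, flank = 0, extra = 6)
  sc <- score_windows(example_motifs()$GTGG, seqs, 1)
  expect_gt(mean(sc >= 0.8), 0.85)   # 0.05 mutation rate erodes a few
})

test_that("bundles reload into equivalent objects", {
  dir <- withr::local_tempfile()
  sim <- fixture_suite("tiny", dir, seed = 3)
  b <- load_fixture(dir)
  expect_equal(sort(names(b$per_sample_peaks)),
               sort(names(sim$per_sample_peaks)))
  expect_equal(b$counts$counts, sim$counts$counts)
  expect_equal(length(b$genes), length(sim$genes))
  expect_equal(b$genome, sim$genome)
  expect_equal(nrow(b$truth$peaks), nrow(sim$truth$peaks))
})
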