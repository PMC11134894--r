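test_that("CLIP proximity uses inclusive edge-to-edge distance, strand-aware", {
  clip <- peaks("chr1", 1000, 1100, "+", peak_id = "clip1")
  q <- peaks("chr1", c(1250, 1350, 1050, 800, 1250),
             c(1300, 1400, 1070, 900, 1300),
             c("+", "+", "+", "+", "-"),
             peak_id = c("gap150", "gap250", "overlap", "gap100", "wrong_strand"))
  ps <- proximity_peakset(q, clip, max_gap = 200)
  expect_setequal(ps$peak_ids, c("gap150", "overlap", "gap100"))
  # boundary: a gap of exactly max_gap is included
  q2 <- peaks("chr1", 1300, 1350, "+", peak_id = "exact")
  expect_equal(proximity_peakset(q2, clip, max_gap = 200)$peak_ids, "exact")
  expect_length(proximity_peakset(q2, clip, max_gap = 199)$peak_ids, 0)
  expect_warning(out <- proximity_peakset(q, clip[0]), "empty")
  expect_length(out$peak_ids, 0)
})

test_that("proximity matches a quadratic all-pairs distance oracle", {
  q <- random_peak_grs(250, seed = 61)
  clip <- random_peak_grs(250, seed = 62)
  ps <- proximity_peakset(q, clip, max_gap = 200)
  # oracle: explicit pairwise gap on 0-based half-open intervals
  qdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(q)),
                    start = BiocGenerics::start(q) - 1L,
                    end = BiocGenerics::end(q),
                    strand = as.character(BiocGenerics::strand(q)))
  cdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(clip)),
                    start = BiocGenerics::start(clip) - 1L,
                    end = BiocGenerics::end(clip),
                    strand = as.character(BiocGenerics::strand(clip)))
  near <- vapply(seq_len(nrow(qdf)), function(i) {
    same <- cdf$chrom == qdf$chrom[i] & cdf$strand == qdf$strand[i]
    if (!any(same)) return(FALSE)
    gap <- pmax(cdf$start[same] - qdf$end[i], qdf$start[i] - cdf$end[same], 0)
    any(gap <= 200)
  }, TRUE)
  expect_setequal(ps$peak_ids, S4Vectors::mcols(q)$peak_id[near])
  # max_gap = 0 reduces to strand-aware overlap (adjacency counts as gap 0)
  ps0 <- proximity_peakset(q, clip, max_gap = 0)
  near0 <- vapply(seq_len(nrow(qdf)), function(i) {
    same <- cdf$chrom == qdf$chrom[i] & cdf$strand == qdf$strand[i]
    any(pmax(cdf$start[same] - qdf$end[i],
             qdf$start[i] - cdf$end[same], 0) == 0)
  }, TRUE)
  expect_setequal(ps0$peak_ids, S4Vectors::mcols(q)$peak_id[near0])
})

make_overlap_input <- function() {
  # 100 genes; 10 genes carry an enhanced peak, of which 6 are CLIP targets
  hosts <- setNames(sprintf("g%03d", 1:100), sprintf("pk%03d", 1:100))
  res <- data.frame(peak_id = names(hosts), log2fc = 0, se = 1, wald = 0,
                    p = 1, padj = 1, converged = TRUE)
  up <- 1:10
  res$log2fc[up] <- 2; res$wald[up] <- 8; res$p[up] <- 1e-8
  res$padj <- p.adjust(res$p, "BH")
  clip <- c(sprintf("g%03d", 1:6), sprintf("g%03d", 50:63))
  list(res = res, hosts = hosts, clip = clip)
}

test_that("gene-level overlap fold enrichment and p match the closed form", {
  x <- make_overlap_input()
  ov <- gene_level_overlap(x$res, x$hosts, x$clip, preset = "fus")
  up <- ov[ov$group == "UP", ]
  expect_equal(up$n_group_genes, 10)
  expect_equal(up$n_clip_targets, 20)
  expect_equal(up$n_overlap, 6)
  expect_equal(up$fold_enrichment, 6 / (10 * 20 / 100))
  expect_equal(up$p, hyper_oracle_upper(6, 20, 80, 10), tolerance = 1e-12)
  dn <- ov[ov$group == "DOWN", ]
  expect_equal(dn$n_overlap, 0)
  expect_equal(dn$p, 1)
  # group covering the whole universe has fold 1 and p ~ 1
  res_all <- x$res; res_all$log2fc <- 2; res_all$wald <- 8
  res_all$p <- 1e-8; res_all$padj <- 1e-8
  ov2 <- gene_level_overlap(res_all, x$hosts, x$clip)
  upall <- ov2[ov2$group == "UP", ]
  expect_equal(upall$fold_enrichment, 1)
  expect_equal(upall$p, 1, tolerance = 1e-9)
})

test_that("genes with peaks in both directions drop out of the ONLY groups", {
  hosts <- setNames(rep(sprintf("g%02d", 1:10), each = 2),
                    sprintf("pk%02d", 1:20))
  res <- data.frame(peak_id = names(hosts), log2fc = 0, se = 1, wald = 0,
                    p = 1, padj = 1, converged = TRUE)
  # g01: up+down; g02: up only; g03: down only
  res[res$peak_id == "pk01", c("log2fc", "wald", "p", "padj")] <-
    list(2, 8, 1e-9, 1e-8)
  res[res$peak_id == "pk02", c("log2fc", "wald", "p", "padj")] <-
    list(-2, -8, 1e-9, 1e-8)
  res[res$peak_id == "pk03", c("log2fc", "wald", "p", "padj")] <-
    list(2, 8, 1e-9, 1e-8)
  res[res$peak_id == "pk05", c("log2fc", "wald", "p", "padj")] <-
    list(-2, -8, 1e-9, 1e-8)
  ov <- gene_level_overlap(res, hosts, clip_target_genes = "g01")
  g <- function(grp) ov[ov$group == grp, ]
  expect_equal(g("UP")$n_group_genes, 2)        # g01, g02
  expect_equal(g("DOWN")$n_group_genes, 2)      # g01, g03
  expect_equal(g("UP_ONLY")$n_group_genes, 1)   # g02
  expect_equal(g("DOWN_ONLY")$n_group_genes, 1) # g03
  # partition: UP_ONLY + DOWN_ONLY + both = UP union DOWN
  expect_equal(g("UP_ONLY")$n_group_genes + g("DOWN_ONLY")$n_group_genes + 1,
               length(union(c("g01", "g02"), c("g01", "g03"))))
})

test_that("planted layered networks are recovered exactly with the truth caller", {
  set.seed(71)
  universe <- sprintf("g%03d", 1:200)
  rbps <- paste0("RBP", 1:4)
  target_map <- setNames(lapply(rbps, function(r) sample(universe, 30)), rbps)
  degs <- sort(sample(universe, 30))
  net <- build_network("ROOT", root_clip_targets = rbps,
                       changed_rbps = rbps, degs = degs,
                       target_caller = function(r) target_map[[r]],
                       evidence = "motif")
  planted <- do.call(rbind, lapply(rbps, function(r) {
    hit <- intersect(degs, target_map[[r]])
    if (!length(hit)) return(NULL)
    data.frame(source = r, target = hit)
  }))
  planted <- rbind(data.frame(source = "ROOT", target = rbps), planted)
  got <- net$edges[order(net$edges$source, net$edges$target),
                   c("source", "target")]
  want <- planted[order(planted$source, planted$target), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expect_equal(net$n_degs_linked,
               length(unique(planted$target[planted$source != "ROOT"])))
  # DEGs disjoint from every target set link nothing
  net0 <- build_network("ROOT", rbps, rbps, degs = c("absent1", "absent2"),
                        target_caller = function(r) target_map[[r]])
  expect_equal(net0$n_degs_linked, 0)
  w <- capture_warnings(
    build_network("ROOT", rbps, rbps, degs,
                  target_caller = function(r) NULL))
  expect_true(any(grepl("no target data", w)))
})

test_that("random-gene null behaves at the extremes and reproduces", {
  universe <- sprintf("g%03d", 1:100)
  builder_all <- function(genes) {
    build_network("ROOT", "RBP1", "RBP1", genes,
                  target_caller = function(r) universe)
  }
  sim <- random_gene_simulation(universe, observed_linked = 10,
                                network_builder = builder_all,
                                n_genes = 10, n_reps = 50, seed = 3) |>
    suppressWarnings()
  expect_true(all(sim$linked_counts == 10))   # every gene is a target
  expect_equal(sim$empirical_p, (1 + 50) / 51)
  exp_warn <- expect_warning(
    random_gene_simulation(universe, 10, builder_all, 10, n_reps = 50,
                           seed = 3), "unstable")
  sim2 <- suppressWarnings(random_gene_simulation(
    universe, 10, builder_all, 10, n_reps = 50, seed = 3))
  expect_identical(sim$linked_counts, sim2$linked_counts)
})
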