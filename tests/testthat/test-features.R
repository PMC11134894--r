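# geneA (+): exons [100,200) [300,400) [600,800), utr5 [100,130), utr3 [740,800)
# geneB (-): single exon [1000,1500), utr5 [1450,1500), utr3 [1000,1080)

test_that("peaks classify by where start and end sites fall, strand-orientated", {
  genes <- toy_genes()
  gr <- peaks("chr1",
              start = c(140, 150, 210, 320, 110, 750, 1100, 1460, 140, 1010),
              end   = c(180, 320, 290, 590, 125, 790, 1200, 1490, 180, 1070),
              strand = c("+", "+", "+", "+", "+", "+", "-", "-", "-", "-"),
              peak_id = sprintf("q%02d", 1:10),
              host_gene = c(rep("geneA", 6), rep("geneB", 4)))
  got <- as.character(classify_peaks(gr, genes))
  expect_equal(got[1], "EX")      # both sites in exon1
  expect_equal(got[2], "EX_EX")   # exon1 -> exon2
  expect_equal(got[3], "IN")      # both in intron1
  expect_equal(got[4], "EX_IN")   # exon2 -> intron2
  expect_equal(got[5], "UTR5")    # both inside the 5' UTR
  expect_equal(got[6], "UTR3")
  expect_equal(got[7], "EX")      # geneB body, - strand
  expect_equal(got[8], "UTR5")    # geneB 5' UTR sits at the right end (-)
  # a minus-strand peak inside geneA (+) has no host -> intergenic
  expect_equal(got[9], "INTERGENIC")
  expect_equal(got[10], "UTR3")
})

test_that("junction orientation distinguishes EX_IN from IN_EX on the minus strand", {
  genes <- list(gm = gene_model("gm", "chr1", "-",
                                exons = cbind(c(0, 500), c(200, 800))))
  # intron is [200,500). On '-', the 5' anchor is the interval end-1.
  # peak [150,300): anchor 299 (intron), other end 150 (exon1) -> IN_EX
  # peak [400,600): anchor 599 (exon2), other end 400 (intron) -> EX_IN
  gr <- peaks("chr1", c(150, 400), c(300, 600), "-",
              peak_id = c("pA", "pB"), host_gene = "gm")
  expect_equal(as.character(classify_peaks(gr, genes)), c("IN_EX", "EX_IN"))
  # the same intervals on a '+' gene flip category
  genes_p <- list(gm = gene_model("gm", "chr1", "+",
                                  exons = cbind(c(0, 500), c(200, 800))))
  gr_p <- peaks("chr1", c(150, 400), c(300, 600), "+",
                peak_id = c("pA", "pB"), host_gene = "gm")
  expect_equal(as.character(classify_peaks(gr_p, genes_p)),
               c("EX_IN", "IN_EX"))
})

test_that("classification is a partition and invariant under translation", {
  genes <- toy_genes()
  set.seed(13)
  st <- sample(100:1400, 120, replace = TRUE)
  gr <- peaks("chr1", st, st + sample(20:120, 120, replace = TRUE),
              sample(c("+", "-"), 120, replace = TRUE),
              peak_id = sprintf("r%03d", 1:120))
  gr <- assign_host_gene(gr, genes)
  cats <- classify_peaks(gr, genes)
  expect_equal(sum(table(cats)), length(gr))      # exactly one category each
  expect_equal(sum(table(cats)[setdiff(FEATURE_CATEGORIES, "INTERGENIC")]),
               length(intragenic(gr)))
  # translate gene models and peaks by a constant: categories unchanged
  shift <- 10000L
  genes_t <- lapply(genes, function(g) {
    gene_model(g$gene_id, g$chrom, g$strand, g$exons + shift,
               if (nrow(g$utr5)) g$utr5 + shift else NULL,
               if (nrow(g$utr3)) g$utr3 + shift else NULL)
  })
  gr_t <- peaks("chr1", BiocGenerics::start(gr) - 1L + shift,
                BiocGenerics::end(gr) + shift,
                as.character(BiocGenerics::strand(gr)),
                peak_id = S4Vectors::mcols(gr)$peak_id,
                host_gene = S4Vectors::mcols(gr)$host_gene)
  expect_equal(as.character(classify_peaks(gr_t, genes_t)),
               as.character(cats))
})

test_that("feature densities are peaks per 100 kb and split-invariant", {
  genes <- list(g = gene_model("g", "chr1", "+", cbind(0, 2000),
                               utr5 = cbind(0, 1000)))
  cats <- factor(c(p1 = "UTR5", p2 = "UTR5"), levels = FEATURE_CATEGORIES)
  d <- feature_density(cats, genes)
  expect_equal(d$per_100kb[d$feature == "UTR5"], 200)   # 2 per 1000 bp
  expect_equal(d$n_peaks[d$feature == "EX"], 0)
  # splitting the UTR into adjacent pieces leaves the density unchanged
  genes2 <- list(g = gene_model("g", "chr1", "+", cbind(0, 2000),
                                utr5 = cbind(c(0, 400), c(400, 1000))))
  expect_equal(feature_density(cats, genes2), d)
})

test_that("random backgrounds match per-class counts, stay inside features and reproduce", {
  genes <- toy_genes()
  set.seed(55)
  st <- sample(100:1400, 80, replace = TRUE)
  gr <- peaks("chr1", st, st + 30, sample(c("+", "-"), 80, replace = TRUE),
              peak_id = sprintf("t%03d", 1:80))
  gr <- assign_host_gene(gr, genes)
  cats <- classify_peaks(gr, genes)
  bg <- random_peak_background(genes, gr, cats, multiplier = 10, seed = 4)
  obs <- table(factor(cats, c("UTR5", "EX", "IN", "UTR3")))
  got <- table(factor(S4Vectors::mcols(bg)$class, c("UTR5", "EX", "IN", "UTR3")))
  expect_equal(as.integer(got), as.integer(obs) * 10L)
  # containment: every drawn peak lies within an interval of its class
  for (cl in names(obs)[obs > 0]) {
    iv <- eprinttools:::feature_intervals(genes, cl)
    sub <- bg[S4Vectors::mcols(bg)$class == cl]
    inside <- vapply(seq_along(sub), function(i) {
      any(iv$start <= BiocGenerics::start(sub)[i] - 1 &
            BiocGenerics::end(sub)[i] <= iv$end)
    }, TRUE)
    expect_true(all(inside))
  }
  bg2 <- random_peak_background(genes, gr, cats, multiplier = 10, seed = 4)
  expect_identical(as.data.frame(bg), as.data.frame(bg2))
})
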