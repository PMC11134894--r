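test_that("median-of-ratios size factors behave on constructed columns", {
  m <- matrix(rpois(400, 100), 100, 4,
              dimnames = list(sprintf("p%d", 1:100), letters[1:4]))
  m[, 2] <- m[, 1]; m[, 3] <- m[, 1]; m[, 4] <- m[, 1]
  expect_equal(unname(estimate_size_factors(m)), rep(1, 4))
  m2 <- m; m2[, 4] <- m[, 4] * 2L
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[4] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(unname(estimate_size_factors(m[, 1, drop = FALSE])), 1)
  zero <- matrix(c(0L, 5L, 5L, 0L), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_warning(estimate_size_factors(zero), "library-size")
})

test_that("host-expression offsets reduce to size factors for flat hosts and floor at the pseudocount", {
  samples <- data.frame(
    name = c("ep1", "ep2", "in1", "in2"),
    assay = c("eprint", "eprint", "input", "input"),
    condition = c("a", "b", "a", "b"), batch = NA, library_size = 1e6)
  ge <- count_table(matrix(c(100L, 100L, 0L, 0L), 2, 2, byrow = TRUE,
                           dimnames = list(c("gFlat", "gZero"),
                                           c("in1", "in2"))),
                    samples[3:4, ])
  hosts <- c(pk1 = "gFlat", pk2 = "gZero")
  sf <- c(ep1 = 1, ep2 = 2)
  sm <- match_input_samples(samples)
  off <- build_offsets(sf, ge, hosts, sm)
  # flat host: offsets are log sf plus a row-constant expression term
  expect_equal(off["pk1", ] - log(sf), c(ep1 = log(100), ep2 = log(100)))
  # zero-expression host floored at 0.5
  expect_equal(off["pk2", ] - log(sf), c(ep1 = log(0.5), ep2 = log(0.5)))
  expect_error(build_offsets(sf, ge, c(pk1 = "missing"), sm), "absent")
})

test_that("footprint samples pair with inputs by condition, batch and replicate order", {
  samples <- data.frame(
    name = c("epA1", "epA2", "epB1", "inA1", "inA2", "inB1"),
    assay = c("eprint", "eprint", "eprint", "input", "input", "input"),
    condition = c("a", "a", "b", "a", "a", "b"),
    batch = NA, library_size = 1)
  m <- match_input_samples(samples)
  expect_equal(m, c(epA1 = "inA1", epA2 = "inA2", epB1 = "inB1"))
  expect_error(match_input_samples(samples[-6, ]), "no matching input")
})

test_that("dispersion estimates track the generative regime", {
  groups <- factor(rep(c("a", "b"), each = 4))
  off <- matrix(0, 1000, 8)
  set.seed(21)
  pois <- matrix(rpois(8000, 100), 1000, 8,
                 dimnames = list(sprintf("p%d", 1:1000), NULL))
  d <- estimate_dispersion(pois, off, groups)
  expect_lt(median(d$alpha), 0.01)
  nb <- matrix(rnbinom(8000, mu = 100, size = 1 / 0.2), 1000, 8,
               dimnames = list(sprintf("p%d", 1:1000), NULL))
  d2 <- estimate_dispersion(nb, off, groups)
  expect_gt(median(d2$alpha), 0.1)
  expect_lt(median(d2$alpha), 0.4)
  cst <- matrix(50L, 10, 8, dimnames = list(sprintf("c%d", 1:10), NULL))
  d3 <- estimate_dispersion(cst, off[1:10, ], groups)
  expect_true(all(d3$alpha_mom <= 0))    # clamped toward the floor/trend
  zr <- rbind(pois[1:20, ], zero = 0L)
  d4 <- estimate_dispersion(zr, off[1:21, ], groups)
  expect_true(d4$all_zero[21])
  expect_error(estimate_dispersion(pois[, 1:2], off[, 1:2],
                                   factor(c("a", "b"))), ">= 2 samples")
})

test_that("NB GLM recovers exact fold changes in the Poisson limit", {
  X <- cbind(1, rep(c(0, 1), each = 2))
  colnames(X) <- c("(Intercept)", "conditionb")
  y <- c(100, 100, 200, 200)
  fit <- fit_nb_glm(y, X, offset = rep(0, 4), alpha = 1e-8)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta[2]), log(2), tolerance = 1e-6)
  # confounded design is a rank error
  Xbad <- cbind(1, c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_error(fit_nb_glm(y, Xbad, rep(0, 4), 0.1), "full rank")
})

test_that("Wald p-values are two-sided normal with BH adjustment over all peaks", {
  p_in <- c(0.01, 0.02, 0.03, 0.04)
  fits <- data.frame(feature_id = paste0("p", 1:4),
                     beta = qnorm(1 - p_in / 2), se = 1, base_mean = 10,
                     converged = TRUE)
  res <- wald_and_adjust(fits)
  expect_equal(res$p, p_in, tolerance = 1e-12)
  expect_equal(res$padj, rep(0.04, 4), tolerance = 1e-12)
  expect_true(all(res$padj >= res$p))
  one <- wald_and_adjust(fits[1, ])
  expect_equal(one$padj, one$p)
  expect_equal(res$wald, res$log2fc / res$se, tolerance = 1e-12)
})

test_that("significance presets apply the published thresholds", {
  expect_equal(significance_preset("fus"), list(padj = 0.05, lfc = 1))
  expect_equal(significance_preset("mn"), list(padj = 0.01, lfc = 1))
  res <- data.frame(peak_id = c("a", "b", "c"),
                    log2fc = c(2, -2, 0.5), se = 1, wald = c(8, -8, 2),
                    p = c(1e-8, 1e-8, 0.04), padj = c(1e-7, 1e-7, 0.04),
                    converged = TRUE)
  sig <- significant_peaks(res, "fus")
  expect_equal(sig$peak_id, c("a", "b"))
  expect_equal(sig$direction, c("enhanced", "reduced"))
})

test_that("input DE recovers planted 2x genes and excludes silent genes", {
  set.seed(31)
  n_g <- 300
  # two conditions x two replicates in each of two batches (8 samples)
  cond <- rep(rep(c("a", "b"), each = 2), 2)
  batch <- rep(c("b1", "b2"), each = 4)
  samples <- data.frame(
    name = sprintf("in_%s_%s_r%d", cond, batch, rep(1:2, 4)),
    assay = "input", condition = cond, batch = batch, library_size = 1e6)
  mu <- matrix(200, n_g, 8)
  planted <- 1:50   # 25 up, 25 down: balanced so normalisation stays anchored
  mu[1:25, cond == "b"] <- 400
  mu[26:50, cond == "b"] <- 100
  mu[, batch == "b2"] <- mu[, batch == "b2"] * 1.3   # batch effect
  cnt <- matrix(rnbinom(n_g * 8, mu = mu, size = 1 / 0.05), n_g, 8,
                dimnames = list(sprintf("g%03d", 1:n_g), samples$name))
  cnt[n_g, ] <- 0L
  ge <- count_table(cnt, samples)
  res <- deg_on_input(ge)
  expect_equal(attr(res, "excluded"), sprintf("g%03d", n_g))
  hit <- res$padj[match(sprintf("g%03d", planted), res$peak_id)] < 0.05
  expect_gte(mean(hit, na.rm = TRUE), 0.8)
  null_p <- res$p[!res$peak_id %in% sprintf("g%03d", planted)]
  expect_lt(mean(null_p < 0.05, na.rm = TRUE), 0.12)
})

test_that("fold-change estimates agree with DESeq2 on a plain design", {
  skip_if_not_installed("DESeq2")
  set.seed(41)
  n <- 200
  mu <- matrix(150, n, 4)
  mu[1:40, 3:4] <- 450
  cnt <- matrix(rnbinom(n * 4, mu = mu, size = 10), n, 4,
                dimnames = list(sprintf("p%03d", 1:n),
                                sprintf("s%d", 1:4)))
  samples <- data.frame(name = sprintf("s%d", 1:4), assay = "eprint",
                        condition = rep(c("a", "b"), each = 2),
                        batch = NA, library_size = 1e6)
  ct <- count_table(cnt, samples)
  mine <- differential_binding(ct, gene_expr = NULL, use_offsets = FALSE)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, data.frame(condition = factor(rep(c("a", "b"), each = 2))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  expect_gt(cor(mine$log2fc, ref$log2FoldChange, use = "complete.obs"),
            0.98)
  expect_gt(cor(sign(mine$wald) * -log10(mine$p),
                sign(ref$stat) * -log10(ref$pvalue),
                use = "complete.obs"), 0.9)
})

test_that("signed-Wald ranking is a strict total order with id tie-break", {
  res <- data.frame(peak_id = c("b", "a", "c", "d"),
                    log2fc = c(1, 1, -1, 0), se = 1,
                    wald = c(2, 2, -3, 0), p = 0.5, padj = 0.5,
                    converged = TRUE)
  rk <- ranked_peaks(res)
  expect_equal(rk$peak_id, c("a", "b", "d", "c"))
  expect_false(any(duplicated(rk$peak_id)))
})
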