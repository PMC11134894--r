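# Shared builders and independent oracles used across the suite.

# a two-gene toy annotation: gene A (+, 3 exons with UTRs), gene B (-, 1 exon)
toy_genes <- function() {
  list(
    geneA = gene_model("geneA", "chr1", "+",
                       exons = cbind(c(100, 300, 600), c(200, 400, 800)),
                       utr5 = cbind(100, 130), utr3 = cbind(740, 800)),
    geneB = gene_model("geneB", "chr1", "-",
                       exons = cbind(1000, 1500),
                       utr5 = cbind(1450, 1500), utr3 = cbind(1000, 1080)))
}

# brute-force merge oracle: connected components of the same-strand overlap
# graph, unions and distinct-sample support counted directly
merge_oracle <- function(per_sample_peaks, min_support = 2L) {
  df <- do.call(rbind, lapply(seq_along(per_sample_peaks), function(i) {
    gr <- per_sample_peaks[[i]]
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               sample = i)
  }))
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ov <- df$chrom[i] == df$chrom[j] & df$strand[i] == df$strand[j] &
        df$start[i] < df$end[j] & df$start[j] < df$end[i]
      if (ov && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    sub <- df[comp == cc, ]
    data.frame(chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), strand = sub$strand[1],
               support = length(unique(sub$sample)))
  }))
  out <- out[out$support >= min_support, , drop = FALSE]
  out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
}

# full-walk GSEA oracle: the O(N) running sum, evaluated at every position
gsea_oracle <- function(stat, hit, N = length(stat)) {
  # stat must already be sorted decreasing; hit is logical of length N
  w <- abs(stat)
  Wh <- sum(w[hit])
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) {
      if (Wh > 0) w[i] / Wh else 1 / sum(hit)
    } else -1 / (N - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# exhaustive hypergeometric oracle: upper-tail P[X >= q] by summing exact
# combinatorial terms (independent of phyper)
hyper_oracle_upper <- function(q, m, n, k) {
  xs <- max(q, 0):min(m, k)
  if (!length(xs) || q > min(m, k)) return(0)
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# genuinely exhaustive subset enumeration for tiny universes
hyper_oracle_enum <- function(q, categ, k) {
  N <- length(categ)
  sets <- utils::combn(N, k)
  mean(colSums(matrix(categ[sets], nrow = k)) >= q)
}

random_peak_grs <- function(n, seed, chroms = c("chr1", "chr2"),
                            max_pos = 10000L) {
  set.seed(seed)
  st <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(20:120, n, replace = TRUE)
  peaks(sample(chroms, n, replace = TRUE), st, st + len,
        sample(c("+", "-"), n, replace = TRUE),
        peak_id = sprintf("p%04d", seq_len(n)))
}

# hand-enumerated cascade fixture: ~30 candidate peaks with a planted
# reason for each to survive or fail a specific stage; returns inputs and
# the expected survivor coordinates
cascade_fixture <- function() {
  mk <- function(start, end, strand = "+") c(start, end, strand)
  # gene layout: three genes on +, one on -; one gene lowly expressed
  genes <- list(
    g1 = gene_model("g1", "chr1", "+", cbind(0, 3000)),
    g2 = gene_model("g2", "chr1", "+", cbind(4000, 7000)),
    g3 = gene_model("g3", "chr1", "-", cbind(8000, 11000)),
    glow = gene_model("glow", "chr1", "+", cbind(12000, 15000)))

  # true peaks: columns chrom,start,end,strand,gene,fate
  spec <- rbind(
    data.frame(start = 100 * (1:6) + 0,    gene = "g1", strand = "+",
               fate = "pass"),
    data.frame(start = 4100 + 150 * (0:5), gene = "g2", strand = "+",
               fate = "pass"),
    data.frame(start = 8100 + 150 * (0:5), gene = "g3", strand = "-",
               fate = "pass"),
    data.frame(start = 2000 + 120 * (0:2), gene = "g1", strand = "+",
               fate = "low_count"),      # cumulative footprint < 50
    data.frame(start = 5200 + 130 * (0:2), gene = "g2", strand = "+",
               fate = "not_enriched"),   # input as high as footprint
    data.frame(start = 12100 + 150 * (0:2), gene = "glow", strand = "+",
               fate = "low_gene"),       # host gene lowly expressed
    data.frame(start = 16000 + 130 * (0:2), gene = NA, strand = "+",
               fate = "intergenic"),
    data.frame(start = 9000 + 170 * (0:1), gene = "g3", strand = "+",
               fate = "wrong_strand"),   # opposite strand of host
    data.frame(start = 2500 + 200 * (0:1), gene = "g1", strand = "+",
               fate = "single_sample"))  # support 1 only
  spec$end <- spec$start + 60
  spec$peak_id <- sprintf("fx_%02d", seq_len(nrow(spec)))

  # per-sample calls: 4 footprint samples; all peaks called in samples 1-2
  # except the single-sample ones (sample 1 only)
  mk_calls <- function(s) {
    keep <- if (s <= 2) spec$fate != "single_sample" | s == 1 else
      rep(FALSE, nrow(spec))
    sub <- spec[keep, , drop = FALSE]
    if (!nrow(sub)) return(peaks("chr1", 0, 1, "+")[0])
    peaks("chr1", sub$start, sub$end, sub$strand,
          peak_id = paste0("s", s, "_", sub$peak_id))
  }
  per_sample <- list(s1 = mk_calls(1), s2 = mk_calls(2),
                     s3 = mk_calls(3)[0], s4 = mk_calls(4)[0])

  samples <- data.frame(
    name = c(paste0("ep", 1:4), paste0("in", 1:4)),
    assay = rep(c("eprint", "input"), each = 4),
    condition = rep(rep(c("a", "b"), each = 2), 2),
    batch = NA, library_size = 1e6)
  ep <- matrix(0L, nrow(spec), 4)
  inp <- matrix(0L, nrow(spec), 4)
  ep[spec$fate %in% c("pass", "intergenic", "wrong_strand",
                      "single_sample"), ] <- 40L   # cumulative 160 >= 50
  ep[spec$fate == "low_gene", ] <- 40L
  ep[spec$fate == "low_count", ] <- 10L            # cumulative 40 < 50
  ep[spec$fate == "not_enriched", ] <- 40L
  inp[spec$fate == "not_enriched", ] <- 40L        # input matches footprint
  inp[spec$fate != "not_enriched", ] <- 1L
  cnt <- cbind(ep, inp)
  rownames(cnt) <- spec$peak_id
  colnames(cnt) <- samples$name
  counts <- count_table(cnt, samples,
                        coords = spec[c("start", "end", "strand")] |>
                          transform(chrom = "chr1"))
  gene_cnt <- matrix(100L, 4, 4,
                     dimnames = list(names(genes), paste0("in", 1:4)))
  gene_cnt["glow", ] <- 5L                         # cumulative 20 < 50
  gene_expr <- count_table(gene_cnt, samples[samples$assay == "input", ])

  expected <- spec[spec$fate == "pass", c("start", "end", "strand")]
  list(per_sample_peaks = per_sample, counts = counts,
       gene_expr = gene_expr, genes = genes, spec = spec,
       expected_survivors = expected)
}
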