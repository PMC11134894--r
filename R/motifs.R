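#' Motif model (position weight matrix)
#'
#' A PWM of per-position nucleotide probabilities over the DNA alphabet
#' with an RBP attribution. RNA-alphabet input (U columns/rows) is mapped
#' to T at construction, since footprint sequences are handled on the DNA
#' alphabet.
#'
#' @param motif_id identifier (e.g. `"M151_0.6"`).
#' @param pwm L x 4 matrix of probabilities, columns `A,C,G,T` (or
#'   `A,C,G,U`); each row must sum to 1 within 1e-6; L >= 4.
#' @param rbp_names character vector of attributed RBPs.
#' @param background length-4 background frequencies (default uniform).
#' @return object of class `motif_model`.
#' @export
motif_model <- function(motif_id, pwm, rbp_names = character(),
                        background = rep(0.25, 4)) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4) stop("pwm must have 4 columns")
  cn <- toupper(colnames(pwm))
  if (is.null(colnames(pwm))) cn <- c("A", "C", "G", "T")
  cn[cn == "U"] <- "T"
  if (!identical(sort(cn), c("A", "C", "G", "T"))) {
    stop("pwm columns must be A,C,G,T/U")
  }
  colnames(pwm) <- cn
  pwm <- pwm[, c("A", "C", "G", "T"), drop = FALSE]
  if (nrow(pwm) < 4) stop("motif length must be >= 4")
  if (any(abs(rowSums(pwm) - 1) > 1e-6)) {
    stop("each pwm row must sum to 1 (tolerance 1e-6)")
  }
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  structure(list(motif_id = as.character(motif_id), pwm = pwm,
                 rbp_names = as.character(rbp_names),
                 background = stats::setNames(background,
                                              c("A", "C", "G", "T"))),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s (L=%d) RBPs: %s\n", x$motif_id,
              nrow(x$pwm), paste(x$rbp_names, collapse = ",")))
  invisible(x)
}

#' Log-odds matrix of a motif (base 2, probabilities floored at 1e-3)
#' @param motif `motif_model`.
#' @return L x 4 matrix of log2 odds against the background.
#' @export
motif_logodds <- function(motif) {
  log2(pmax(motif$pwm, 1e-3) /
         matrix(pmax(motif$background, 1e-3), nrow(motif$pwm), 4,
                byrow = TRUE))
}

#' Consensus sequence of a motif (ties broken A<C<G<T)
#' @param motif `motif_model`.
#' @return character scalar.
#' @export
motif_consensus <- function(motif) {
  paste(c("A", "C", "G", "T")[apply(motif$pwm, 1, which.max)],
        collapse = "")
}

#' Turn a plain k-mer into a degenerate motif model
#'
#' Supports k-mer motif lists (e.g. Bind-n-Seq-derived) through the same
#' scanning code path: the matched base gets probability 0.97, the others
#' 0.01 each.
#'
#' @param kmer character scalar over A,C,G,T/U.
#' @param rbp_names attribution.
#' @return `motif_model` with id `kmer_<seq>`.
#' @export
kmer_to_motif <- function(kmer, rbp_names = character()) {
  kmer <- toupper(chartr("U", "T", kmer))
  b <- strsplit(kmer, "")[[1]]
  stopifnot(all(b %in% c("A", "C", "G", "T")))
  pwm <- matrix(0.01, length(b), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- 0.97
  motif_model(paste0("kmer_", kmer), pwm, rbp_names)
}

#' Read motifs in minimal MEME format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' the alphabet may be ACGT or ACGU (U is mapped to T). RBP names are
#' taken from the alternate name field of the `MOTIF` line (comma
#' separated).
#'
#' @param path MEME-format file.
#' @return named list of `motif_model`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  out <- list()
  for (si in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[si]]), "[ \t]+")[[1]]
    id <- hdr[2]
    rbps <- if (length(hdr) >= 3) strsplit(hdr[3], ",")[[1]] else character()
    to <- if (si < length(starts)) starts[si + 1] - 1 else length(lines)
    block <- lines[starts[si]:to]
    mi <- grep("letter-probability matrix", block)
    if (!length(mi)) stop("motif ", id, ": no letter-probability matrix")
    w <- suppressWarnings(as.integer(
      sub(".*w= *([0-9]+).*", "\\1", block[mi[1]])))
    rows <- block[(mi[1] + 1):length(block)]
    rows <- rows[nzchar(trimws(rows))]
    num <- suppressWarnings(lapply(strsplit(trimws(rows), "[ \t]+"),
                                   as.numeric))
    num <- num[vapply(num, function(v) length(v) == 4 && !anyNA(v), TRUE)]
    if (is.na(w)) w <- length(num)
    if (length(num) < w) stop("motif ", id, ": truncated matrix")
    pwm <- do.call(rbind, num[seq_len(w)])
    colnames(pwm) <- c("A", "C", "G", "T")
    out[[id]] <- motif_model(id, pwm, rbps)
  }
  out
}

#' Write motifs in minimal MEME format
#' @param motifs list of `motif_model`.
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$motif_id,
                       paste(m$rbp_names, collapse = ",")), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$pwm)), con)
    writeLines(apply(m$pwm, 1, function(r) paste(sprintf("%.6f", r),
                                                 collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif from a positions-by-nucleotide matrix file
#'
#' Plain-text matrix with a header naming the nucleotide columns
#' (`A C G U` or `A C G T`, an optional leading position column) and one
#' row per motif position — the layout used by RBP motif databases that
#' distribute per-motif matrix files.
#'
#' @param path matrix file.
#' @param motif_id id (default: file base name).
#' @param rbp_names attribution.
#' @return `motif_model`.
#' @export
read_motif_matrix <- function(path, motif_id = NULL, rbp_names = character()) {
  if (is.null(motif_id)) {
    motif_id <- tools::file_path_sans_ext(basename(path))
  }
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  names(tab) <- toupper(names(tab))
  names(tab)[names(tab) == "U"] <- "T"
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(tab))) {
    stop("motif matrix must have columns A,C,G,T/U: ", path)
  }
  motif_model(motif_id, as.matrix(tab[need]), rbp_names)
}

# integer codes 1..4 for A,C,G,T; NA for anything else (score-neutral)
encode_dna <- function(seqs) {
  m <- t(vapply(strsplit(toupper(chartr("U", "T", seqs)), ""), function(b) {
    idx <- match(b, c("A", "C", "G", "T"))
    length(idx) <- max(nchar(seqs))
    idx
  }, integer(max(nchar(seqs)))))
  if (length(seqs) == 1) m <- matrix(m, nrow = 1)
  m
}

#' Relative log-odds score of a motif at one position
#'
#' Raw score: sum over motif positions of `log2(p_base / bg_base)` with
#' probabilities floored at 1e-3. The relative score rescales linearly to
#' `[0, 1]` between the minimum and maximum attainable raw scores, so 1 is
#' the consensus path and 0 the anti-consensus. Non-ACGT bases contribute
#' 0 (background-neutral).
#'
#' @param motif `motif_model`.
#' @param window_sequence sequence (length >= `position + L - 1`).
#' @param position 1-based start of the motif placement.
#' @return score in `[0, 1]`.
#' @export
relative_logodds_score <- function(motif, window_sequence, position = 1L) {
  sc <- score_windows(motif, window_sequence, position)
  sc[1, 1]
}

#' Score a motif at multiple start positions of multiple sequences
#'
#' @param motif `motif_model`.
#' @param seqs character vector of equal-length sequences.
#' @param positions 1-based start positions to score.
#' @return matrix `length(seqs)` x `length(positions)` of relative
#'   log-odds scores in `[0, 1]`.
#' @export
score_windows <- function(motif, seqs, positions) {
  lo <- motif_logodds(motif)
  L <- nrow(lo)
  lo_min <- sum(apply(lo, 1, min))
  lo_max <- sum(apply(lo, 1, max))
  codes <- encode_dna(seqs)
  if (max(positions) + L - 1 > ncol(codes)) {
    stop("sequence too short for motif at requested positions")
  }
  raw <- matrix(0, nrow(codes), length(positions))
  for (i in seq_len(L)) {
    sub <- codes[, positions + i - 1L, drop = FALSE]
    contrib <- lo[i, ][sub]           # NA bases -> NA
    contrib[is.na(contrib)] <- 0      # score-neutral
    raw <- raw + matrix(contrib, nrow(codes))
  }
  (raw - lo_min) / (lo_max - lo_min)
}

#' Extract anchor-centred window sequences in transcription orientation
#'
#' For each peak, the genomic sequence covering offsets `-flank ..
#' +flank + extra - 1` around the 5' footprint anchor, read 5'->3' along
#' the transcript (reverse-complemented for minus-strand peaks). Windows
#' running off the contig are padded with `N` (score-neutral).
#'
#' @param gr peak `GRanges`.
#' @param genome named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param flank bases on each side of the anchor.
#' @param extra extra downstream bases (use the motif length so every
#'   offset in `-flank..flank` has a full window).
#' @return character vector of sequences of length `2*flank + extra`.
#' @export
anchor_window_sequences <- function(gr, genome, flank = 100L, extra = 0L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  anchors <- peak_anchor(gr)   # 0-based
  chroms <- as.character(seqnames(gr))
  sd <- as.character(BiocGenerics::strand(gr))
  vapply(seq_along(gr), function(i) {
    chr_seq <- genome[[chroms[i]]]
    if (is.null(chr_seq)) stop("contig missing from genome: ", chroms[i])
    clen <- nchar(chr_seq)
    a <- anchors[i]
    if (sd[i] == "-") { lo <- a - flank - extra + 1L; hi <- a + flank }
    else { lo <- a - flank; hi <- a + flank + extra - 1L }
    from <- max(lo, 0L); to <- min(hi, clen - 1L)
    body <- if (from <= to) substr(chr_seq, from + 1L, to + 1L) else ""
    pad_l <- strrep("N", max(0L, -lo))
    pad_r <- strrep("N", max(0L, hi - (clen - 1L)))
    s <- paste0(pad_l, body, pad_r)
    if (sd[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, "")
}

#' Positional motif profile around peak starts
#'
#' Scans each peak for the motif at every offset of a window centred on
#' the 5' footprint anchor (offset 0), averages relative log-odds scores
#' across peaks at each offset and converts the per-offset means to
#' z-scores across offsets. Enrichment of the motif at offset 0 is the
#' signature of the exonuclease stalling at the bound protein.
#'
#' @param motif `motif_model`.
#' @param gr peak `GRanges`.
#' @param genome contig sequences (named character or `DNAStringSet`).
#' @param half_window offsets scanned are `-half_window .. +half_window`
#'   (default 100, i.e. a 200-bp window).
#' @return data.frame of class `positional_profile`: `position`,
#'   `mean_score`, `z`.
#' @export
positional_profile <- function(motif, gr, genome, half_window = 100L) {
  if (length(gr) < 10) {
    warning("positional profile from < 10 peaks; z-scores are unstable")
  }
  L <- nrow(motif$pwm)
  seqs <- anchor_window_sequences(gr, genome, flank = half_window,
                                  extra = L)
  sc <- score_windows(motif, seqs, seq_len(2L * half_window + 1L))
  m <- colMeans(sc)
  z <- (m - mean(m)) / stats::sd(m)
  out <- data.frame(position = seq(-half_window, half_window),
                    mean_score = m, z = z)
  attr(out, "motif_id") <- motif$motif_id
  class(out) <- c("positional_profile", "data.frame")
  out
}

#' Motif-carrying peakset
#'
#' A peak belongs to the motif's peakset iff the motif scores at or above
#' `threshold` (relative log-odds) at any offset of the window centred on
#' the peak start (default 50 bp: offsets -25..+25).
#'
#' @param motif `motif_model`.
#' @param gr peak `GRanges`.
#' @param genome contig sequences.
#' @param half_window half-width of the scanned window (default 25).
#' @param threshold relative log-odds hit threshold (default 0.8).
#' @return object of class `peak_set`: list with `set_id`, `peak_ids`,
#'   `provenance`.
#' @export
motif_peakset <- function(motif, gr, genome, half_window = 25L,
                          threshold = 0.8) {
  L <- nrow(motif$pwm)
  seqs <- anchor_window_sequences(gr, genome, flank = half_window,
                                  extra = L)
  sc <- score_windows(motif, seqs, seq_len(2L * half_window + 1L))
  hit <- apply(sc, 1, max) >= threshold
  peak_set(motif$motif_id, S4Vectors::mcols(gr)$peak_id[hit], "motif")
}

#' Construct a peak set
#' @param set_id name.
#' @param peak_ids member peak ids.
#' @param provenance one of `"motif"`, `"clip_overlap"`, `"kmer_cluster"`.
#' @return `peak_set`.
#' @export
peak_set <- function(set_id, peak_ids,
                     provenance = c("motif", "clip_overlap", "kmer_cluster")) {
  provenance <- match.arg(provenance)
  structure(list(set_id = as.character(set_id),
                 peak_ids = unique(as.character(peak_ids)),
                 provenance = provenance),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s (%s): %d peaks\n", x$set_id, x$provenance,
              length(x$peak_ids)))
  invisible(x)
}

#' Feature enrichment/depletion of motif peaksets
#'
#' For each peakset and each feature category present in the universe, an
#' upper-tail hypergeometric test for enrichment and a lower-tail test for
#' depletion of that category among the set's peaks. BH adjustment is
#' applied across the whole set x category grid (separately for the
#' enrichment and depletion families).
#'
#' @param peaksets a `peak_set` or list of them.
#' @param categories named factor from [classify_peaks()] over the peak
#'   universe.
#' @return data.frame with one row per set x category.
#' @export
motif_feature_enrichment <- function(peaksets, categories) {
  if (methods::is(peaksets, "peak_set")) peaksets <- list(peaksets)
  universe <- names(categories)
  N <- length(universe)
  cats <- levels(droplevels(categories))
  rows <- lapply(peaksets, function(ps) {
    members <- intersect(ps$peak_ids, universe)
    k <- length(members)
    do.call(rbind, lapply(cats, function(cl) {
      m <- sum(categories == cl)
      q <- sum(categories[members] == cl)
      data.frame(set_id = ps$set_id, category = cl, set_size = k,
                 in_category = q, universe_in_category = m,
                 universe_size = N,
                 p_enrich = stats::phyper(q - 1, m, N - m, k,
                                          lower.tail = FALSE),
                 p_deplete = stats::phyper(q, m, N - m, k),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$padj_enrich <- stats::p.adjust(out$p_enrich, "BH")
  out$padj_deplete <- stats::p.adjust(out$p_deplete, "BH")
  out
}
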