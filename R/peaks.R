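#' Construct a peak GRanges
#'
#' Peaks are represented as a `GRanges` with metadata columns `peak_id`,
#' `support` (number of samples whose calls overlap the peak) and
#' `host_gene` (`NA` until assigned). Coordinates are supplied 0-based
#' half-open (BED convention) and stored 1-based closed as usual for
#' `GRanges`.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds (`end > start`).
#' @param strand `"+"` or `"-"` per peak.
#' @param peak_id unique identifiers; generated when `NULL`.
#' @param support integer replicate support, `>= 1`.
#' @param host_gene host gene ids or `NA`.
#' @return `GRanges` of peaks.
#' @export
peaks <- function(chrom, start, end, strand, peak_id = NULL,
                  support = 1L, host_gene = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stop("peak start must be >= 0")
  if (any(end <= start)) stop("peak end must be > start")
  if (!all(strand %in% c("+", "-"))) stop("peak strand must be '+' or '-'")
  n <- length(start)
  if (is.null(peak_id)) peak_id <- sprintf("peak_%05d", seq_len(n))
  if (anyDuplicated(peak_id)) stop("duplicate peak_id values")
  if (any(support < 1)) stop("peak support must be >= 1")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand)
  S4Vectors::mcols(gr)$peak_id <- as.character(peak_id)
  S4Vectors::mcols(gr)$support <- rep_len(as.integer(support), n)
  S4Vectors::mcols(gr)$host_gene <- rep_len(as.character(host_gene), n)
  names(gr) <- S4Vectors::mcols(gr)$peak_id
  gr
}

#' 5' footprint anchor of peaks
#'
#' The exonuclease degrades RNA 5'->3' and stalls at the crosslinked
#' protein, so the transcription-orientated 5' end of a peak marks the
#' footprint start: the first interval base on `+` peaks, the last on `-`
#' peaks. Returned 0-based.
#'
#' @param gr peak `GRanges`.
#' @return integer vector of 0-based anchor positions.
#' @export
peak_anchor <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  ifelse(s == "-", BiocGenerics::end(gr) - 1L, BiocGenerics::start(gr) - 1L)
}

#' Read peaks from a BED6 file
#'
#' Intervals are 0-based half-open in the file and preserved exactly.
#' Malformed lines raise an error naming the line number; a missing or `.`
#' strand is an error because the assay is stranded.
#'
#' @param path BED6 file (whitespace-delimited).
#' @return peak `GRanges`; empty input gives a zero-length `GRanges`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
    !startsWith(lines, "track")
  idx <- which(keep)
  if (!length(idx)) {
    return(peaks(character(), integer(), integer(), character())[0])
  }
  f <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(lengths(f) < 6L)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1]], " in ", path,
         ": expected >= 6 fields")
  }
  m <- do.call(rbind, lapply(f, `[`, 1:6))
  st <- suppressWarnings(as.integer(m[, 2]))
  en <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(st) | is.na(en) | en <= st | st < 0)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1]], " in ", path,
         ": bad coordinates")
  }
  bad <- which(!m[, 6] %in% c("+", "-"))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1]], " in ", path,
         ": strand must be '+' or '-'")
  }
  ids <- m[, 4]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  peaks(m[, 1], st, en, m[, 6], peak_id = ids)
}

#' Write peaks to BED6
#'
#' @param gr peak `GRanges`.
#' @param path output file.
#' @param score values for the BED score column (default replicate support).
#' @export
write_peaks <- function(gr, path, score = NULL) {
  if (is.null(score)) {
    score <- S4Vectors::mcols(gr)$support
    if (is.null(score)) score <- rep(0L, length(gr))
  }
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   name = S4Vectors::mcols(gr)$peak_id,
                   score = score,
                   strand = as.character(BiocGenerics::strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write depth-normalised coverage as bedgraph
#'
#' Coverage values are scaled to reads per million (`1e6 / library_size`)
#' so tracks from libraries of different depth are comparable. Adjacent
#' records with equal value are run-length merged; records are sorted by
#' chromosome and start.
#'
#' @param x either a peak/interval `GRanges` (per-base coverage is computed
#'   from interval pileup) or a `data.frame` with columns
#'   `chrom,start,end,value` (0-based half-open).
#' @param library_size total mapped reads of the library; must be positive.
#' @param path output bedgraph file.
#' @export
write_bedgraph <- function(x, library_size, path) {
  if (length(library_size) != 1 || !is.finite(library_size) ||
      library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  scale <- 1e6 / library_size
  if (methods::is(x, "GRanges")) {
    cov <- GenomicRanges::coverage(x)
    recs <- lapply(names(cov), function(chr) {
      r <- cov[[chr]]
      v <- S4Vectors::runValue(r)
      l <- S4Vectors::runLength(r)
      en <- cumsum(l)
      st <- en - l
      keep <- v != 0
      if (!any(keep)) return(NULL)
      data.frame(chrom = chr, start = st[keep], end = en[keep],
                 value = v[keep] * scale)
    })
    df <- do.call(rbind, recs)
    if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), value = numeric())
  } else {
    df <- data.frame(chrom = as.character(x$chrom), start = x$start,
                     end = x$end, value = x$value * scale)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  # run-length merge of adjacent equal-value records
  if (nrow(df) > 1) {
    repeat {
      n <- nrow(df)
      same <- df$chrom[-1] == df$chrom[-n] & df$start[-1] == df$end[-n] &
        df$value[-1] == df$value[-n]
      if (!any(same)) break
      i <- which(same)[1]
      df$end[i] <- df$end[i + 1]
      df <- df[-(i + 1), , drop = FALSE]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
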