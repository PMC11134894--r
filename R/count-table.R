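#' Count table with sample metadata
#'
#' Container for a features x samples matrix of non-negative integer read
#' counts plus per-sample metadata. Used both for per-peak counts (rows =
#' peak ids) and gene-level input expression (rows = gene ids).
#'
#' @param counts integer matrix, features in rows (rownames required),
#'   samples in columns.
#' @param samples `data.frame` with columns `name`, `assay` (`"eprint"` or
#'   `"input"`), `condition`, `batch` (optional, `NA` allowed) and
#'   `library_size` (> 0). Row order must match `colnames(counts)`.
#' @param coords optional `data.frame` (`chrom,start,end,strand`, 0-based
#'   half-open) giving the genomic interval each count row was measured on;
#'   required when counts must be matched to merged peaks by overlap.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, samples, coords = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  samples <- as.data.frame(samples)
  need <- c("name", "assay", "condition", "library_size")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns: ", paste(need, collapse = ", "))
  }
  if (!"batch" %in% names(samples)) samples$batch <- NA_character_
  if (anyDuplicated(samples$name)) stop("duplicate sample names")
  if (!all(samples$assay %in% c("eprint", "input"))) {
    stop("assay must be 'eprint' or 'input'")
  }
  if (any(samples$library_size <= 0)) stop("library_size must be > 0")
  if (is.null(colnames(counts))) colnames(counts) <- samples$name
  if (!identical(colnames(counts), as.character(samples$name))) {
    stop("colnames(counts) must equal samples$name in order")
  }
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    stopifnot(nrow(coords) == nrow(counts))
  }
  structure(list(counts = counts, samples = samples, coords = coords),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = "+")))
  invisible(x)
}

#' Read a count table from TSV
#'
#' The counts file has a header of sample names and a first column of
#' feature ids; optional columns `chrom,start,end,strand` (before the
#' sample columns) carry the measured intervals. Sample metadata is read
#' from a companion TSV with columns `name,assay,condition,batch,library_size`.
#'
#' @param counts_path counts TSV.
#' @param samples_path sample metadata TSV.
#' @return `count_table`.
#' @export
read_count_table <- function(counts_path, samples_path) {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- tab[[1]]
  tab[[1]] <- NULL
  coord_cols <- c("chrom", "start", "end", "strand")
  coords <- NULL
  if (all(coord_cols %in% names(tab))) {
    coords <- tab[coord_cols]
    tab <- tab[setdiff(names(tab), coord_cols)]
  }
  samples <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  count_table(as.matrix(tab)[, samples$name, drop = FALSE], samples, coords)
}

#' Write a count table (and its sample metadata) to TSV
#'
#' @param ct `count_table`.
#' @param counts_path,samples_path output files.
#' @export
write_count_table <- function(ct, counts_path, samples_path) {
  df <- data.frame(feature_id = rownames(ct$counts))
  if (!is.null(ct$coords)) df <- cbind(df, ct$coords)
  df <- cbind(df, as.data.frame(ct$counts, check.names = FALSE))
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Subset a count table by feature ids or sample predicate
#'
#' @param ct `count_table`.
#' @param features feature ids to keep (default all).
#' @param assay keep only samples of this assay (default all).
#' @return `count_table`.
#' @export
subset_count_table <- function(ct, features = NULL, assay = NULL) {
  counts <- ct$counts; coords <- ct$coords; samples <- ct$samples
  if (!is.null(features)) {
    idx <- match(features, rownames(counts))
    if (anyNA(idx)) stop("unknown feature ids in subset")
    counts <- counts[idx, , drop = FALSE]
    if (!is.null(coords)) coords <- coords[idx, , drop = FALSE]
  }
  if (!is.null(assay)) {
    keep <- samples$assay == assay
    samples <- samples[keep, , drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  count_table(counts, samples, coords)
}
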