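#' Gene model
#'
#' A gene model holds the flattened feature structure of one gene: exons,
#' the introns between them, and the 5'/3' UTR portions of the exonic
#' space. Intervals are supplied 0-based half-open. Invariants enforced:
#' exons are disjoint and sorted, introns are exactly the inter-exon gaps,
#' UTRs are subsets of exonic space, and exons + introns tile the gene span
#' without overlap.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start,end` (0-based half-open).
#' @param utr5,utr3 optional interval matrices, subsets of exonic space.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) {
    stop("gene ", gene_id, ": exon end must be > start")
  }
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  introns <- if (nrow(exons) > 1) {
    cbind(start = exons[-nrow(exons), 2], end = exons[-1, 1])
  } else {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  norm_utr <- function(u, label) {
    if (is.null(u) || !length(u)) {
      return(matrix(integer(), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    u <- matrix(as.integer(u), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    u <- u[order(u[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(u))) {
      inside <- any(u[i, 1] >= exons[, 1] & u[i, 2] <= exons[, 2])
      if (!inside) {
        stop("gene ", gene_id, ": ", label,
             " interval outside exonic space")
      }
    }
    u
  }
  structure(list(gene_id = as.character(gene_id), chrom = chrom,
                 strand = strand, exons = exons, introns = introns,
                 utr5 = norm_utr(utr5, "five_prime_utr"),
                 utr3 = norm_utr(utr3, "three_prime_utr"),
                 span = c(start = unname(exons[1, 1]),
                          end = unname(exons[nrow(exons), 2]))),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) exons=%d introns=%d\n",
              x$gene_id, x$chrom, x$span[1], x$span[2], x$strand,
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Gene spans as GRanges
#'
#' @param genes list of `gene_model`.
#' @return `GRanges` of gene spans (1-based closed) named by gene id.
#' @export
gene_spans <- function(genes) {
  gr <- GenomicRanges::GRanges(
    vapply(genes, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(genes, function(g) g$span[["start"]], 0L) + 1L,
                     vapply(genes, function(g) g$span[["end"]], 0L)),
    strand = vapply(genes, `[[`, "", "strand"))
  names(gr) <- vapply(genes, `[[`, "", "gene_id")
  S4Vectors::mcols(gr)$gene_id <- names(gr)
  gr
}

#' Read a minimal GTF-like gene annotation
#'
#' Supports the feature types `gene`, `exon`, `five_prime_utr` and
#' `three_prime_utr` with a `gene_id` attribute; other feature types are
#' ignored. GTF 1-based closed coordinates are converted to the internal
#' 0-based half-open convention on read. Introns are derived as the gaps
#' between consecutive exons. Overlapping exons within a gene, or exons
#' outside the declared gene span, are errors.
#'
#' @param path annotation file.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  f <- strsplit(lines[keep], "\t")
  bad <- which(lengths(f) < 9L)
  if (length(bad)) {
    stop("malformed annotation line ", which(keep)[bad[1]], " in ", path)
  }
  m <- do.call(rbind, lapply(f, `[`, 1:9))
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9])
  if (any(gid == m[, 9])) stop("annotation record without gene_id attribute")
  rec <- data.frame(chrom = m[, 1], type = m[, 3],
                    start = as.integer(m[, 4]) - 1L,  # to 0-based
                    end = as.integer(m[, 5]),
                    strand = m[, 7], gene_id = gid,
                    stringsAsFactors = FALSE)
  out <- lapply(split(rec, rec$gene_id), function(r) {
    ex <- r[r$type == "exon", , drop = FALSE]
    if (!nrow(ex)) stop("gene ", r$gene_id[1], ": no exon records")
    g <- r[r$type == "gene", , drop = FALSE]
    if (nrow(g)) {
      if (any(ex$start < g$start[1] | ex$end > g$end[1])) {
        stop("gene ", r$gene_id[1], ": exon outside gene span")
      }
    }
    mk <- function(tp) {
      u <- r[r$type == tp, , drop = FALSE]
      if (nrow(u)) cbind(u$start, u$end) else NULL
    }
    gene_model(r$gene_id[1], r$chrom[1], r$strand[1],
               exons = cbind(ex$start, ex$end),
               utr5 = mk("five_prime_utr"), utr3 = mk("three_prime_utr"))
  })
  out[order(names(out))]
}

#' Write gene models as GTF-like annotation
#'
#' @param genes list of `gene_model`.
#' @param path output file.
#' @export
write_gene_annotation <- function(genes, path) {
  fmt <- function(g, type, iv) {
    if (!nrow(iv)) return(character())
    sprintf("%s\teprinttools\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            g$chrom, type, iv[, 1] + 1L, iv[, 2], g$strand, g$gene_id)
  }
  lines <- unlist(lapply(genes, function(g) {
    c(sprintf("%s\teprinttools\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
              g$chrom, g$span[["start"]] + 1L, g$span[["end"]], g$strand,
              g$gene_id),
      fmt(g, "exon", g$exons),
      fmt(g, "five_prime_utr", g$utr5),
      fmt(g, "three_prime_utr", g$utr3))
  }))
  writeLines(lines, path)
  invisible(path)
}
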