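#' Candidate genes overlapping haplotype blocks
#'
#' A gene is a candidate for a block iff its interval overlaps the block
#' interval by at least 1 bp (both 1-based inclusive; touching intervals
#' that share no base do not overlap).
#'
#' @param blocks data.frame from [detect_blocks()] / [blocks_around()].
#' @param gene_models result of [read_gene_models()].
#' @return data.frame: block row id, chrom, start, end, gene.
#' @export
genes_in_blocks <- function(blocks, gene_models) {
  genes <- gene_models$genes
  if (nrow(blocks) == 0) {
    return(data.frame(block = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      gene = character(0), stringsAsFactors = FALSE))
  }
  bgr <- GenomicRanges::GRanges(blocks$chrom,
                                IRanges::IRanges(blocks$start, blocks$end))
  ov <- GenomicRanges::findOverlaps(bgr, genes, minoverlap = 1L)
  data.frame(block = S4Vectors::queryHits(ov),
             chrom = blocks$chrom[S4Vectors::queryHits(ov)],
             start = blocks$start[S4Vectors::queryHits(ov)],
             end = blocks$end[S4Vectors::queryHits(ov)],
             gene = genes$ID[S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' QTL overlap of candidate intervals
#'
#' Each QTL is counted once if any candidate interval (gene or block)
#' overlaps it; counts are reported per trait category alongside the full
#' match table.
#'
#' @param intervals data.frame with chrom, start, end (and optionally a
#'   gene/id column named \code{id}).
#' @param qtls data.frame: name, chrom, start, end, category (one of
#'   resistance/tolerance, morphological, physiological).
#' @return list: \code{counts} (named per-category QTL counts),
#'   \code{matches} (interval x QTL match table).
#' @export
qtl_overlap <- function(intervals, qtls) {
  ok_cat <- c("resistance/tolerance", "morphological", "physiological")
  stop_if_not(all(qtls$category %in% ok_cat), "unknown QTL category label")
  if (nrow(intervals) == 0) {
    counts <- stats::setNames(rep(0L, length(ok_cat)), ok_cat)
    return(list(counts = counts,
                matches = data.frame(id = character(0), qtl = character(0),
                                     category = character(0),
                                     stringsAsFactors = FALSE)))
  }
  igr <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(intervals$start,
                                                 intervals$end))
  qgr <- GenomicRanges::GRanges(qtls$chrom,
                                IRanges::IRanges(qtls$start, qtls$end))
  ov <- GenomicRanges::findOverlaps(igr, qgr, minoverlap = 1L)
  id <- if (!is.null(intervals$id)) intervals$id else
    sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  matches <- unique(data.frame(
    id = id[S4Vectors::queryHits(ov)],
    qtl = qtls$name[S4Vectors::subjectHits(ov)],
    category = qtls$category[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  hit_qtls <- unique(matches[, c("qtl", "category")])
  counts <- stats::setNames(integer(length(ok_cat)), ok_cat)
  tb <- table(hit_qtls$category)
  counts[names(tb)] <- as.integer(tb)
  rownames(matches) <- NULL
  list(counts = counts, matches = matches)
}

#' Hypergeometric GO-term enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the seen number of annotated genes in the query, given the
#' term's size in the universe; BH-FDR across terms.
#'
#' @param query character vector of query genes (must be within universe).
#' @param annotation data.frame: gene, term (one row per assignment).
#' @param universe character vector of all genes considered.
#' @return data.frame: term, term_size, overlap, expected, p, q.
#' @export
hypergeometric_enrichment <- function(query, annotation, universe) {
  stop_if_not(length(universe) > 0 && length(query) > 0,
              "empty query or universe")
  stop_if_not(all(query %in% universe), "query must be a subset of universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  N <- length(universe); nq <- length(query)
  rows <- lapply(terms, function(tm) {
    members <- unique(ann$gene[ann$term == tm])
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(term = tm, term_size = K, overlap = k,
               expected = nq * K / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out[order(out$p, out$term), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
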