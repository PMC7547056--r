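#' Extract candidate-microbial (unmapped) reads from a SAM stream
#'
#' A record is retained iff its unmapped bit (0x4) is set; with
#' \code{paired_mode = "both"} (the default) a paired record additionally
#' requires the mate-unmapped bit (0x8), on the grounds that a read whose
#' mate maps to the host genome is likely host-derived. Secondary (0x100)
#' and supplementary (0x800) records are always dropped so a template is
#' never counted twice. Only the flag field is interpreted; sequences are
#' passed through for optional FASTA/FASTQ export.
#'
#' @param sam_path path to a SAM file (text; header lines ignored).
#' @param paired_mode "both" (read and mate unmapped) or "read"
#'   (read-unmapped bit alone decides).
#' @param fasta_out optional path; retained reads are written as FASTA.
#' @return list: \code{reads} data.frame (qname, flag, seq),
#'   \code{n_retained}, \code{n_records}.
#' @export
extract_unmapped <- function(sam_path, paired_mode = c("both", "read"),
                             fasta_out = NULL) {
  paired_mode <- match.arg(paired_mode)
  lines <- readLines(sam_path)
  body <- which(!startsWith(lines, "@"))
  qname <- character(0); flag <- integer(0); seqs <- character(0)
  keep <- logical(0)
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      stop(sprintf("malformed SAM record at line %d: %d fields", i,
                   length(f)), call. = FALSE)
    }
    fl <- suppressWarnings(as.integer(f[2]))
    if (is.na(fl) || fl < 0) {
      stop(sprintf("malformed flag field at line %d: '%s'", i, f[2]),
           call. = FALSE)
    }
    unmapped <- bitwAnd(fl, 4L) != 0L
    mate_unmapped <- bitwAnd(fl, 8L) != 0L
    paired <- bitwAnd(fl, 1L) != 0L
    secondary <- bitwAnd(fl, 256L) != 0L || bitwAnd(fl, 2048L) != 0L
    ok <- !secondary && unmapped &&
      (paired_mode == "read" || !paired || mate_unmapped)
    qname <- c(qname, f[1]); flag <- c(flag, fl); seqs <- c(seqs, f[10])
    keep <- c(keep, ok)
  }
  reads <- data.frame(qname = qname[keep], flag = flag[keep],
                      seq = seqs[keep], stringsAsFactors = FALSE)
  if (!is.null(fasta_out) && nrow(reads) > 0) {
    ss <- Biostrings::DNAStringSet(reads$seq)
    names(ss) <- make.unique(reads$qname)
    Biostrings::writeXStringSet(ss, fasta_out)
  }
  list(reads = reads, n_retained = nrow(reads), n_records = length(body))
}

#' Read a taxonomic classification report
#'
#' Two dialects. \code{"kraken"}: the six-column Kraken report
#' (percent, clade reads, direct reads, rank code, taxid, indented name);
#' genus-level clade totals are taken from rows with rank code "G", and
#' the unclassified row ("U") is recorded but excluded. \code{"plain"}:
#' a headerless two-column genus/count table. Duplicate genus rows are
#' summed with a warning.
#'
#' @param path report file.
#' @param dialect "kraken" or "plain".
#' @return named numeric vector genus -> count; attribute
#'   \code{unclassified} holds the unclassified read count (kraken only).
#' @export
read_classification_report <- function(path, dialect = c("kraken", "plain")) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    stop_if_not(ncol(d) >= 2, "plain dialect needs two columns")
    taxon <- trimws(d[[1]]); count <- as.numeric(d[[2]])
  } else {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    stop_if_not(ncol(d) >= 6,
                "kraken dialect needs 6 columns (pct, clade, direct, rank, taxid, name)")
    rank <- trimws(d[[4]])
    uncl <- sum(as.numeric(d[[2]][rank == "U"]))
    g <- rank == "G"
    if (!any(g)) warning("no genus-rank rows in report")
    taxon <- trimws(d[[6]][g]); count <- as.numeric(d[[2]][g])
    out <- collapse_duplicates(taxon, count)
    attr(out, "unclassified") <- uncl
    return(out)
  }
  collapse_duplicates(taxon, count)
}

collapse_duplicates <- function(taxon, count) {
  if (anyDuplicated(taxon)) {
    warning("duplicate genus rows summed")
    agg <- tapply(count, taxon, sum)
    return(stats::setNames(as.numeric(agg), names(agg)))
  }
  stats::setNames(count, taxon)
}
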