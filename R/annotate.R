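#' Read gene models from GFF3
#'
#' Imports the annotation with rtracklayer and splits it into gene
#' records and CDS parts (grouped by parent gene). Only what the variant
#' annotator needs is kept: intervals, strand, IDs.
#'
#' @param gff_path GFF3 file.
#' @return list: \code{genes} (GRanges with ID), \code{cds} (GRanges with
#'   gene id in \code{gene}).
#' @export
read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path)
  genes <- gr[gr$type == "gene"]
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  ## Parent may point at an mRNA; resolve one level if needed
  mrna <- gr[gr$type == "mRNA"]
  if (length(mrna) > 0) {
    m2g <- stats::setNames(as.character(S4Vectors::mcols(mrna)$Parent),
                           S4Vectors::mcols(mrna)$ID)
    hit <- parent %in% names(m2g)
    parent[hit] <- m2g[parent[hit]]
  }
  cds$gene <- parent
  list(genes = genes, cds = cds)
}

#' Classify the coding effect of a SNP
#'
#' Rebuilds the codon containing the SNP from the CDS parts of the
#' containing gene, in transcript orientation (reverse-complement on the
#' minus strand), substitutes the alternate allele, and compares amino
#' acids under the standard genetic code.
#'
#' @param chrom,pos,ref,alt SNP description (1-based position; plus-strand
#'   ref/alt alleles).
#' @param gene_models result of [read_gene_models()].
#' @param reference a \code{Biostrings::DNAStringSet} keyed by chromosome
#'   (or a FASTA path).
#' @return one of "intergenic", "non-coding", "synonymous", "missense",
#'   "nonsense"; attribute \code{detail} carries codon/aa info. A gene
#'   whose CDS length is not a multiple of 3 is flagged and skipped
#'   (warning, effect NA).
#' @export
annotate_snp_effect <- function(chrom, pos, ref, alt, gene_models,
                                reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))
  }
  stop_if_not(chrom %in% names(reference), "chromosome not in reference")
  stop_if_not(pos >= 1 && pos <= Biostrings::width(reference[chrom]),
              "position outside the reference")

  snp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  in_cds <- GenomicRanges::findOverlaps(snp, gene_models$cds)
  if (length(in_cds) == 0) {
    in_gene <- GenomicRanges::findOverlaps(snp, gene_models$genes)
    return(if (length(in_gene) == 0) "intergenic" else "non-coding")
  }

  cds_hit <- gene_models$cds[S4Vectors::subjectHits(in_cds)[1]]
  gene_id <- cds_hit$gene
  parts <- gene_models$cds[gene_models$cds$gene == gene_id]
  parts <- parts[order(GenomicRanges::start(parts))]
  total <- sum(GenomicRanges::width(parts))
  if (total %% 3 != 0) {
    warning(sprintf("CDS length of %s not a multiple of 3; skipped", gene_id))
    return(NA_character_)
  }
  strand <- as.character(GenomicRanges::strand(parts))[1]

  ## transcript sequence and the SNP's offset within it
  chrseq <- reference[[chrom]]
  seqs <- lapply(seq_along(parts), function(i) {
    Biostrings::subseq(chrseq, GenomicRanges::start(parts)[i],
                       GenomicRanges::end(parts)[i])
  })
  tx <- do.call(Biostrings::xscat, seqs)
  before <- 0L
  for (i in seq_along(parts)) {
    st <- GenomicRanges::start(parts)[i]; en <- GenomicRanges::end(parts)[i]
    if (pos >= st && pos <= en) { offset_plus <- before + (pos - st + 1L); break }
    before <- before + (en - st + 1L)
  }
  if (strand == "-") {
    tx <- Biostrings::reverseComplement(tx)
    offset <- total - offset_plus + 1L
    ref_t <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
    alt_t <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
  } else {
    offset <- offset_plus
    ref_t <- ref; alt_t <- alt
  }

  txc <- as.character(tx)
  stop_if_not(substr(txc, offset, offset) == ref_t,
              "reference allele does not match the reference sequence")
  ci <- (offset - 1L) %/% 3L
  codon_ref <- substr(txc, 3L * ci + 1L, 3L * ci + 3L)
  within <- offset - 3L * ci
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_t

  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon_ref]); aa_alt <- unname(code[codon_alt])
  effect <- if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "nonsense"
            else "missense"
  attr(effect, "detail") <- list(gene = gene_id, codon_ref = codon_ref,
                                 codon_alt = codon_alt, aa_ref = aa_ref,
                                 aa_alt = aa_alt, codon_index = ci + 1L)
  effect
}
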