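#' Generate gene models, reference, QTL / GO / pathway tables
#'
#' Builds the follow-up inputs the haplotype and function modules consume,
#' consistent with a generated genotype matrix: non-overlapping
#' single-exon genes tiling each chromosome with gaps (every CDS starts
#' with ATG, has length divisible by 3 and no internal stop), a random
#' nucleotide reference whose bases agree with each gene's CDS and with
#' every SNP's ref allele, QTL intervals spanning 1-20 genes with the
#' three trait categories, 1-5 GO terms per gene from a 50-term
#' vocabulary, and a genus-to-pathway weight table with rows summing to 1.
#'
#' @param cfg a [synth_config()].
#' @param genotypes a [genotype_matrix()] from [generate_genotypes()].
#' @param causal_snps ids of the causal SNPs (from the genotype truth).
#' @param place_causal_in_genes if TRUE (default) a gene is laid over
#'   every causal SNP so coding-effect annotation has something to find.
#' @param n_qtls number of QTL intervals (default 15).
#' @param n_pathways pathways in the weight table (default 24).
#' @return list: \code{gene_models} (genes/cds GRanges, as
#'   [read_gene_models()] returns), \code{reference} (DNAStringSet),
#'   \code{qtls}, \code{go_annotation}, \code{pathway_weights},
#'   \code{genotypes} (copy with ref/alt alleles consistent with the
#'   reference).
#' @export
generate_annotations <- function(cfg, genotypes, causal_snps = character(0),
                                 place_causal_in_genes = TRUE, n_qtls = 15L,
                                 n_pathways = 24L) {
  map <- genotypes$map
  with_subseed(cfg$seed, "annotations", {
    chroms <- unique(map$chrom)
    chrlen <- vapply(chroms, function(ch) {
      max(map$pos[map$chrom == ch]) + 5000L
    }, integer(1))

    bases <- c("A", "C", "G", "T")
    ref <- lapply(chrlen, function(L) sample(bases, L, replace = TRUE))
    names(ref) <- chroms

    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(expand.grid(bases, bases, bases), 1, paste0,
                    collapse = "")
    sense <- setdiff(codons, stops)

    ## place genes: causal-anchored first, then tile the gaps
    genes <- list()
    add_gene <- function(ch, start, len, strand) {
      genes[[length(genes) + 1]] <<- data.frame(
        chrom = ch, start = start, end = start + len - 1L,
        strand = strand, stringsAsFactors = FALSE)
    }
    if (place_causal_in_genes && length(causal_snps)) {
      for (s in causal_snps) {
        i <- match(s, map$snp)
        len <- 3L * sample(100:300, 1)
        start <- max(1L, map$pos[i] - as.integer(len / 2))
        start <- start - (start - 1L) %% 1L
        add_gene(map$chrom[i], start, len, sample(c("+", "-"), 1))
      }
    }
    for (ch in chroms) {
      cur <- 1000L
      existing <- do.call(rbind, genes)
      ex <- if (!is.null(existing)) existing[existing$chrom == ch, ] else NULL
      while (cur < chrlen[ch] - 2000L) {
        cur <- cur + sample(200:1500, 1)
        len <- 3L * sample(100:300, 1)
        if (cur + len - 1L >= chrlen[ch]) break
        clash <- !is.null(ex) && nrow(ex) > 0 &&
          any(ex$start <= cur + len - 1L & ex$end >= cur)
        if (!clash) add_gene(ch, cur, len, sample(c("+", "-"), 1))
        cur <- cur + len
      }
    }
    gtab <- do.call(rbind, genes)
    gtab <- gtab[order(gtab$chrom, gtab$start), , drop = FALSE]
    ## drop any residual overlaps (causal genes keep priority by order)
    keep <- rep(TRUE, nrow(gtab))
    last_end <- stats::setNames(rep(0L, length(chroms)), chroms)
    for (i in seq_len(nrow(gtab))) {
      if (gtab$start[i] <= last_end[gtab$chrom[i]]) { keep[i] <- FALSE; next }
      last_end[gtab$chrom[i]] <- gtab$end[i]
    }
    gtab <- gtab[keep, , drop = FALSE]
    gtab$ID <- sprintf("gene%04d", seq_len(nrow(gtab)))
    rownames(gtab) <- NULL

    ## write CDS sequences into the reference: ATG start, no internal stop
    for (i in seq_len(nrow(gtab))) {
      len <- gtab$end[i] - gtab$start[i] + 1L
      tx <- c("ATG", sample(sense, len / 3L - 1L, replace = TRUE))
      txs <- paste(tx, collapse = "")
      if (gtab$strand[i] == "-") {
        txs <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(txs)))
      }
      ref[[gtab$chrom[i]]][gtab$start[i]:gtab$end[i]] <-
        strsplit(txs, "")[[1]]
    }

    ## SNP ref alleles follow the reference; alt is any other base
    map$ref <- vapply(seq_len(nrow(map)), function(i) {
      ref[[map$chrom[i]]][map$pos[i]]
    }, character(1))
    map$alt <- vapply(map$ref, function(b) sample(setdiff(bases, b), 1),
                      character(1))
    geno2 <- genotype_matrix(genotypes$dosage, map[, c("snp", "chrom", "pos",
                                                       "ref", "alt")])

    reference <- Biostrings::DNAStringSet(
      vapply(ref, paste, character(1), collapse = ""))
    names(reference) <- chroms

    genes_gr <- GenomicRanges::GRanges(
      gtab$chrom, IRanges::IRanges(gtab$start, gtab$end),
      strand = gtab$strand, type = "gene", ID = gtab$ID)
    cds_gr <- GenomicRanges::GRanges(
      gtab$chrom, IRanges::IRanges(gtab$start, gtab$end),
      strand = gtab$strand, type = "CDS", gene = gtab$ID)
    gene_models <- list(genes = genes_gr, cds = cds_gr)

    ## QTL intervals spanning 1-20 consecutive genes
    cats <- c("resistance/tolerance", "morphological", "physiological")
    qtls <- do.call(rbind, lapply(seq_len(n_qtls), function(k) {
      ch <- sample(chroms, 1)
      gch <- gtab[gtab$chrom == ch, ]
      i0 <- sample.int(nrow(gch), 1)
      span <- sample(1:20, 1)
      i1 <- min(nrow(gch), i0 + span - 1L)
      data.frame(name = sprintf("qtl%03d", k), chrom = ch,
                 start = gch$start[i0], end = gch$end[i1],
                 category = sample(cats, 1), stringsAsFactors = FALSE)
    }))

    ## GO: 1-5 terms per gene from a 50-term vocabulary
    vocab <- sprintf("GO:%07d", seq_len(50))
    go <- do.call(rbind, lapply(seq_len(nrow(gtab)), function(i) {
      tm <- sample(vocab, sample(1:5, 1))
      data.frame(gene = gtab$ID[i], term = tm, stringsAsFactors = FALSE)
    }))

    ## genus -> pathway weights, rows normalized
    genera <- sprintf("Genus%03d", seq_len(cfg$n_genera))
    pw_names <- sprintf("pathway%02d", seq_len(n_pathways))
    class1 <- sample(c("Metabolism", "Genetic Information Processing",
                       "Environmental Information Processing",
                       "Cellular Processes", "Human Diseases",
                       "Organismal Systems"), n_pathways, replace = TRUE)
    W <- matrix(stats::rexp(cfg$n_genera * n_pathways),
                nrow = cfg$n_genera, dimnames = list(genera, pw_names))
    ## sparsify: each genus contributes to ~1/3 of pathways
    Z <- matrix(stats::runif(length(W)) < 1 / 3, nrow = nrow(W))
    Z[cbind(seq_len(nrow(W)), sample.int(n_pathways, nrow(W),
                                         replace = TRUE))] <- TRUE
    W <- W * Z
    pw <- pathway_weights(W, data.frame(pathway = pw_names, class1 = class1,
                                        stringsAsFactors = FALSE))

    list(gene_models = gene_models, reference = reference, qtls = qtls,
         go_annotation = go, pathway_weights = pw, genotypes = geno2)
  })
}

#' Write gene models as GFF3
#'
#' gene + mRNA + CDS records per gene, via rtracklayer.
#' @param gene_models list(genes, cds) as from [generate_annotations()].
#' @param path output .gff3 file.
#' @export
write_gff3 <- function(gene_models, path) {
  g <- gene_models$genes
  mrna <- g
  S4Vectors::mcols(mrna) <- NULL
  mrna$type <- "mRNA"
  mrna$ID <- paste0(g$ID, ".1")
  mrna$Parent <- g$ID
  cds <- gene_models$cds
  cds2 <- cds
  S4Vectors::mcols(cds2) <- NULL
  cds2$type <- "CDS"
  cds2$ID <- paste0(cds$gene, ".1.cds")
  cds2$Parent <- paste0(cds$gene, ".1")
  all <- c(g, mrna, cds2)
  all$phase <- ifelse(all$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(sort(all), path, format = "gff3")
  invisible(path)
}

#' Write a reference as FASTA
#' @param reference DNAStringSet.
#' @param path output .fa file.
#' @export
write_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}
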