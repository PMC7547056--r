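# Fixtures are built in code at test time; nothing binary ships with the
# package.

# A small profile with two locations and known counts
tiny_profile <- function() {
  counts <- matrix(
    c(30L, 10L, 0L, 5L,
      20L, 20L, 5L, 0L,
      0L,  40L, 10L, 2L,
      15L, 15L, 15L, 15L),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("S", 1:4), c("Pseudomonas", "Bacillus",
                                        "Clostridium", "Methanobrevibacter")))
  lineage <- data.frame(
    genus = colnames(counts),
    superkingdom = c("Bacteria", "Bacteria", "Bacteria", "Archaea"),
    phylum = c("Proteobacteria", "Firmicutes", "Firmicutes",
               "Euryarchaeota"),
    stringsAsFactors = FALSE)
  metadata <- data.frame(sample = rownames(counts),
                         location = c("agCh", "agCh", "agPh", "agPh"),
                         total_reads = rowSums(counts),
                         stringsAsFactors = FALSE)
  taxonomic_profile(counts, lineage, metadata)
}

# A SAM fixture: header + records with the given flags
write_sam_fixture <- function(flags, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:10000")
  recs <- vapply(seq_along(flags), function(i) {
    mapped <- bitwAnd(flags[i], 4L) == 0L
    paste(sprintf("read%03d", i), flags[i],
          if (mapped) "chr1" else "*", if (mapped) 100 + i else 0,
          if (mapped) 60 else 0, if (mapped) "10M" else "*",
          "*", 0, 0, "ACGTACGTAC", "IIIIIIIIII", sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  path
}

# Random undirected weighted graph on n nodes as an edge data.frame
random_graph <- function(n, p_edge = 0.5, weighted = TRUE) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(from = paste0("n", pairs[, 1]), to = paste0("n", pairs[, 2]),
             weight = if (weighted) stats::runif(nrow(pairs), -1, 1)
                      else rep(1, nrow(pairs)),
             stringsAsFactors = FALSE)
}

graph_nodes <- function(n) paste0("n", seq_len(n))

# Inbred dosage fixture: n samples x m SNPs in {0,2}
random_inbred <- function(n, m, maf = NULL) {
  f <- if (is.null(maf)) stats::runif(m, 0.1, 0.5) else rep(maf, m)
  d <- sapply(f, function(fr) 2L * stats::rbinom(n, 1, fr))
  dimnames(d) <- list(sprintf("i%03d", seq_len(n)),
                      sprintf("snp%03d", seq_len(m)))
  d
}
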