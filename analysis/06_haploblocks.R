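#!/usr/bin/env Rscript
# Stage 6: haplotype blocks, candidate genes, QTL overlap, GO enrichment.
#
# Around each significant SNP (+-100 kb) the confidence-interval block
# rule is applied to the inbred genotypes; genes overlapping a block by
# at least one base become candidates, candidates are intersected with
# the QTL table per trait category, and the candidate set is tested for
# GO-term enrichment against the whole gene universe.

suppressPackageStartupMessages(library(phyllonet))

sd_ <- "results/synthetic_study"
geno <- read_vcf(file.path(sd_, "genotypes.vcf"))
gm <- read_gene_models(file.path(sd_, "genes.gff3"))
sig <- read.delim("results/gwas/significant_snps.tsv")
dir.create("results/haploblocks", showWarnings = FALSE, recursive = TRUE)
w <- function(d, f) write.table(d, file.path("results/haploblocks", f),
                                sep = "\t", quote = FALSE, row.names = FALSE)

if (nrow(sig) == 0) {
  cat("no significant SNPs; nothing to follow up\n")
  quit(save = "no", status = 0)
}

blocks <- blocks_around(geno, sig$snp, window = 1e5)
w(blocks, "blocks.tsv")
ub <- unique(blocks[, c("chrom", "start", "end", "n_snps")])
cat(sprintf("%d significant SNPs fall in %d distinct haplotype blocks\n",
            nrow(sig), nrow(ub)))
cat(sprintf("  block sizes: %s SNPs\n",
            paste(sort(unique(ub$n_snps)), collapse = ", ")))

cand <- genes_in_blocks(ub, gm)
w(cand, "candidate_genes.tsv")
genes <- unique(cand$gene)
cat(sprintf("%d candidate genes overlap the blocks\n", length(genes)))

qtls <- read.delim(file.path(sd_, "qtls.tsv"))
gr <- gm$genes[match(genes, gm$genes$ID)]
iv <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr), id = gr$ID)
qo <- qtl_overlap(iv, qtls)
w(qo$matches, "qtl_matches.tsv")
cat("QTL overlap by category:\n")
print(qo$counts)

go <- read.delim(file.path(sd_, "go_annotation.tsv"))
enr <- hypergeometric_enrichment(genes, go, unique(gm$genes$ID))
w(enr, "go_enrichment.tsv")
cat(sprintf("GO enrichment: %d terms tested, %d at q < 0.05; top term %s (p = %.3g)\n",
            nrow(enr), sum(enr$q < 0.05), enr$term[1], enr$p[1]))
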