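test_that("kinship is the centered cross-product with PSD structure", {
  ## two samples, one SNP (0, 2): centered (-1, 1), K = [[1,-1],[-1,1]]
  d <- matrix(c(0, 2), 2, 1, dimnames = list(c("s1", "s2"), "snp1"))
  K <- kinship(d)
  expect_equal(unname(K), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  ## genetically identical samples: every SNP is monomorphic, K constant
  d2 <- matrix(rep(c(0, 2, 2), each = 3), 3, 3,
               dimnames = list(paste0("s", 1:3), paste0("m", 1:3)))
  expect_warning(K2 <- suppressMessages(kinship(d2)), "monomorphic")
  expect_true(all(abs(K2 - K2[1, 1]) < 1e-12))

  ## symmetric PSD on a random inbred panel; monomorphic SNPs excluded
  set.seed(6)
  dd <- random_inbred(40, 60)
  dd[, 1] <- 0   # monomorphic
  expect_message(K3 <- kinship(dd), "monomorphic")
  expect_equal(K3, t(K3))
  expect_gte(min(eigen(K3, symmetric = TRUE)$values), -1e-8)
  expect_identical(attr(K3, "n_monomorphic"), 1L)
})

test_that("with identity kinship the scan collapses to OLS", {
  set.seed(8)
  n <- 60
  G <- matrix(rbinom(n * 40, 2, 0.4), n, 40,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:40)))
  y <- rnorm(n)
  K <- diag(n); dimnames(K) <- list(rownames(G), rownames(G))
  sc <- lmm_scan(G, y, K, min_maf = 0.01)
  for (j in seq_len(nrow(sc))) {
    ols <- summary(lm(y ~ G[, sc$snp[j]]))$coefficients
    expect_equal(sc$p[j], ols[2, 4], tolerance = 1e-6)
    expect_equal(sc$beta[j], ols[2, 1], tolerance = 1e-6)
  }
  expect_error(lmm_scan(G, rep(1, n), K), "degenerate")
})

test_that("the mixed model absorbs confounding that OLS inflates", {
  ## trait with a polygenic component aligned to kinship: OLS p-values
  ## inflate, the LMM stays near lambda = 1
  cfg <- synth_config(n_samples = 250, n_snps = 1200, n_blocks = 60,
                      n_causal = 0, seed = 31)
  tr <- matrix(rnorm(250), ncol = 1,
               dimnames = list(sprintf("ACC%04d", 1:250), "t"))
  gg <- generate_genotypes(cfg, tr)
  K <- kinship(gg$genotypes)
  eg <- eigen(K, symmetric = TRUE)
  ## polygenic trait: u ~ N(0, 2K) plus noise
  set.seed(32)
  u <- eg$vectors %*% (sqrt(pmax(eg$values, 0) * 2) * rnorm(250))
  y <- as.numeric(u) + rnorm(250)
  sc <- lmm_scan(gg$genotypes, y, K, min_maf = 0.05)
  expect_gt(nrow(sc), 800)
  lam_lmm <- lambda_gc(sc$p)
  ols_p <- apply(gg$genotypes$dosage[, sc$snp], 2,
                 function(g) summary(lm(y ~ g))$coefficients[2, 4])
  expect_lt(abs(lam_lmm - 1), abs(lambda_gc(ols_p) - 1))
  expect_lt(lam_lmm, 1.2)
})

test_that("the Sidak omnibus matches its closed form", {
  expect_equal(omnibus_multitrait(rep(1, 5)), 1)
  expect_equal(omnibus_multitrait(0.037), 0.037)            # T = 1
  expect_equal(omnibus_multitrait(c(0.01, 0.5, 0.9, 0.2, 0.8, 0.3,
                                    0.4, 0.6, 0.7, 0.99, 0.05, 0.02)),
               1 - 0.99^12, tolerance = 1e-12)
  expect_error(omnibus_multitrait(c(0.1, NA)), "missing")
})

test_that("BH adjustment matches the hand case and a step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  set.seed(10)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- fdr_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("significance calling respects thresholds and gene assignment", {
  cfg <- synth_config(n_samples = 250, n_genera = 60, n_hubs = 2,
                      n_snps = 400, n_blocks = 40, n_causal = 2,
                      causal_effect = 1.5, maf_range = c(0.25, 0.5),
                      seed = 41)
  sim <- generate_counts(cfg)
  tr <- hub_abundances(sim$profile, sim$truth$hub_genus_ids)
  gg <- generate_genotypes(cfg, tr)
  K <- kinship(gg$genotypes)
  scan <- scan_hub_traits(gg$genotypes, gg$traits, K)
  ## threshold 1 keeps everything; below-minimum keeps nothing
  expect_identical(nrow(call_significant(scan, 1, use_fdr = FALSE)),
                   nrow(scan$per_snp))
  expect_identical(nrow(call_significant(
    scan, min(scan$per_snp$omnibus_p) / 2, use_fdr = FALSE)), 0L)
  ## FDR calls recover the causal SNPs (or r2 > 0.8 proxies)
  sig <- call_significant(scan, 0.05, use_fdr = TRUE)
  for (s in gg$truth$causal_snp_ids) {
    proxied <- any(vapply(sig$snp, function(t) {
      t == s || ld_stats(gg$genotypes$dosage[, s],
                         gg$genotypes$dosage[, t])$r2 > 0.8
    }, logical(1)))
    expect_true(proxied)
  }
  ## gene assignment for called SNPs inside genes
  ann <- generate_annotations(cfg, gg$genotypes,
                              causal_snps = gg$truth$causal_snp_ids)
  sig2 <- call_significant(scan, 0.05, gene_models = ann$gene_models)
  inside <- sig2$snp %in% gg$truth$causal_snp_ids
  expect_true(all(!is.na(sig2$gene[inside])))
})

test_that("haplotype contrasts use exact rank sums and group minimums", {
  d <- matrix(c(rep(0, 3), rep(2, 3)), 6, 1,
              dimnames = list(paste0("s", 1:6), "snpX"))
  trait <- c(1, 2, 3, 4, 5, 6)
  res <- haplotype_abundance_test(d, "snpX", trait)
  ## exact two-sided p for {1,2,3} vs {4,5,6} is 2/choose(6,3) = 0.1
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  ## swapping group labels leaves p unchanged
  res2 <- haplotype_abundance_test(2 - d, "snpX", trait)
  expect_equal(res2$p, res$p)
  ## identical values give p = 1
  res3 <- haplotype_abundance_test(d, "snpX", rep(1, 6))
  expect_equal(res3$p, 1)
  ## undersized groups are skipped with q = NA
  d4 <- matrix(c(0, 0, 2, 2, 2, 1), 6, 1,
               dimnames = list(paste0("s", 1:6), "snpY"))
  res4 <- haplotype_abundance_test(d4, "snpY", trait, min_group = 3)
  expect_true(all(res4$skipped))
  expect_true(all(is.na(res4$q)))
})

test_that("coding-effect annotation rebuilds codons on both strands", {
  ## two single-exon genes on a 120 bp chromosome, one per strand
  ## plus gene: CDS 10..27, ATG GCT TGG AAA CCC TAG-free tail
  plus_cds <- "ATGGCTTGGAAACCCGGG"
  minus_cds <- "ATGTTTGCAGATTAA"  # on transcript; genome carries its RC
  chrom <- paste0(strrep("A", 9), plus_cds, strrep("C", 10),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(minus_cds))),
                  strrep("T", 10))
  ref <- Biostrings::DNAStringSet(c(chr1 = chrom))
  gm <- list(
    genes = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(10, 38), c(27, 52)), strand = c("+", "-"),
      type = "gene", ID = c("gp", "gm")),
    cds = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(10, 38), c(27, 52)), strand = c("+", "-"),
      type = "CDS", gene = c("gp", "gm")))

  cases <- list(
    ## plus strand: ATG -> ACG at codon 1 position 2 = missense M->T
    list(pos = 11, ref = "T", alt = "C", want = "missense"),
    ## plus strand: GCT -> GCC codon 2 wobble = synonymous A->A
    list(pos = 15, ref = "T", alt = "C", want = "synonymous"),
    ## plus strand: TGG -> TAG codon 3 = nonsense W->*
    list(pos = 17, ref = "G", alt = "A", want = "nonsense"),
    ## intergenic and non-CDS positions
    list(pos = 5, ref = "A", alt = "G", want = "intergenic"),
    list(pos = 30, ref = "C", alt = "G", want = "intergenic"))
  for (cs in cases) {
    eff <- annotate_snp_effect("chr1", cs$pos, cs$ref, cs$alt, gm, ref)
    expect_identical(as.character(eff), cs$want)
  }

  ## minus strand: genome coordinates 38..52 hold RC(minus_cds).
  ## transcript codon 2 = TTT (F); genomic base for transcript offset 4
  ## is position 52 - 4 + 1 = 49, genome base = complement(T) = A.
  ## plus-strand alt G = transcript C -> codon CTT (L): missense.
  eff <- annotate_snp_effect("chr1", 49, "A", "G", gm, ref)
  expect_identical(as.character(eff), "missense")
  det <- attr(eff, "detail")
  expect_identical(det$codon_ref, "TTT")
  expect_identical(det$aa_ref, "F")
  ## transcript TTT -> TTC (synonymous) via genomic position 47:
  ## offset = 52 - 47 + 1 = 6, codon 2 position 3; plus-strand ref A,
  ## alt G complements to transcript C
  eff2 <- annotate_snp_effect("chr1", 47, "A", "G", gm, ref)
  expect_identical(as.character(eff2), "synonymous")

  ## mismatched reference allele is an error, not a silent call
  expect_error(annotate_snp_effect("chr1", 11, "G", "C", gm, ref),
               "does not match")
})
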