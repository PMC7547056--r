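test_that("LD statistics read haplotypes straight off inbred dosages", {
  set.seed(12)
  x <- random_inbred(80, 1)[, 1]
  ## duplicated column: complete LD
  r <- ld_stats(x, x)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$Dprime, 1, tolerance = 1e-12)

  ## hand case: 40 AB and 60 ab haplotypes, no recombinants
  gi <- c(rep(2, 40), rep(0, 60))
  gj <- c(rep(2, 40), rep(0, 60))
  r2 <- ld_stats(gi, gj)
  expect_equal(r2$D, 0.4 - 0.4 * 0.4, tolerance = 1e-12)   # 0.24
  expect_equal(r2$Dprime, 1, tolerance = 1e-12)
  expect_equal(r2$r2, 1, tolerance = 1e-12)

  ## heterozygotes are excluded pairwise
  gi[1] <- 1
  r3 <- ld_stats(gi, gj)
  expect_identical(r3$n_excluded, 1L)
  expect_identical(r3$n_used, 99L)

  expect_error(ld_stats(rep(2, 10), random_inbred(10, 1)[, 1]),
               "monomorphic")
})

test_that("independent SNPs show r2 near the 1/n sampling floor", {
  set.seed(14)
  n <- 1000
  r2s <- replicate(300, {
    a <- 2 * rbinom(n, 1, 0.4); b <- 2 * rbinom(n, 1, 0.4)
    if (sd(a) == 0 || sd(b) == 0) NA else ld_stats(a, b)$r2
  })
  r2s <- r2s[!is.na(r2s)]
  se <- sd(r2s) / sqrt(length(r2s))
  expect_lt(abs(mean(r2s) - 1 / n), 3 * se + 1e-4)
})

test_that("r2 and D' agree with a 2x2 haplotype-table oracle", {
  set.seed(15)
  done <- 0
  while (done < 50) {
    d <- random_inbred(60, 2, maf = runif(1, 0.15, 0.5))
    ok <- tryCatch(ld_stats(d[, 1], d[, 2]), error = function(e) NULL)
    if (is.null(ok)) next
    o <- oracle_ld(d[, 1] / 2, d[, 2] / 2)
    expect_equal(ok$D, o$D, tolerance = 1e-9)
    expect_equal(ok$Dprime, o$Dprime, tolerance = 1e-9)
    expect_equal(ok$r2, o$r2, tolerance = 1e-9)
    done <- done + 1
  }
})

test_that("D' confidence intervals pin perfect LD and are permissive at n small", {
  ## no recombinants, decent counts: CI hugs 1
  ci <- dprime_ci(c(AB = 40, Ab = 0, aB = 0, ab = 60))
  expect_gte(unname(ci["low"]), 0.7)
  expect_gte(unname(ci["high"]), 0.98)
  ## clear recombination pushes the upper bound down
  ci2 <- dprime_ci(c(AB = 25, Ab = 25, aB = 25, ab = 25))
  expect_lt(ci2["high"], 0.98)
})

test_that("block detection recovers constructed LD structure exactly", {
  set.seed(16)
  n <- 120
  h1 <- rbinom(n, 1, 0.4); h2 <- rbinom(n, 1, 0.5)
  ## two perfect-LD triplets separated in position
  dos <- 2 * cbind(h1, h1, h1, h2, h2, h2)
  dimnames(dos) <- list(sprintf("i%03d", 1:n), sprintf("s%d", 1:6))
  map <- data.frame(snp = colnames(dos), chrom = "chr1",
                    pos = c(100L, 200L, 300L, 5000L, 5100L, 5200L),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, map)
  b <- detect_blocks(gm)
  expect_identical(nrow(b), 2L)
  expect_identical(b$start, c(100L, 5000L))
  expect_identical(b$end, c(300L, 5200L))
  expect_identical(b$snps, c("s1,s2,s3", "s4,s5,s6"))

  ## translation invariance: shifting positions shifts blocks identically
  map2 <- map; map2$pos <- map$pos + 7777L
  map2$snp <- sprintf("t%d", 1:6); colnames(dos) -> old
  dos2 <- dos; colnames(dos2) <- map2$snp
  b2 <- detect_blocks(genotype_matrix(dos2, map2))
  expect_identical(b2$start, b$start + 7777L)
  expect_identical(b2$end, b$end + 7777L)

  ## anchoring: an anchor inside a block returns that block; an isolated
  ## anchor comes back as a singleton interval
  ba <- detect_blocks(gm, anchors = "s2")
  expect_identical(ba$anchor, "s2")
  expect_identical(ba$start, 100L)
  iso <- cbind(dos, 2 * rbinom(n, 1, 0.5))
  colnames(iso)[7] <- "s7"
  mapi <- rbind(map, data.frame(snp = "s7", chrom = "chr1", pos = 9000L,
                                ref = "A", alt = "G"))
  bi <- detect_blocks(genotype_matrix(iso, mapi), anchors = "s7")
  expect_identical(bi$n_snps, 1L)
  expect_identical(bi$start, 9000L)

  ## blocks_around merges overlapping anchor windows but reports each
  anchored <- blocks_around(gm, c("s1", "s5"), window = 1000)
  expect_identical(anchored$anchor, c("s1", "s5"))
  expect_identical(anchored$start, c(100L, 5000L))
})

test_that("candidate genes overlap blocks by at least one base", {
  gm <- list(genes = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 100, 210, 400), c(200, 200, 300, 450)),
    ID = c("gA", "gA2", "gB", "gC")))
  gm$genes <- gm$genes[-2]   # single interval per gene
  blocks <- data.frame(chrom = "chr1", start = c(150L, 301L),
                       end = c(250L, 350L), stringsAsFactors = FALSE)
  cand <- genes_in_blocks(blocks, gm)
  ## block 1 overlaps gA (150-200) and gB (210-250); block 2 touches
  ## nothing (gB ends at 300, block starts at 301)
  expect_setequal(cand$gene[cand$block == 1], c("gA", "gB"))
  expect_identical(sum(cand$block == 2), 0L)
})

test_that("QTL overlap counts each QTL once per category", {
  qtls <- data.frame(
    name = c("q1", "q2", "q3", "q4"),
    chrom = "chr1",
    start = c(100L, 500L, 900L, 1300L),
    end = c(400L, 800L, 1200L, 1600L),
    category = c("resistance/tolerance", "resistance/tolerance",
                 "morphological", "physiological"),
    stringsAsFactors = FALSE)
  ## two genes inside q1 (dedup), one in q3; q2/q4 untouched
  iv <- data.frame(chrom = "chr1", start = c(120L, 300L, 950L),
                   end = c(180L, 380L, 1000L), id = c("g1", "g2", "g3"),
                   stringsAsFactors = FALSE)
  qo <- qtl_overlap(iv, qtls)
  expect_identical(unname(qo$counts),
                   c(1L, 1L, 0L))   # resistance, morphological, physiological
  expect_identical(sum(qo$matches$qtl == "q1"), 2L)

  ## constructed multi-category fixture returns exact per-category counts
  set.seed(17)
  qt2 <- data.frame(
    name = sprintf("q%02d", 1:9), chrom = "chr2",
    start = seq(100L, 8100L, by = 1000L),
    end = seq(500L, 8500L, by = 1000L),
    category = rep(c("resistance/tolerance", "morphological",
                     "physiological"), times = c(4, 3, 2)),
    stringsAsFactors = FALSE)
  iv2 <- data.frame(chrom = "chr2", start = qt2$start + 10L,
                    end = qt2$start + 20L, id = sprintf("g%02d", 1:9),
                    stringsAsFactors = FALSE)
  expect_identical(unname(qtl_overlap(iv2, qt2)$counts), c(4L, 3L, 2L))
  expect_error(qtl_overlap(iv, transform(qtls, category = "weird")),
               "category")
})

test_that("hypergeometric enrichment matches exact tail sums", {
  ## universe 20, term 5, query 5, overlap 4: p = 76/15504
  ann <- data.frame(gene = paste0("g", 1:5), term = "T1",
                    stringsAsFactors = FALSE)
  universe <- paste0("g", 1:20)
  query <- c(paste0("g", 1:4), "g20")
  r <- hypergeometric_enrichment(query, ann, universe)
  expect_equal(r$p[r$term == "T1"], 76 / 15504, tolerance = 1e-12)

  ## an overlap at its random expectation is unremarkable
  ann2 <- data.frame(gene = paste0("g", 1:10), term = "T2")
  q2 <- c(paste0("g", 1:3), paste0("g", 11:13))  # overlap 3 = 6*10/20
  r2 <- hypergeometric_enrichment(q2, ann2, universe)
  expect_gt(r2$p, 0.3)

  ## a term absent from the query keeps p = 1, never 0
  ann3 <- data.frame(gene = c("g1", "g2"), term = "T3")
  r3 <- hypergeometric_enrichment(c("g19", "g20"), ann3, universe)
  expect_equal(r3$p, 1)

  ## exact enumeration oracle on random small universes
  set.seed(18)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample(2:(N - 2), 1)
    annR <- data.frame(gene = sample(uni, K), term = "T")
    nq <- sample(2:(N - 2), 1)
    qr <- sample(uni, nq)
    k <- length(intersect(annR$gene, qr))
    got <- hypergeometric_enrichment(qr, annR, uni)
    expect_equal(got$p, oracle_hyper_tail(k, K, N, nq), tolerance = 1e-9)
  }
  expect_error(hypergeometric_enrichment("x", ann, universe), "subset")
})
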