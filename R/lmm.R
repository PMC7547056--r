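#' Centered relatedness (kinship) matrix
#'
#' K = W W' / m over the mean-centered dosage columns W, after per-SNP
#' mean imputation of missing dosages and exclusion of monomorphic SNPs.
#' Symmetric and positive semidefinite by construction.
#'
#' @param genotypes a [genotype_matrix()] or a samples x SNPs dosage
#'   matrix.
#' @return samples x samples kinship matrix; attribute
#'   \code{n_snps_used} / \code{n_monomorphic}.
#' @export
kinship <- function(genotypes) {
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
       else genotypes
  stop_if_not(nrow(d) >= 2, "need at least 2 samples")
  d <- impute_mean(d)
  mono <- apply(d, 2, stats::sd) == 0
  if (any(mono)) message(sprintf("%d monomorphic SNP(s) excluded from kinship",
                                 sum(mono)))
  W <- scale(d[, !mono, drop = FALSE], center = TRUE, scale = FALSE)
  m <- ncol(W)
  K <- if (m >= 1) tcrossprod(W) / m else {
    warning("all SNPs monomorphic: kinship is the zero matrix")
    matrix(0, nrow(d), nrow(d))
  }
  dimnames(K) <- list(rownames(d), rownames(d))
  attr(K, "n_snps_used") <- m
  attr(K, "n_monomorphic") <- sum(mono)
  K
}

impute_mean <- function(d) {
  if (!anyNA(d)) return(d)
  for (j in which(colSums(is.na(d)) > 0)) {
    d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  }
  d
}

#' Exact single-trait linear mixed model association scan
#'
#' Fits, for every SNP g, the model y = b0 + g b + u + e with
#' u ~ N(0, sg2 K) and e ~ N(0, se2 I), by exact REML profile likelihood
#' over the variance ratio delta = se2/sg2. One spectral decomposition of
#' K is shared across all SNPs; the REML criterion is evaluated on a
#' log-spaced delta grid for all SNPs at once (three matrix products per
#' scan) and then refined per SNP by Brent search in the bracketing grid
#' interval. The Wald test uses the t distribution with n - 2 degrees of
#' freedom, so with K = I the per-SNP p-value equals the OLS F-test
#' p-value exactly.
#'
#' @param genotypes a [genotype_matrix()] or dosage matrix.
#' @param trait numeric trait vector aligned with samples.
#' @param K kinship matrix from [kinship()] (or its pre-computed eigen
#'   decomposition, as returned by \code{eigen(K, symmetric = TRUE)}).
#' @param min_maf SNPs below this minor-allele frequency are skipped
#'   (default 0.05).
#' @param n_grid points of the log-spaced delta grid (default 80, spanning
#'   1e-5..1e5).
#' @param refine Brent-refine delta per SNP within its grid bracket
#'   (default TRUE).
#' @return data.frame: snp, maf, beta, se, statistic, p, delta.
#' @export
lmm_scan <- function(genotypes, trait, K, min_maf = 0.05, n_grid = 80L,
                     refine = TRUE) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
       else genotypes
  stop_if_not(nrow(G) >= 10, "need at least 10 samples")
  stop_if_not(length(trait) == nrow(G), "trait/sample mismatch")
  stop_if_not(stats::sd(trait) > 0, "degenerate trait (zero variance)")
  G <- impute_mean(G)
  n <- nrow(G)

  maf <- apply(G, 2, dosage_maf)
  use <- which(maf >= min_maf & apply(G, 2, stats::sd) > 0)
  stop_if_not(length(use) > 0, "no SNP passes the MAF filter")

  eg <- if (is.list(K) && !is.null(K$vectors)) K
        else eigen(K, symmetric = TRUE)
  s <- pmax(eg$values, 0)
  stop_if_not(min(eg$values) > -1e-6 * max(abs(eg$values)) - 1e-8,
              "K is not positive semidefinite")
  U <- eg$vectors

  yr <- drop(crossprod(U, trait))
  or_ <- drop(crossprod(U, rep(1, n)))
  Gr <- crossprod(U, G[, use, drop = FALSE])
  Gr2 <- Gr^2
  m <- length(use)

  deltas <- exp(seq(log(1e-5), log(1e5), length.out = n_grid))
  Wmat <- 1 / (outer(s, deltas, "+"))          # n x n_grid weights
  sld <- colSums(log(outer(s, deltas, "+")))   # sum log(s + delta)

  a11 <- colSums(or_^2 * Wmat)
  b1 <- colSums(or_ * yr * Wmat)
  yy <- colSums(yr^2 * Wmat)
  A12 <- crossprod(Gr, or_ * Wmat)             # m x n_grid
  A22 <- crossprod(Gr2, Wmat)
  B2 <- crossprod(Gr, yr * Wmat)

  det <- sweep(A22, 2, a11, "*") - A12^2
  beta <- (sweep(B2, 2, a11, "*") - sweep(A12, 2, b1, "*")) / det
  beta0 <- (sweep(A22, 2, b1, "*") - A12 * B2) / det
  ## RSS = y'Wy - beta0 * b1 - beta * b2
  RSS <- sweep(-(sweep(beta0, 2, b1, "*") + beta * B2), 2, yy, "+")
  RSS[RSS < 1e-12] <- 1e-12
  crit <- (n - 2) * log(RSS) + log(det) +
    matrix(sld, nrow = m, ncol = n_grid, byrow = TRUE)

  best <- max.col(-crit, ties.method = "first")

  reml_crit <- function(delta, g_r) {
    w <- 1 / (s + delta)
    a11s <- sum(or_^2 * w); a12s <- sum(or_ * g_r * w)
    a22s <- sum(g_r^2 * w)
    b1s <- sum(or_ * yr * w); b2s <- sum(g_r * yr * w)
    dets <- a11s * a22s - a12s^2
    bet <- (a11s * b2s - a12s * b1s) / dets
    bet0 <- (a22s * b1s - a12s * b2s) / dets
    rss <- max(sum(yr^2 * w) - bet0 * b1s - bet * b2s, 1e-12)
    (n - 2) * log(rss) + sum(log(s + delta)) + log(dets)
  }

  out <- data.frame(snp = colnames(G)[use], maf = maf[use],
                    beta = NA_real_, se = NA_real_, statistic = NA_real_,
                    p = NA_real_, delta = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_len(m)) {
    k <- best[j]
    dj <- deltas[k]
    if (refine) {
      lo <- deltas[max(1, k - 1)]; hi <- deltas[min(n_grid, k + 1)]
      if (hi > lo) {
        op <- stats::optimize(reml_crit, interval = c(lo, hi),
                              g_r = Gr[, j], tol = 1e-4)
        if (op$objective < crit[j, k]) dj <- op$minimum
      }
    }
    w <- 1 / (s + dj)
    a11s <- sum(or_^2 * w); a12s <- sum(or_ * Gr[, j] * w)
    a22s <- sum(Gr2[, j] * w)
    b1s <- sum(or_ * yr * w); b2s <- sum(Gr[, j] * yr * w)
    dets <- a11s * a22s - a12s^2
    bet <- (a11s * b2s - a12s * b1s) / dets
    bet0 <- (a22s * b1s - a12s * b2s) / dets
    rss <- max(sum(yr^2 * w) - bet0 * b1s - bet * b2s, 0)
    sigma2 <- rss / (n - 2)
    se <- sqrt(sigma2 * a11s / dets)
    tt <- bet / se
    out$beta[j] <- bet; out$se[j] <- se; out$statistic[j] <- tt
    out$p[j] <- 2 * stats::pt(-abs(tt), df = n - 2)
    out$delta[j] <- dj
  }
  out
}

#' Association scan of several hub traits plus omnibus combination
#'
#' Runs [lmm_scan()] per trait (sharing one eigendecomposition of K),
#' combines the per-trait p-values of each SNP into a Sidak omnibus
#' p = 1 - (1 - min_t p_t)^T, and BH-adjusts both the per-trait and the
#' omnibus p-values.
#'
#' @param genotypes a [genotype_matrix()].
#' @param traits samples x traits matrix (e.g. [hub_abundances()]).
#' @param K kinship matrix.
#' @inheritParams lmm_scan
#' @return list: \code{per_trait} (long data.frame with q per trait),
#'   \code{per_snp} (snp, chrom, pos, omnibus_p, omnibus_q, min_trait).
#' @export
scan_hub_traits <- function(genotypes, traits, K, min_maf = 0.05,
                            n_grid = 80L, refine = TRUE) {
  stop_if_not(is.matrix(traits) && !is.null(colnames(traits)),
              "traits must be a named column matrix")
  eg <- eigen(K, symmetric = TRUE)
  res <- lapply(colnames(traits), function(tr) {
    d <- lmm_scan(genotypes, traits[, tr], eg, min_maf = min_maf,
                  n_grid = n_grid, refine = refine)
    d$trait <- tr
    d$q <- fdr_adjust(d$p)
    d
  })
  long <- do.call(rbind, res)
  pmat <- matrix(long$p, ncol = ncol(traits))
  rownames(pmat) <- res[[1]]$snp
  omni <- apply(pmat, 1, omnibus_multitrait)
  map <- if (inherits(genotypes, "genotype_matrix")) genotypes$map else NULL
  per_snp <- data.frame(snp = res[[1]]$snp,
                        omnibus_p = omni,
                        omnibus_q = fdr_adjust(omni),
                        min_trait = colnames(traits)[apply(pmat, 1, which.min)],
                        stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(map)) {
    i <- match(per_snp$snp, map$snp)
    per_snp$chrom <- map$chrom[i]; per_snp$pos <- map$pos[i]
  }
  list(per_trait = long, per_snp = per_snp)
}

#' Sidak omnibus combination of per-trait p-values for one SNP
#'
#' p_omnibus = 1 - (1 - min_t p_t)^T over the T traits; preserves the
#' "significant for at least one hub" semantics while correcting for the
#' number of traits scanned.
#'
#' @param p vector of per-trait p-values (no missing values).
#' @return the omnibus p-value.
#' @export
omnibus_multitrait <- function(p) {
  stop_if_not(!anyNA(p) && length(p) >= 1, "missing trait p-value")
  ## expm1 keeps precision for very small minima
  -expm1(length(p) * log1p(-min(p)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (delegates to \code{p.adjust(method = "BH")}).
#' @param p vector of p-values in (0, 1].
#' @return q-values, same order as input.
#' @export
fdr_adjust <- function(p) {
  stop_if_not(length(p) > 0, "empty p-value vector")
  stats::p.adjust(p, method = "BH")
}

#' Call significant SNPs from a multi-trait scan
#'
#' SNPs whose omnibus p (or BH q, if \code{use_fdr}) falls below the
#' threshold, sorted by chromosome and position; each called SNP is
#' assigned a containing gene when gene models are supplied.
#'
#' @param scan result of [scan_hub_traits()].
#' @param p_threshold significance threshold (default: q < 0.05).
#' @param use_fdr threshold the BH q-value (default TRUE) rather than the
#'   raw omnibus p.
#' @param gene_models optional result of [read_gene_models()].
#' @return data.frame of called SNPs.
#' @export
call_significant <- function(scan, p_threshold = 0.05, use_fdr = TRUE,
                             gene_models = NULL) {
  d <- scan$per_snp
  val <- if (use_fdr) d$omnibus_q else d$omnibus_p
  hits <- d[val < p_threshold, , drop = FALSE]
  if (!is.null(hits$chrom)) {
    hits <- hits[order(hits$chrom, hits$pos), , drop = FALSE]
  }
  if (!is.null(gene_models) && nrow(hits) > 0 && !is.null(hits$chrom)) {
    gr <- GenomicRanges::GRanges(hits$chrom,
                                 IRanges::IRanges(hits$pos, hits$pos))
    ov <- GenomicRanges::findOverlaps(gr, gene_models$genes)
    hits$gene <- NA_character_
    hits$gene[S4Vectors::queryHits(ov)] <-
      gene_models$genes$ID[S4Vectors::subjectHits(ov)]
  }
  rownames(hits) <- NULL
  hits
}

#' Genomic inflation factor
#'
#' lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1); ~1 for a
#' well-calibrated null scan.
#' @param p vector of p-values.
#' @export
lambda_gc <- function(p) {
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' Pairwise haplotype-abundance contrasts at SNPs
#'
#' For each SNP, samples are grouped by genotype (dosage 0/1/2); every
#' group pair with at least \code{min_group} samples each is compared with
#' a two-sided Wilcoxon rank-sum test on the trait (e.g. the CLR abundance
#' of a hub, or the mean of the 12 hubs). BH-FDR is applied across all
#' contrasts performed in the batch.
#'
#' @param genotypes a [genotype_matrix()] (or dosage matrix).
#' @param snps SNP ids to test.
#' @param trait numeric trait vector aligned with samples.
#' @param min_group minimum genotype-group size (default 3); smaller
#'   groups are skipped with a note in the output.
#' @return data.frame: snp, group1, group2, n1, n2, W, p, q (q = NA for
#'   skipped contrasts).
#' @export
haplotype_abundance_test <- function(genotypes, snps, trait, min_group = 3L) {
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
       else genotypes
  rows <- list()
  for (snp in snps) {
    g <- d[, snp]
    lv <- sort(unique(g[!is.na(g)]))
    if (length(lv) < 2) next
    for (a in seq_along(lv)) for (b in seq_along(lv)) {
      if (b <= a) next
      ga <- trait[!is.na(g) & g == lv[a]]
      gb <- trait[!is.na(g) & g == lv[b]]
      skipped <- length(ga) < min_group || length(gb) < min_group
      p <- W <- NA_real_
      if (!skipped) {
        wt <- stats::wilcox.test(ga, gb, alternative = "two.sided",
                                 exact = length(ga) < 50 && length(gb) < 50 &&
                                   !anyDuplicated(c(ga, gb)))
        W <- unname(wt$statistic); p <- wt$p.value
        if (is.na(p)) p <- 1   # all-tied values: no evidence either way
      }
      rows[[length(rows) + 1]] <- data.frame(
        snp = snp, group1 = lv[a], group2 = lv[b],
        n1 = length(ga), n2 = length(gb), W = W, p = p,
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  stop_if_not(length(rows) > 0, "no testable genotype groups")
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  done <- !out$skipped
  if (any(done)) out$q[done] <- fdr_adjust(out$p[done])
  rownames(out) <- NULL
  out
}
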