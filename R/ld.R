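#' Two-locus linkage disequilibrium statistics for inbred genotypes
#'
#' Inbred lines carry their haplotypes in the open: a homozygous dosage
#' pair (0/2 coded) at two SNPs IS a two-locus haplotype, so frequencies
#' are read directly from the genotype columns with no EM phasing.
#' Heterozygous or missing entries are excluded pairwise (count reported).
#'
#' D = p_AB - p_A p_B; D' = D / D_max with the standard sign-dependent
#' D_max; r2 = D^2 / (p_A q_A p_B q_B).
#'
#' @param gi,gj dosage vectors in {0, 2} (1 = heterozygote, dropped).
#' @return list: D, Dprime, r2, n_used, n_excluded, haplotype counts.
#' @export
ld_stats <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj) & gi != 1 & gj != 1
  n_exc <- length(gi) - sum(ok)
  a <- gi[ok] / 2; b <- gj[ok] / 2
  n <- length(a)
  stop_if_not(n >= 2, "fewer than 2 informative haplotypes")
  pA <- mean(a); pB <- mean(b)
  stop_if_not(pA > 0 && pA < 1 && pB > 0 && pB < 1,
              "monomorphic SNP after filtering")
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       Dprime = if (dmax == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       n_used = n, n_excluded = n_exc,
       counts = c(AB = sum(a == 1 & b == 1), Ab = sum(a == 1 & b == 0),
                  aB = sum(a == 0 & b == 1), ab = sum(a == 0 & b == 0)))
}

#' Likelihood-grid confidence interval for |D'|
#'
#' Multinomial likelihood of the four observed haplotype counts evaluated
#' on a |D'| grid (steps of 0.001) with allele frequencies fixed at their
#' MLEs; the CI bounds are the grid quantiles of the normalized
#' likelihood, Wall-Pritchard style.
#'
#' @param counts named haplotype counts (AB, Ab, aB, ab).
#' @param level CI mass (default 0.9, bounds at 5%/95%).
#' @return c(low, high) bounds on |D'|.
#' @export
dprime_ci <- function(counts, level = 0.9) {
  nAB <- counts[["AB"]]; nAb <- counts[["Ab"]]
  naB <- counts[["aB"]]; nab <- counts[["ab"]]
  n <- nAB + nAb + naB + nab
  pA <- (nAB + nAb) / n; pB <- (nAB + naB) / n
  dmax_pos <- min(pA * (1 - pB), (1 - pA) * pB)
  dmax_neg <- min(pA * pB, (1 - pA) * (1 - pB))
  D_hat <- nAB / n - pA * pB
  dmax <- if (D_hat >= 0) dmax_pos else dmax_neg
  sgn <- if (D_hat >= 0) 1 else -1
  grid <- seq(0, 1, by = 0.001)
  D <- sgn * grid * dmax
  f1 <- pA * pB + D; f2 <- pA * (1 - pB) - D
  f3 <- (1 - pA) * pB - D; f4 <- (1 - pA) * (1 - pB) + D
  bad <- f1 < -1e-12 | f2 < -1e-12 | f3 < -1e-12 | f4 < -1e-12
  ll <- nAB * log(pmax(f1, 1e-12)) + nAb * log(pmax(f2, 1e-12)) +
    naB * log(pmax(f3, 1e-12)) + nab * log(pmax(f4, 1e-12))
  ll[bad] <- -Inf
  lk <- exp(ll - max(ll))
  cum <- cumsum(lk) / sum(lk)
  a <- (1 - level) / 2
  lo <- grid[which(cum >= a)[1]]
  hi <- grid[which(cum >= 1 - a)[1]]
  c(low = lo, high = hi)
}

#' Haplotype blocks around significant SNPs
#'
#' Subsets the genotype matrix to a window around each anchor SNP and runs
#' [detect_blocks()] with the anchors supplied, so each significant SNP is
#' reported with its containing block (or a singleton interval).
#'
#' @param genotypes a [genotype_matrix()].
#' @param anchors significant SNP ids.
#' @param window half-width in bp searched around each anchor
#'   (default 100 kb).
#' @param ... passed to [detect_blocks()].
#' @return data.frame of anchored blocks (one row per anchor).
#' @export
blocks_around <- function(genotypes, anchors, window = 1e5, ...) {
  map <- genotypes$map
  ai <- match(anchors, map$snp)
  stop_if_not(!anyNA(ai), "unknown anchor SNP")
  ## merge anchors with overlapping windows so each region is scanned once
  ord <- order(map$chrom[ai], map$pos[ai])
  res <- list()
  grp_anchors <- character(0); grp_chrom <- NA; grp_lo <- grp_hi <- NA
  flush <- function() {
    if (!length(grp_anchors)) return(invisible(NULL))
    keep <- which(map$chrom == grp_chrom & map$pos >= grp_lo &
                    map$pos <= grp_hi)
    sub <- genotype_matrix(genotypes$dosage[, keep, drop = FALSE],
                           map[keep, , drop = FALSE])
    res[[length(res) + 1]] <<- detect_blocks(sub, anchors = grp_anchors, ...)
    invisible(NULL)
  }
  for (k in ord) {
    i <- ai[k]
    lo <- map$pos[i] - window; hi <- map$pos[i] + window
    if (length(grp_anchors) && identical(map$chrom[i], grp_chrom) &&
        lo <= grp_hi) {
      grp_hi <- max(grp_hi, hi)
      grp_anchors <- c(grp_anchors, map$snp[i])
    } else {
      flush()
      grp_anchors <- map$snp[i]; grp_chrom <- map$chrom[i]
      grp_lo <- lo; grp_hi <- hi
    }
  }
  flush()
  out <- do.call(rbind, res)
  ## restore the caller's anchor order
  out <- out[match(anchors, out$anchor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confidence-interval haplotype-block detection
#'
#' Gabriel-style rule on inbred genotypes: a SNP pair is in "strong LD"
#' iff the 90% likelihood CI of |D'| has lower bound >= 0.70 and upper
#' bound >= 0.98. A block is a maximal run of consecutive SNPs in which at
#' least \code{strong_fraction} (default 0.95) of the informative pairs
#' are strong. Candidate intervals are scanned longest-first and accepted
#' greedily without overlap, which makes the result deterministic.
#'
#' @param genotypes a [genotype_matrix()] (inbred, {0,2}).
#' @param chrom chromosome to scan (default: all, one at a time).
#' @param lower_min,upper_min CI thresholds (0.70 / 0.98).
#' @param strong_fraction minimum fraction of strong pairs in a block.
#' @param anchors optional significant-SNP ids; if given, only blocks
#'   containing an anchor are returned (anchors outside any block are
#'   reported as singleton intervals).
#' @param max_span only SNP pairs within this many positions of each
#'   other enter the pair classification (default 500 kb).
#' @return data.frame: chrom, start, end, n_snps, snps (comma-joined),
#'   anchor (NA unless anchored).
#' @export
detect_blocks <- function(genotypes, chrom = NULL, lower_min = 0.70,
                          upper_min = 0.98, strong_fraction = 0.95,
                          anchors = NULL, max_span = 5e5) {
  map <- genotypes$map
  chroms <- if (is.null(chrom)) unique(map$chrom) else chrom
  out <- list()
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    poly <- idx[vapply(idx, function(j) {
      d <- genotypes$dosage[, j]
      d <- d[!is.na(d) & d != 1]
      length(unique(d)) > 1
    }, logical(1))]
    if (length(poly) < 2) next
    pos <- map$pos[poly]
    np <- length(poly)

    strong <- matrix(NA, np, np)   # NA = uninformative pair
    for (a in seq_len(np - 1)) for (b in (a + 1):np) {
      if (pos[b] - pos[a] > max_span) next
      ok <- tryCatch(ld_stats(genotypes$dosage[, poly[a]],
                              genotypes$dosage[, poly[b]]),
                     error = function(e) NULL)
      if (is.null(ok)) next
      ci <- dprime_ci(ok$counts)
      strong[a, b] <- ci["low"] >= lower_min && ci["high"] >= upper_min
    }

    cand <- list()
    for (a in seq_len(np - 1)) {
      n_strong <- 0L; n_inf <- 0L
      for (b in (a + 1):np) {
        if (pos[b] - pos[a] > max_span) break
        vals <- strong[a:(b - 1), b]
        n_strong <- n_strong + sum(vals, na.rm = TRUE)
        n_inf <- n_inf + sum(!is.na(vals))
        if (n_inf > 0 && n_strong / n_inf >= strong_fraction) {
          cand[[length(cand) + 1]] <- c(a, b)
        }
      }
    }
    if (length(cand)) {
      lens <- vapply(cand, function(x) x[2] - x[1], numeric(1))
      taken <- rep(FALSE, np)
      for (i in order(-lens, vapply(cand, `[`, numeric(1), 1))) {
        a <- cand[[i]][1]; b <- cand[[i]][2]
        if (any(taken[a:b])) next
        taken[a:b] <- TRUE
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = pos[a], end = pos[b], n_snps = b - a + 1L,
          snps = paste(map$snp[poly[a:b]], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  blocks <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_snps = integer(0), snps = character(0),
               stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL

  if (!is.null(anchors)) {
    res <- list()
    for (a in anchors) {
      i <- match(a, map$snp)
      stop_if_not(!is.na(i), sprintf("unknown anchor SNP %s", a))
      hit <- which(blocks$chrom == map$chrom[i] & blocks$start <= map$pos[i] &
                     blocks$end >= map$pos[i])
      if (length(hit)) {
        b <- blocks[hit[1], , drop = FALSE]; b$anchor <- a
      } else {
        b <- data.frame(chrom = map$chrom[i], start = map$pos[i],
                        end = map$pos[i], n_snps = 1L, snps = a, anchor = a,
                        stringsAsFactors = FALSE)
      }
      res[[length(res) + 1]] <- b
    }
    blocks <- do.call(rbind, res)
    rownames(blocks) <- NULL
  } else if (nrow(blocks)) {
    blocks$anchor <- NA_character_
  }
  blocks
}
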