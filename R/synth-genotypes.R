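#' Generate inbred genotypes in LD blocks with planted causal SNPs
#'
#' Inbred biallelic dosages in {0, 2} (optional residual heterozygosity at
#' \code{het_rate}). SNPs are partitioned into \code{n_blocks} contiguous
#' blocks laid out along \code{n_chromosomes} chromosomes; within a block,
#' each haplotype copies its allele from the adjacent SNP with probability
#' \code{copy_prob} and otherwise redraws from the SNP's allele frequency
#' (frequencies uniform in \code{maf_range}). This copying process gives
#' high adjacent-SNP r2 that decays along the block and vanishes across
#' block boundaries.
#'
#' \code{n_causal} SNPs with minor-allele frequency at least
#' \code{causal_maf_min} are picked (one block each where possible) and
#' assigned round-robin to the hub traits; each adds
#' \code{causal_effect * dosage / 2} CLR units to its trait. The shifted
#' trait table is returned alongside the genotypes.
#'
#' @param cfg a [synth_config()].
#' @param traits samples x hubs CLR abundance matrix (from
#'   [hub_abundances()]); row count must equal \code{cfg$n_samples}.
#' @param causal_maf_min minimum realized MAF for a causal SNP
#'   (default 0.2, so planted effects are detectable at desk scale).
#' @return list: \code{genotypes} (a [genotype_matrix()]), \code{traits}
#'   (shifted copy), \code{truth} (causal_snp_ids, causal_trait_map,
#'   block assignment).
#' @export
generate_genotypes <- function(cfg, traits, causal_maf_min = 0.2) {
  validate_synth_config(cfg)
  stop_if_not(nrow(traits) == cfg$n_samples, "traits rows must match samples")
  n <- cfg$n_samples; m <- cfg$n_snps
  samples <- rownames(traits) %||% sprintf("ACC%04d", seq_len(n))

  with_subseed(cfg$seed, "genotypes", {
    block <- sort(rep_len(seq_len(cfg$n_blocks), m))
    chrom_of_block <- sort(rep_len(seq_len(cfg$n_chromosomes), cfg$n_blocks))
    chrom <- paste0("chr", chrom_of_block[block])

    ## positions: blocks tile each chromosome with inter-SNP gaps
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      gaps <- sample(200:2000, length(idx), replace = TRUE)
      pos[idx] <- 10000L + cumsum(gaps)
    }

    freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    hap <- matrix(0L, nrow = n, ncol = m)
    for (b in seq_len(cfg$n_blocks)) {
      idx <- which(block == b)
      hap[, idx[1]] <- stats::rbinom(n, 1, freq[idx[1]])
      for (k in seq_along(idx)[-1]) {
        j <- idx[k]
        copy <- stats::runif(n) < cfg$copy_prob
        hap[, j] <- ifelse(copy, hap[, idx[k - 1]],
                           stats::rbinom(n, 1, freq[j]))
      }
    }
    dosage <- 2 * hap
    if (cfg$het_rate > 0) {
      het <- matrix(stats::runif(n * m) < cfg$het_rate, nrow = n)
      dosage[het] <- 1
    }

    snp_id <- sprintf("%s_%d", chrom, pos)
    dimnames(dosage) <- list(samples, snp_id)
    map <- data.frame(snp = snp_id, chrom = chrom, pos = pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
    gm <- genotype_matrix(dosage, map)

    truth <- list(causal_snp_ids = character(0),
                  causal_trait_map = character(0), block = block)
    shifted <- traits
    if (cfg$n_causal > 0) {
      eligible <- which(gm$map$maf >= causal_maf_min)
      stop_if_not(length(eligible) >= cfg$n_causal,
                  "not enough SNPs at the requested causal MAF")
      ## spread causal SNPs over distinct blocks where possible
      eb <- split(eligible, block[eligible])
      picks <- integer(0)
      for (bl in sample(names(eb))) {
        if (length(picks) == cfg$n_causal) break
        cand <- eb[[bl]]
        picks <- c(picks, cand[sample.int(length(cand), 1)])
      }
      if (length(picks) < cfg$n_causal) {
        rest <- setdiff(eligible, picks)
        picks <- c(picks, rest[sample.int(length(rest),
                                          cfg$n_causal - length(picks))])
      }
      picks <- sort(picks)
      hubs <- rep_len(colnames(traits), cfg$n_causal)
      for (i in seq_len(cfg$n_causal)) {
        shifted[, hubs[i]] <- shifted[, hubs[i]] +
          cfg$causal_effect * dosage[, picks[i]] / 2
      }
      truth$causal_snp_ids <- snp_id[picks]
      truth$causal_trait_map <- stats::setNames(hubs, snp_id[picks])
    }
    list(genotypes = gm, traits = shifted, truth = truth)
  })
}
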