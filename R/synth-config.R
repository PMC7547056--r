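#' Configuration for the synthetic phyllosphere study generator
#'
#' Bundles every knob of the synthetic-data module. The defaults emulate a
#' desk-scale version of a rice leaf-microbiome survey: a few hundred inbred
#' accessions grown in two locations with partially disjoint genus pools,
#' heavy-tailed genus abundances, a handful of latent "hub" factors that
#' induce co-occurrence structure, and inbred biallelic genotypes laid out
#' in LD blocks with a small set of SNPs causally shifting hub abundances
#' on the CLR scale.
#'
#' @param n_samples number of accessions (samples).
#' @param n_genera number of bacterial/archaeal genera in the pool.
#' @param n_hubs number of planted hub genera (latent factors).
#' @param hub_loading loading of each latent factor on its hub genus
#'   (log-abundance units per factor SD). Partner genera load at a random
#'   fraction of this (see \code{partner_loading_range}).
#' @param n_partners number of partner genera recruited by each hub factor.
#' @param partner_loading_range partner loadings are drawn uniformly in
#'   \code{hub_loading * partner_loading_range}.
#' @param depth_range integer pair; per-sample total read depth is uniform
#'   on this range.
#' @param n_locations number of growing locations (default 2, e.g. agCh/agPh).
#' @param location_private_fraction fraction of genera private to each
#'   location (absent everywhere else).
#' @param private_occupancy probability that a location-private genus is
#'   present in any one sample of its home location (location-specific
#'   taxa are sporadic, so they sit below a 50% overall prevalence filter).
#' @param base_sd SD of per-genus base log abundance (heavy tail).
#' @param noise_sd per-sample, per-genus log-normal noise SD.
#' @param n_snps,n_blocks number of SNPs and LD blocks.
#' @param n_chromosomes chromosomes the blocks are distributed over.
#' @param copy_prob within-block probability that a haplotype copies its
#'   allele from the adjacent SNP (LD strength).
#' @param het_rate residual heterozygosity rate (inbred lines; <= 1%).
#' @param n_causal number of causal SNPs.
#' @param causal_effect trait shift (CLR units) per alt allele copy pair.
#' @param maf_range minor-allele-frequency range, in (0, 0.5].
#' @param seed master integer seed; every table derives a sub-stream.
#'
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(n_samples = 300L,
                         n_genera = 200L,
                         n_hubs = 5L,
                         hub_loading = 1.0,
                         n_partners = 15L,
                         partner_loading_range = c(0.3, 0.6),
                         depth_range = c(20000L, 100000L),
                         n_locations = 2L,
                         location_private_fraction = 0.1,
                         private_occupancy = 0.6,
                         base_sd = 1.5,
                         noise_sd = 0.7,
                         n_snps = 2000L,
                         n_blocks = 100L,
                         n_chromosomes = 2L,
                         copy_prob = 0.95,
                         het_rate = 0,
                         n_causal = 3L,
                         causal_effect = 1.0,
                         maf_range = c(0.05, 0.5),
                         seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genera = as.integer(n_genera),
    n_hubs = as.integer(n_hubs), hub_loading = hub_loading,
    n_partners = as.integer(n_partners),
    partner_loading_range = partner_loading_range,
    depth_range = as.integer(depth_range), n_locations = as.integer(n_locations),
    location_private_fraction = location_private_fraction,
    private_occupancy = private_occupancy,
    base_sd = base_sd, noise_sd = noise_sd,
    n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
    n_chromosomes = as.integer(n_chromosomes), copy_prob = copy_prob,
    het_rate = het_rate, n_causal = as.integer(n_causal),
    causal_effect = causal_effect, maf_range = maf_range,
    seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stop_if_not(cfg$n_hubs <= cfg$n_genera, "n_hubs must not exceed n_genera")
  stop_if_not(cfg$n_causal <= cfg$n_snps, "n_causal must not exceed n_snps")
  stop_if_not(cfg$depth_range[1] <= cfg$depth_range[2],
              "depth_range must be (min, max) with min <= max")
  stop_if_not(all(cfg$depth_range > 0), "depths must be positive")
  stop_if_not(cfg$n_hubs == 0 || cfg$n_partners >= 3,
              "hub partner sets smaller than 3 are unrecoverable")
  stop_if_not(cfg$location_private_fraction >= 0 &&
                cfg$location_private_fraction <= 1,
              "location_private_fraction must lie in [0, 1]")
  stop_if_not(all(cfg$maf_range > 0) && all(cfg$maf_range <= 0.5) &&
                cfg$maf_range[1] <= cfg$maf_range[2],
              "maf_range must lie in (0, 0.5]")
  stop_if_not(cfg$het_rate <= 0.01, "het_rate above 1% is not inbred material")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic phyllosphere study configuration\n")
  cat(sprintf("  samples: %d  genera: %d  hubs: %d (loading %.2f)\n",
              x$n_samples, x$n_genera, x$n_hubs, x$hub_loading))
  cat(sprintf("  locations: %d (private fraction %.2f)  depth: [%d, %d]\n",
              x$n_locations, x$location_private_fraction,
              x$depth_range[1], x$depth_range[2]))
  cat(sprintf("  SNPs: %d in %d blocks, %d causal (effect %.2f CLR)  seed: %d\n",
              x$n_snps, x$n_blocks, x$n_causal, x$causal_effect, x$seed))
  invisible(x)
}
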