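#' Generate a synthetic genus-count profile with planted hubs
#'
#' Draws a samples x genera count matrix emulating the salient structure of
#' unmapped-read leaf-microbiome profiles: heavy-tailed (log-normal) genus
#' base abundances, latent-factor co-occurrence structure around a set of
#' planted hub genera, per-location private genus pools, and variable
#' sequencing depth with exact multinomial compositionality.
#'
#' Each of the \code{n_hubs} latent factors is a standard-normal sample
#' score that loads with weight \code{hub_loading} onto its hub genus and
#' with a smaller, heterogeneous weight (uniform in
#' \code{hub_loading * partner_loading_range}) onto \code{n_partners}
#' partner genera. The loading asymmetry is what makes the hub the most
#' connected member of its own co-occurrence neighbourhood: hub-partner
#' correlations exceed partner-partner correlations, so correlation-based
#' network inference sees a hub-centred star superimposed on a weak clique.
#'
#' @param cfg a [synth_config()].
#' @return a list with elements \code{profile} (a [taxonomic_profile()])
#'   and \code{truth} (hub ids, partner sets, per-genus base log abundance,
#'   location-private pools, factor scores).
#' @export
generate_counts <- function(cfg) {
  validate_synth_config(cfg)
  n <- cfg$n_samples; g <- cfg$n_genera
  stop_if_not(n >= 1 && g >= 2, "need at least one sample and two genera")

  genera <- sprintf("Genus%03d", seq_len(g))
  samples <- sprintf("ACC%04d", seq_len(n))

  with_subseed(cfg$seed, "counts", {
    ## lineage: ~8 phyla, one archaeal
    phyla <- c("Proteobacteria", "Actinobacteria", "Firmicutes",
               "Bacteroidetes", "Cyanobacteria", "Tenericutes",
               "Verrucomicrobia", "Euryarchaeota")
    phylum <- sample(phyla, g, replace = TRUE,
                     prob = c(0.35, 0.2, 0.15, 0.1, 0.07, 0.05, 0.04, 0.04))
    superkingdom <- ifelse(phylum == "Euryarchaeota", "Archaea", "Bacteria")

    base <- stats::rnorm(g, mean = 0, sd = cfg$base_sd)

    ## planted hubs and their partner sets
    hub_idx <- integer(0); partners <- list(); loadmat <- NULL
    if (cfg$n_hubs > 0) {
      hub_idx <- sample.int(g, cfg$n_hubs)
      pool <- setdiff(seq_len(g), hub_idx)
      stop_if_not(length(pool) >= cfg$n_partners,
                  "not enough non-hub genera to recruit partners")
      loadmat <- matrix(0, nrow = g, ncol = cfg$n_hubs)
      for (h in seq_len(cfg$n_hubs)) {
        p <- sample(pool, cfg$n_partners)
        pool <- setdiff(pool, p)   # refill if exhausted
        if (length(pool) < cfg$n_partners) pool <- setdiff(seq_len(g), hub_idx)
        partners[[h]] <- p
        loadmat[hub_idx[h], h] <- cfg$hub_loading
        loadmat[p, h] <- cfg$hub_loading *
          stats::runif(length(p), cfg$partner_loading_range[1],
                       cfg$partner_loading_range[2])
      }
    }

    ## locations with private genus pools (drawn outside hub machinery
    ## where possible so planted structure survives the location split)
    location <- rep(sprintf("LOC%d", seq_len(cfg$n_locations)), length.out = n)
    n_priv <- floor(cfg$location_private_fraction * g)
    involved <- unique(c(hub_idx, unlist(partners)))
    free <- setdiff(seq_len(g), involved)
    private <- vector("list", cfg$n_locations)
    names(private) <- sprintf("LOC%d", seq_len(cfg$n_locations))
    for (l in seq_len(cfg$n_locations)) {
      take <- min(n_priv, length(free))
      private[[l]] <- sort(sample(free, take))
      free <- setdiff(free, private[[l]])
    }

    factors <- if (cfg$n_hubs > 0) {
      matrix(stats::rnorm(n * cfg$n_hubs), nrow = n)
    } else NULL

    eta <- matrix(rep(base, each = n), nrow = n)
    if (!is.null(factors)) eta <- eta + factors %*% t(loadmat)
    eta <- eta + matrix(stats::rnorm(n * g, sd = cfg$noise_sd), nrow = n)

    ## location mask: a private genus of location l is absent elsewhere
    mask <- matrix(1, nrow = n, ncol = g)
    for (l in seq_len(cfg$n_locations)) {
      if (!length(private[[l]])) next
      others <- which(location != names(private)[l])
      mask[others, private[[l]]] <- 0
      ## sporadic occupancy within the home location
      home <- which(location == names(private)[l])
      occ <- matrix(stats::rbinom(length(home) * length(private[[l]]), 1,
                                  cfg$private_occupancy),
                    nrow = length(home))
      mask[home, private[[l]]] <- occ
    }

    depth <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n,
                    replace = TRUE)
    counts <- matrix(0L, nrow = n, ncol = g,
                     dimnames = list(samples, genera))
    for (i in seq_len(n)) {
      w <- exp(eta[i, ]) * mask[i, ]
      counts[i, ] <- as.integer(stats::rmultinom(1, depth[i], prob = w))
    }

    lineage <- data.frame(genus = genera, superkingdom = superkingdom,
                          phylum = phylum, stringsAsFactors = FALSE)
    metadata <- data.frame(sample = samples, location = location,
                           total_reads = depth, stringsAsFactors = FALSE)
    profile <- taxonomic_profile(counts, lineage, metadata)

    truth <- list(
      hub_genus_ids = genera[hub_idx],
      partner_sets = lapply(partners, function(p) genera[p]),
      base_log_abundance = stats::setNames(base, genera),
      private_pools = lapply(private, function(p) genera[p]),
      factor_scores = factors)
    list(profile = profile, truth = truth)
  })
}

#' CLR abundances of the hub genera
#'
#' Convenience accessor: CLR-transforms the full count matrix and returns
#' the columns of the named hub genera, the trait table fed to the
#' association scan.
#'
#' @param profile a [taxonomic_profile()].
#' @param hubs character vector of hub genus names.
#' @param pseudocount added before the log; default 0.5.
#' @return samples x hubs numeric matrix.
#' @export
hub_abundances <- function(profile, hubs, pseudocount = 0.5) {
  stop_if_not(all(hubs %in% colnames(profile$counts)),
              "unknown hub genus name")
  clr <- clr_transform(profile$counts, pseudocount = pseudocount)
  clr$values[, hubs, drop = FALSE]
}
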