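#' Shannon diversity (nats)
#'
#' H = -sum p_i log p_i over the nonzero proportions of a count vector.
#' Natural log by default (a base switch is provided); delegates to
#' \code{vegan::diversity}.
#'
#' @param x non-negative count (or proportion) vector, sum > 0.
#' @param base logarithm base (default \code{exp(1)} = nats).
#' @return Shannon index H.
#' @export
shannon <- function(x, base = exp(1)) {
  stop_if_not(all(x >= 0), "counts must be non-negative")
  stop_if_not(sum(x) > 0, "all-zero vector has no Shannon index")
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Genus richness
#'
#' Number of strictly positive entries of a count vector.
#' @param x non-negative count vector.
#' @return integer richness.
#' @export
richness <- function(x) {
  stop_if_not(all(x >= 0), "counts must be non-negative")
  sum(x > 0)
}

#' Per-sample diversity summary with group contrasts
#'
#' Richness and Shannon H per sample, plus group means/SDs by a metadata
#' column (e.g. growing location).
#'
#' @param profile a [taxonomic_profile()].
#' @param by metadata column used for grouping (default "location").
#' @return list: \code{per_sample} data.frame (sample, group, richness,
#'   shannon), \code{by_group} data.frame of group means and SDs.
#' @export
diversity_summary <- function(profile, by = "location") {
  m <- profile$counts
  grp <- profile$metadata[[by]]
  per <- data.frame(
    sample = rownames(m), group = grp,
    richness = apply(m, 1, richness),
    shannon = apply(m, 1, shannon),
    stringsAsFactors = FALSE, row.names = NULL)
  agg <- do.call(rbind, lapply(split(per, per$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               mean_richness = mean(d$richness), sd_richness = stats::sd(d$richness),
               mean_shannon = mean(d$shannon), sd_shannon = stats::sd(d$shannon))
  }))
  rownames(agg) <- NULL
  list(per_sample = per, by_group = agg)
}

#' Genus accumulation curve
#'
#' Cumulative richness as samples are added in random order, averaged over
#' permutations (vegan's \code{specaccum(method = "random")}), with a
#' percentile confidence band computed from the per-permutation curves.
#' Deterministic under \code{seed}. The final point equals the total
#' richness for every ordering, so its band has zero width.
#'
#' @param profile a [taxonomic_profile()].
#' @param n_permutations random sample orderings (default 100).
#' @param ci_level confidence level for the percentile band (default 0.95).
#' @param seed integer seed.
#' @return data.frame: k, mean_richness, ci_low, ci_high.
#' @export
accumulation_curve <- function(profile, n_permutations = 100L,
                               ci_level = 0.95, seed = 1L) {
  stop_if_not(n_permutations >= 1, "need at least one permutation")
  stop_if_not(nrow(profile$counts) >= 1, "need at least one sample")
  a <- (1 - ci_level) / 2
  with_subseed(seed, "accumulation", {
    sac <- vegan::specaccum(profile$counts, method = "random",
                            permutations = n_permutations)
    perm <- sac$perm   # sites x permutations cumulative richness
    data.frame(
      k = sac$sites,
      mean_richness = rowMeans(perm),
      ci_low = apply(perm, 1, stats::quantile, probs = a),
      ci_high = apply(perm, 1, stats::quantile, probs = 1 - a),
      row.names = NULL)
  })
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over \code{stats::kruskal.test} with the degenerate
#' all-identical case mapped to H = 0, p = 1 instead of NaN.
#'
#' @param values numeric vector.
#' @param groups group labels, >= 2 non-empty groups.
#' @return list: H, df, p.value.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  stop_if_not(nlevels(droplevels(groups)) >= 2, "need at least 2 groups")
  if (stats::sd(values) == 0) {
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' SIMPER: taxon contributions to between-group Bray-Curtis dissimilarity
#'
#' For two groups, the contribution of taxon i is the mean over all
#' between-group sample pairs (x, y) of |x_i - y_i| / sum_j (x_j + y_j).
#' Contributions therefore sum exactly to the mean between-group
#' Bray-Curtis dissimilarity. Taxa are ranked by contribution and the
#' minimal prefix reaching \code{target_fraction} of the total is flagged.
#'
#' @param rel samples x taxa relative-abundance matrix.
#' @param groups two-level group labels aligned with rows of \code{rel}.
#' @param target_fraction cumulative-contribution target (default 0.7).
#' @return list: \code{contributions} data.frame (taxon, contribution,
#'   cumulative_fraction, in_target_set), \code{mean_dissimilarity},
#'   \code{target_taxa}.
#' @export
simper <- function(rel, groups, target_fraction = 0.7) {
  groups <- as.factor(groups)
  stop_if_not(nlevels(droplevels(groups)) == 2, "SIMPER is two-group only")
  ia <- which(groups == levels(droplevels(groups))[1])
  ib <- which(groups == levels(droplevels(groups))[2])
  stop_if_not(length(ia) > 0 && length(ib) > 0, "empty group")

  contrib <- numeric(ncol(rel))
  npair <- length(ia) * length(ib)
  for (i in ia) {
    xi <- rel[i, ]
    for (j in ib) {
      yj <- rel[j, ]
      denom <- sum(xi + yj)
      if (denom > 0) contrib <- contrib + abs(xi - yj) / denom
    }
  }
  contrib <- contrib / npair
  ord <- order(-contrib, colnames(rel))
  total <- sum(contrib)
  cum <- cumsum(contrib[ord]) / ifelse(total == 0, 1, total)
  n_target <- if (total == 0) 0L else which(cum >= target_fraction)[1]
  tab <- data.frame(taxon = colnames(rel)[ord],
                    contribution = contrib[ord],
                    cumulative_fraction = cum,
                    in_target_set = seq_along(ord) <= n_target,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(contributions = tab, mean_dissimilarity = total,
       target_taxa = tab$taxon[tab$in_target_set])
}
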