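#' Genus-to-pathway weight table
#'
#' Wraps a genus x pathway non-negative weight matrix with an optional
#' pathway hierarchy (KEGG-style class 1 / class 2-3 labels). Rows are
#' normalized to sum to 1 on construction.
#'
#' @param weights genus x pathway matrix with dimnames.
#' @param hierarchy optional data.frame(pathway, class1, class2_3).
#' @return object of class \code{pathway_weights}.
#' @export
pathway_weights <- function(weights, hierarchy = NULL) {
  stop_if_not(all(weights >= 0), "pathway weights must be non-negative")
  rs <- rowSums(weights)
  stop_if_not(all(rs > 0), "every genus row needs positive total weight")
  weights <- weights / rs
  if (!is.null(hierarchy)) {
    stop_if_not(all(colnames(weights) %in% hierarchy$pathway),
                "hierarchy must cover every pathway")
  }
  structure(list(weights = weights, hierarchy = hierarchy),
            class = "pathway_weights")
}

#' Read a pathway weight table from TSV
#'
#' First column genus, remaining columns pathways; an optional hierarchy
#' sidecar TSV has columns pathway, class1, class2_3.
#' @param path weight TSV.
#' @param hierarchy_path optional sidecar TSV.
#' @export
read_pathway_weights <- function(path, hierarchy_path = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  w <- as.matrix(d[, -1, drop = FALSE])
  rownames(w) <- d[[1]]
  h <- if (!is.null(hierarchy_path)) {
    utils::read.delim(hierarchy_path, stringsAsFactors = FALSE)
  } else NULL
  pathway_weights(w, h)
}

#' Project community composition onto pathway profiles
#'
#' Abundance-weighted mapping: the community function profile is
#' \code{rel \%*\% weights} over the shared genus universe, row-renormalized.
#' Genera without pathway annotation are reported and renormalized away.
#' Before renormalization the projected mass of a sample equals its covered
#' (annotated) abundance fraction, which is returned as an attribute.
#'
#' @param rel samples x genera relative-abundance matrix.
#' @param weights a [pathway_weights()].
#' @return samples x pathways proportion matrix (rows sum to 1); attributes
#'   \code{covered_fraction} (per sample) and \code{uncovered_genera}.
#' @export
project_functions <- function(rel, weights) {
  common <- intersect(colnames(rel), rownames(weights$weights))
  stop_if_not(length(common) > 0, "no genus overlap with the weight table")
  uncovered <- setdiff(colnames(rel), common)
  raw <- rel[, common, drop = FALSE] %*%
    weights$weights[common, , drop = FALSE]
  covered <- rowSums(rel[, common, drop = FALSE])
  out <- raw / ifelse(covered == 0, 1, covered)
  attr(out, "covered_fraction") <- covered
  attr(out, "uncovered_genera") <- uncovered
  out
}

#' Aggregate a function profile to a hierarchy level
#'
#' @param profile samples x pathways matrix from [project_functions()].
#' @param weights the [pathway_weights()] carrying the hierarchy.
#' @param level hierarchy column name (e.g. "class1").
#' @export
aggregate_functions <- function(profile, weights, level = "class1") {
  stop_if_not(!is.null(weights$hierarchy), "no hierarchy attached")
  lab <- weights$hierarchy[[level]][
    match(colnames(profile), weights$hierarchy$pathway)]
  t(rowsum(t(profile), group = lab))
}

#' Compare two community function profiles
#'
#' Two-sided Wilcoxon rank-sum test on the per-pathway mean abundances of
#' the two groups (the pathway sets are aligned first).
#'
#' @param profile_a,profile_b samples x pathways matrices for the two
#'   groups.
#' @return list: statistic (W), p.value, n_pathways.
#' @export
compare_function_profiles <- function(profile_a, profile_b) {
  common <- intersect(colnames(profile_a), colnames(profile_b))
  stop_if_not(length(common) >= 2, "need at least 2 shared pathways")
  ma <- colMeans(profile_a[, common, drop = FALSE])
  mb <- colMeans(profile_b[, common, drop = FALSE])
  wt <- stats::wilcox.test(ma, mb, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_pathways = length(common))
}
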