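#' Infer a co-occurrence network from CLR abundances
#'
#' Pairwise Pearson (or Spearman) association between CLR columns. An edge
#' is kept iff |r| >= \code{min_abs_r} AND its permutation-null BH-FDR
#' q-value is below \code{fdr_alpha}. The null is built by independently
#' permuting the sample order of every column \code{n_permutations} times
#' and pooling all null |r| values; the empirical p of an observed pair is
#' (1 + #null >= |r|) / (1 + #null).
#'
#' Constant columns have undefined correlations and are excluded with a
#' warning before inference.
#'
#' @param clr a \code{clr_matrix} from [clr_transform()] (or a plain
#'   samples x taxa matrix).
#' @param method "pearson" or "spearman".
#' @param min_abs_r absolute-correlation threshold (default 0.3).
#' @param n_permutations permutations for the null (default 50).
#' @param fdr_alpha BH FDR level (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return a \code{co_network}: list with \code{edges} (data.frame from,
#'   to, weight, p, q), \code{nodes}, and the igraph \code{graph}.
#' @export
infer_edges <- function(clr, method = c("pearson", "spearman"),
                        min_abs_r = 0.3, n_permutations = 50L,
                        fdr_alpha = 0.05, seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(clr, "clr_matrix")) clr$values else clr
  stop_if_not(nrow(x) >= 3, "need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant column(s) excluded", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  p_taxa <- ncol(x)
  stop_if_not(p_taxa >= 2, "need at least 2 variable taxa")

  r <- stats::cor(x, method = method)
  ut <- upper.tri(r)
  obs <- abs(r[ut])

  null_abs <- with_subseed(seed, "edge-perm", {
    out <- numeric(0)
    for (b in seq_len(n_permutations)) {
      xp <- apply(x, 2, sample)
      rp <- stats::cor(xp, method = method)
      out <- c(out, abs(rp[upper.tri(rp)]))
    }
    out
  })
  ns <- sort(null_abs)
  ## p = (1 + #null >= obs) / (1 + n_null), via a single sorted lookup
  p <- (1 + length(ns) - findInterval(obs, ns, left.open = TRUE)) /
    (1 + length(ns))
  q <- stats::p.adjust(p, method = "BH")

  idx <- which(ut, arr.ind = TRUE)
  keep <- obs >= min_abs_r & q < fdr_alpha
  edges <- data.frame(
    from = colnames(x)[idx[keep, 1]],
    to = colnames(x)[idx[keep, 2]],
    weight = r[ut][keep], p = p[keep], q = q[keep],
    stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = colnames(x))
  igraph::E(g)$weight <- edges$weight
  structure(list(edges = edges, nodes = colnames(x), graph = g,
                 params = list(method = method, min_abs_r = min_abs_r,
                               n_permutations = n_permutations,
                               fdr_alpha = fdr_alpha, seed = seed)),
            class = "co_network")
}

#' Build a co_network directly from an edge list
#'
#' Used by tests and by callers that obtained edges elsewhere.
#' @param edges data.frame(from, to, weight).
#' @param nodes character vector of all node names (defaults to those in
#'   the edge list).
#' @export
co_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  stop_if_not(!any(edges$from == edges$to), "self-edges are not allowed")
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  igraph::E(g)$weight <- edges$weight
  structure(list(edges = edges, nodes = nodes, graph = g, params = list()),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("co-occurrence network: %d nodes, %d edges, mean degree %.2f\n",
              s["n_nodes"], s["n_edges"], s["average_degree"]))
  invisible(x)
}

#' Per-node network metrics
#'
#' Weighted degree (sum of |weight| over incident edges), betweenness
#' centrality on the unweighted skeleton (correlation weights are
#' similarities, not distances), local clustering coefficient on the
#' skeleton, and eigenvector centrality of the |weight| adjacency computed
#' per connected component and max-normalized within each component
#' (a disconnected graph is allowed; the component id is reported).
#'
#' @param network a \code{co_network}.
#' @return data.frame: node, weighted_degree, betweenness, clustering,
#'   eigencentrality, component.
#' @export
node_metrics <- function(network) {
  g <- network$graph
  stop_if_not(igraph::vcount(g) > 0, "empty network")
  w <- abs(igraph::E(g)$weight %||% rep(1, igraph::ecount(g)))

  gs <- g
  if (igraph::ecount(gs) > 0) gs <- igraph::delete_edge_attr(g, "weight")
  btw <- igraph::betweenness(gs, directed = FALSE, normalized = FALSE)
  cc <- igraph::transitivity(gs, type = "localundirected", isolates = "zero")

  wdeg <- igraph::strength(g, weights = w)

  ## deterministic eigencentrality: dense symmetric eigen of the |w|
  ## adjacency, per component, max-normalized (ARPACK's random restarts
  ## would break run-to-run reproducibility)
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = if
    (igraph::ecount(g) > 0) "weight" else NULL, sparse = TRUE))
  A <- abs(A)
  comp <- igraph::components(g)
  eig <- numeric(igraph::vcount(g))
  for (k in seq_len(comp$no)) {
    vs <- which(comp$membership == k)
    if (length(vs) == 1 || sum(A[vs, vs]) == 0) { eig[vs] <- 0; next }
    es <- eigen(A[vs, vs, drop = FALSE], symmetric = TRUE)
    v <- abs(es$vectors[, which.max(es$values)])
    eig[vs] <- v / max(v)
  }

  data.frame(node = igraph::V(g)$name,
             weighted_degree = as.numeric(wdeg),
             betweenness = as.numeric(btw),
             clustering = as.numeric(cc),
             eigencentrality = eig,
             component = comp$membership,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Louvain module detection
#'
#' Greedy modularity optimization on the |weight| graph; deterministic
#' under the supplied seed.
#'
#' @param network a \code{co_network}.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed.
#' @return list: \code{membership} (named integer vector), \code{Q}
#'   (modularity of the partition), \code{n_modules}.
#' @export
detect_modules <- function(network, resolution = 1, seed = 1L) {
  g <- network$graph
  stop_if_not(igraph::ecount(g) > 0, "module detection needs at least one edge")
  w <- abs(igraph::E(g)$weight %||% rep(1, igraph::ecount(g)))
  cl <- with_subseed(seed, "louvain",
                     igraph::cluster_louvain(g, weights = w,
                                             resolution = resolution))
  memb <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(memb), igraph::V(g)$name),
       Q = igraph::modularity(g, memb, weights = w),
       n_modules = length(unique(memb)))
}

#' Composite hub scoring
#'
#' The composite is the weighted mean of within-network z-scores of
#' weighted degree, betweenness and eigencentrality (equal weights by
#' default). Clustering coefficient and module label are reported per hub
#' but not scored: modularity class is categorical, and true hubs tend to
#' have low local clustering. Ties are broken deterministically by node
#' name.
#'
#' @param metrics data.frame from [node_metrics()].
#' @param k number of hubs to call (default 12).
#' @param weights length-3 numeric: weights for (weighted_degree,
#'   betweenness, eigencentrality).
#' @param modules optional membership vector from [detect_modules()].
#' @return list: \code{scores} (full ranked table), \code{hubs}
#'   (character vector of the k hub nodes).
#' @export
score_hubs <- function(metrics, k = 12L, weights = c(1, 1, 1),
                       modules = NULL) {
  stop_if_not(k >= 1, "k must be at least 1")
  stop_if_not(k <= nrow(metrics), "k exceeds the number of nodes")
  stop_if_not(length(weights) == 3 && sum(weights) > 0, "invalid weights")
  z <- cbind(zscore(metrics$weighted_degree),
             zscore(metrics$betweenness),
             zscore(metrics$eigencentrality))
  composite <- as.numeric(z %*% (weights / sum(weights)))
  tab <- metrics
  tab$composite <- composite
  if (!is.null(modules)) tab$module <- modules[tab$node]
  ord <- order(-tab$composite, tab$node)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$is_hub <- seq_len(nrow(tab)) <= k
  list(scores = tab, hubs = tab$node[seq_len(k)])
}

#' Global network summary
#'
#' @param network a \code{co_network}.
#' @param modules optional result of [detect_modules()]; its Q is reported
#'   (NA for an edgeless graph or when not supplied).
#' @return named numeric vector: n_nodes, n_edges, average_degree, Q.
#' @export
network_summary <- function(network, modules = NULL) {
  g <- network$graph
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  q <- if (!is.null(modules)) modules$Q else NA_real_
  c(n_nodes = n, n_edges = m,
    average_degree = if (n > 0) 2 * m / n else NA_real_,
    Q = q)
}
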