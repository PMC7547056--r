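test_that("CLR transform has zero row sums and scale invariance", {
  x <- rbind(c(1, 1, 1, 1), c(1, 10, 100, 1000))
  clr <- clr_transform(x, pseudocount = 0)
  expect_equal(unname(clr$values[1, ]), c(0, 0, 0, 0))
  expect_equal(unname(clr_transform(rbind(c(1, 10, 100)), 0)$values[1, ]),
               c(-log(10), 0, log(10)), tolerance = 1e-12)
  ## clr(2x) = clr(x) at zero pseudocount
  expect_equal(clr_transform(2 * x, 0)$values, clr_transform(x, 0)$values)
  expect_error(clr_transform(matrix(-1)), "non-negative")
  expect_error(clr_transform(matrix(c(0, 1), 1), pseudocount = 0),
               "pseudocount")
})

test_that("edge inference keeps perfect correlations of either sign", {
  set.seed(3)
  z <- rnorm(60)
  x <- cbind(a = z, b = z, c = -z, d = rnorm(60))
  net <- infer_edges(x, min_abs_r = 0.3, n_permutations = 40, seed = 1)
  key <- paste(net$edges$from, net$edges$to)
  expect_true("a b" %in% key)
  expect_true("a c" %in% key)
  wab <- net$edges$weight[key == "a b"]
  wac <- net$edges$weight[key == "a c"]
  expect_equal(wab, 1, tolerance = 1e-12)
  expect_equal(wac, -1, tolerance = 1e-12)
})

test_that("constant columns are excluded with a warning", {
  x <- cbind(a = rnorm(30), b = rep(1, 30), c = rnorm(30))
  expect_warning(net <- infer_edges(x, n_permutations = 10, seed = 1),
                 "constant")
  expect_false("b" %in% net$nodes)
})

test_that("independent columns produce almost no edges", {
  set.seed(5)
  x <- matrix(rnorm(500 * 30), 500, 30,
              dimnames = list(NULL, paste0("g", 1:30)))
  net <- infer_edges(x, min_abs_r = 0, n_permutations = 40,
                     fdr_alpha = 0.05, seed = 2)
  n_pairs <- choose(30, 2)
  retention <- nrow(net$edges) / n_pairs
  expect_lte(retention, 0.05 + 2 * sqrt(0.05 * 0.95 / n_pairs))
})

test_that("node metrics match hand geometry on canonical graphs", {
  ## 5-node star: center betweenness (n-1)(n-2)/2 = 6, leaves 0
  star <- data.frame(from = "hub", to = paste0("leaf", 1:4), weight = 1)
  ns <- co_network(star)
  m <- node_metrics(ns)
  expect_equal(m$betweenness[m$node == "hub"], 6)
  expect_true(all(m$betweenness[m$node != "hub"] == 0))
  expect_equal(score_hubs(m, k = 1)$hubs, "hub")

  ## triangle: clustering 1 everywhere
  tri <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                    weight = c(0.5, 0.5, 0.5))
  mt <- node_metrics(co_network(tri))
  expect_true(all(mt$clustering == 1))

  ## complete graph with equal weights: eigencentrality all equal (max 1)
  k5 <- random_graph(5, p_edge = 2)      # p > 1 keeps every edge
  k5$weight <- 0.7
  mk <- node_metrics(co_network(k5))
  expect_true(all(abs(mk$eigencentrality - 1) < 1e-9))
})

test_that("metrics agree with brute-force oracles on small graphs", {
  ## exhaustive over all 4-node graphs, then random 5-7 node graphs
  nodes4 <- graph_nodes(4)
  pairs4 <- t(combn(4, 2))
  for (code in 0:63) {
    keep <- as.logical(intToBits(code))[1:6]
    if (sum(keep) == 0) next
    edges <- data.frame(from = paste0("n", pairs4[keep, 1]),
                        to = paste0("n", pairs4[keep, 2]),
                        weight = 1, stringsAsFactors = FALSE)
    net <- co_network(edges, nodes4)
    m <- node_metrics(net)
    expect_equal(setNames(m$betweenness, m$node),
                 oracle_betweenness(edges, nodes4), tolerance = 1e-9)
    expect_equal(setNames(m$clustering, m$node),
                 oracle_clustering(edges, nodes4), tolerance = 1e-9)
  }

  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:7, 1)
    edges <- random_graph(n, p_edge = 0.55)
    if (nrow(edges) == 0) next
    nodes <- graph_nodes(n)
    net <- co_network(edges, nodes)
    m <- node_metrics(net)
    expect_equal(setNames(m$betweenness, m$node),
                 oracle_betweenness(edges, nodes), tolerance = 1e-9)
    expect_equal(setNames(m$clustering, m$node),
                 oracle_clustering(edges, nodes), tolerance = 1e-9)
    expect_equal(setNames(m$eigencentrality, m$node),
                 oracle_eigencentrality(edges, nodes), tolerance = 1e-6)
    ## weighted degree = sum of |w| on incident edges
    wd <- sapply(nodes, function(v)
      sum(abs(edges$weight[edges$from == v | edges$to == v])))
    expect_equal(setNames(m$weighted_degree, m$node), wd, tolerance = 1e-12)
  }
})

test_that("module detection separates disconnected cliques", {
  clique <- function(tag) {
    p <- t(combn(5, 2))
    data.frame(from = paste0(tag, p[, 1]), to = paste0(tag, p[, 2]),
               weight = 1, stringsAsFactors = FALSE)
  }
  two <- rbind(clique("a"), clique("b"))
  net <- co_network(two)
  mod <- detect_modules(net, seed = 1)
  expect_identical(mod$n_modules, 2L)
  expect_equal(mod$Q, 0.5, tolerance = 1e-12)
  ## members split exactly by clique
  expect_length(unique(mod$membership[paste0("a", 1:5)]), 1)
  expect_length(unique(mod$membership[paste0("b", 1:5)]), 1)

  one <- co_network(clique("a"))
  expect_identical(detect_modules(one, seed = 1)$n_modules, 1L)

  ## node relabeling yields the same partition up to label names
  two_shuf <- two[sample(nrow(two)), ]
  mod2 <- detect_modules(co_network(two_shuf), seed = 1)
  expect_identical(mod2$n_modules, 2L)
  expect_equal(mod2$Q, 0.5, tolerance = 1e-12)

  ## partition modularity never below the one-module baseline
  set.seed(11)
  for (i in 1:5) {
    e <- random_graph(8, 0.4)
    if (nrow(e) < 2) next
    netr <- co_network(e)
    mr <- detect_modules(netr, seed = 3)
    g <- netr$graph
    q1 <- igraph::modularity(g, rep(1, igraph::vcount(g)),
                             weights = abs(igraph::E(g)$weight))
    expect_gte(mr$Q, q1 - 1e-12)
  }
})

test_that("hub scoring uses the composite with a lexicographic tie-break", {
  ## all-equal metrics: the k lexicographically first nodes win
  m <- data.frame(node = c("d", "b", "a", "c"), weighted_degree = 1,
                  betweenness = 1, clustering = 0, eigencentrality = 1,
                  component = 1)
  expect_identical(score_hubs(m, k = 2)$hubs, c("a", "b"))
  expect_error(score_hubs(m, k = 0), "at least 1")
  expect_error(score_hubs(m, k = 9), "exceeds")

  ## weights shift the ranking
  m2 <- data.frame(node = c("deg", "btw"), weighted_degree = c(10, 0),
                   betweenness = c(0, 10), clustering = 0,
                   eigencentrality = c(1, 1), component = 1)
  expect_identical(score_hubs(m2, k = 1, weights = c(1, 0, 0))$hubs, "deg")
  expect_identical(score_hubs(m2, k = 1, weights = c(0, 1, 0))$hubs, "btw")
})

test_that("network summary reports size, degree and modularity", {
  tri <- co_network(data.frame(from = c("a", "a", "b"),
                               to = c("b", "c", "c"), weight = 1))
  s <- network_summary(tri, detect_modules(tri, seed = 1))
  expect_equal(unname(s[c("n_nodes", "n_edges", "average_degree")]),
               c(3, 3, 2))

  lone <- co_network(data.frame(from = character(0), to = character(0),
                                weight = numeric(0)), nodes = letters[1:5])
  s0 <- network_summary(lone)
  expect_equal(unname(s0["n_edges"]), 0)
  expect_true(is.na(s0["Q"]))

  clique <- function(tag) {
    p <- t(combn(5, 2))
    data.frame(from = paste0(tag, p[, 1]), to = paste0(tag, p[, 2]),
               weight = 1, stringsAsFactors = FALSE)
  }
  two <- co_network(rbind(clique("a"), clique("b")))
  s2 <- network_summary(two, detect_modules(two, seed = 1))
  expect_equal(unname(s2), c(10, 20, 4, 0.5))
})

test_that("abundance does not buy hub status", {
  ## a very abundant genus with no co-occurrence partners stays out of
  ## the hub set
  cfg <- synth_config(n_samples = 300, n_genera = 100, n_hubs = 3,
                      hub_loading = 1.0, location_private_fraction = 0,
                      seed = 23)
  sim <- generate_counts(cfg)
  counts <- sim$profile$counts
  free <- setdiff(colnames(counts),
                  c(sim$truth$hub_genus_ids, unlist(sim$truth$partner_sets)))
  loud <- free[1]
  counts[, loud] <- counts[, loud] + 5000L   # dominant but independent
  prof <- taxonomic_profile(counts, sim$profile$lineage,
                            sim$profile$metadata)
  net <- infer_edges(clr_transform(prevalence_filter(prof, 0.5)$counts),
                     n_permutations = 30, seed = 1)
  hubs <- score_hubs(node_metrics(net), k = 3)$hubs
  expect_false(loud %in% hubs)
})
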