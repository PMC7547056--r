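# Independent brute-force oracles. These deliberately share no code with
# the implementation (and avoid igraph/vegan): direct enumeration, hand
# DP, closed forms.

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

oracle_bray_curtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

# SIMPER contributions by direct pair loop
oracle_simper <- function(rel, groups) {
  lv <- unique(groups)
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  contrib <- rep(0, ncol(rel))
  for (i in ia) for (j in ib) {
    contrib <- contrib + abs(rel[i, ] - rel[j, ]) / sum(rel[i, ] + rel[j, ])
  }
  unname(contrib / (length(ia) * length(ib)))
}

# Kruskal-Wallis with tie correction from first principles
oracle_kruskal <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  groups <- as.factor(groups)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(g) sum(g)^2 / length(g))) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / corr
  list(H = H, p = stats::pchisq(H, df = nlevels(groups) - 1,
                                lower.tail = FALSE))
}

# BH step-up by definition: q_(i) = min_{j >= i} m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# --- graph oracles (adjacency-matrix based, unit skeleton) ------------

adj_from_edges <- function(edges, nodes) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges$from[k], edges$to[k]] <- abs(edges$weight[k])
    A[edges$to[k], edges$from[k]] <- abs(edges$weight[k])
  }
  A
}

# BFS distances and shortest-path counts from source s (level-synchronous)
bfs_sigma <- function(S, s) {  # S: unweighted 0/1 adjacency
  n <- nrow(S)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  level <- s
  while (length(level)) {
    nxt <- integer(0)
    for (v in level) {
      for (u in which(S[v, ] > 0)) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
        if (dist[u] == dist[v] + 1) sigma[u] <- sigma[u] + sigma[v]
      }
    }
    level <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

oracle_betweenness <- function(edges, nodes) {
  S <- (adj_from_edges(edges, nodes) > 0) * 1
  n <- length(nodes)
  bt <- rep(0, n)
  info <- lapply(seq_len(n), function(s) bfs_sigma(S, s))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(info[[s]]$dist[t])) next
    d <- info[[s]]$dist[t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (info[[s]]$dist[v] + info[[t]]$dist[v] == d) {
        bt[v] <- bt[v] +
          info[[s]]$sigma[v] * info[[t]]$sigma[v] / info[[s]]$sigma[t]
      }
    }
  }
  stats::setNames(bt, nodes)
}

oracle_clustering <- function(edges, nodes) {
  S <- (adj_from_edges(edges, nodes) > 0) * 1
  vapply(seq_along(nodes), function(v) {
    nb <- which(S[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(S[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1)) |> stats::setNames(nodes)
}

# eigencentrality per connected component by power iteration on |w|,
# max-normalized within component
oracle_eigencentrality <- function(edges, nodes) {
  A <- adj_from_edges(edges, nodes)
  n <- length(nodes)
  ## components by reachability
  S <- (A > 0) * 1
  R <- diag(n) + S
  for (i in seq_len(n)) R <- (R %*% (diag(n) + S) > 0) * 1
  comp <- rep(NA_integer_, n); cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) { cid <- cid + 1; comp[which(R[v, ] > 0)] <- cid }
  }
  out <- rep(0, n)
  for (k in unique(comp)) {
    vs <- which(comp == k)
    if (length(vs) == 1 || sum(A[vs, vs]) == 0) { out[vs] <- 0; next }
    x <- rep(1, length(vs))
    Ak <- A[vs, vs, drop = FALSE]
    ## spectral shift keeps bipartite components from oscillating while
    ## leaving the principal eigenvector unchanged
    Ak <- Ak + diag(max(rowSums(Ak)) + 1, length(vs))
    for (it in 1:2000) {
      y <- Ak %*% x
      x <- y / sqrt(sum(y^2))
    }
    x <- abs(as.numeric(x))
    out[vs] <- x / max(x)
  }
  stats::setNames(out, nodes)
}

# modularity of a partition (unit weights)
oracle_modularity <- function(edges, nodes, membership) {
  m <- nrow(edges)
  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  ein <- sum(membership[edges$from] == membership[edges$to])
  dc <- tapply(as.numeric(deg), membership[nodes], sum)
  ein / m - sum((dc / (2 * m))^2)
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  bell <- c(1, 1, 2, 5, 15, 52, 203, 877, 4140, 21147, 115975)
  out <- vector("list", bell[n + 1])
  cnt <- 0L
  a <- integer(n)
  recurse <- function(i, mx) {
    if (i > n) {
      cnt <<- cnt + 1L
      out[[cnt]] <<- a[1:n]
      return(invisible(NULL))
    }
    for (v in 1:(mx + 1)) {
      a[i] <<- v
      recurse(i + 1, max(mx, v))
    }
  }
  a[1] <- 1L
  if (n == 1) return(list(1L))
  recurse(2, 1)
  out
}

# hypergeometric upper tail by direct combinatorial sum
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# 2x2 LD stats from a haplotype table
oracle_ld <- function(a, b) {   # a, b in {0,1} haplotypes
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  n <- sum(tab)
  pA <- sum(tab[2, ]) / n; pB <- sum(tab[, 2]) / n
  pAB <- tab[2, 2] / n
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = if (dmax == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}
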