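# Independent oracles used to cross-check the package implementations.
# None of these call package internals or igraph.

# --- graph oracles -----------------------------------------------------------

# adjacency list from an integer edge matrix over nodes 1..n
oracle_adj <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# BFS from s: hop distances and shortest-path counts (layer-by-layer DP)
oracle_bfs <- function(adj, s, n) {
  dist <- rep(Inf, n); sig <- numeric(n)
  dist[s] <- 0; sig[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sig[v] <- sig[v] + sig[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sig = sig)
}

# exhaustive pair-by-pair betweenness: for every unordered reachable pair
# (s,t) and every interior v, add sig(s,v)*sig(v,t)/sig(s,t) when v lies on
# a shortest s-t path; normalize by 2/((N-1)(N-2)) within each component.
oracle_betweenness <- function(n, edges) {
  adj <- oracle_adj(n, edges)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s, n))
  raw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      dst <- bfs[[s]]$dist[t]
      if (is.infinite(dst)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst) {
          raw[v] <- raw[v] + bfs[[s]]$sig[v] * bfs[[t]]$sig[v] / bfs[[s]]$sig[t]
        }
      }
    }
  }
  comp_size <- vapply(seq_len(n), function(v) sum(is.finite(bfs[[v]]$dist)),
                      numeric(1))
  ifelse(comp_size > 2, raw * 2 / ((comp_size - 1) * (comp_size - 2)), 0)
}

oracle_avg_path <- function(n, edges) {
  adj <- oracle_adj(n, edges)
  vapply(seq_len(n), function(s) {
    d <- oracle_bfs(adj, s, n)$dist
    d <- d[-s][is.finite(d[-s])]
    if (length(d) == 0) NA_real_ else mean(d)
  }, numeric(1))
}

# seeded random Erdos-Renyi edge list over nodes "n1".."nN"
random_graph <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p_edge
    list(n = n, edges = pairs[keep, , drop = FALSE])
  })
}

int_edges_to_net <- function(n, edges) {
  ids <- sprintf("n%02d", seq_len(n))
  netmet::network_new(cbind(ids[edges[, 1]], ids[edges[, 2]]), nodes = ids)
}

# --- prioritization oracle ---------------------------------------------------

# literal two-pass transcription of the ranking statistic
oracle_r_score <- function(xi, xj, w = 0.5, floor = 1e-5) {
  xj <- pmax(xj, floor)
  inv <- 1 / xj
  t1 <- if (max(xi) == min(xi)) rep(0, length(xi)) else
    (xi - min(xi)) / (max(xi) - min(xi))
  t2 <- if (max(inv) == min(inv)) rep(0, length(inv)) else
    (inv - min(inv)) / (max(inv) - min(inv))
  w * t1 + (1 - w) * t2
}

# --- enrichment oracles ------------------------------------------------------

# exhaustive enumeration of all size-n draws from a universe of size N:
# P[overlap with a set of size K >= k]
oracle_hyper_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)   # WLOG the set is elements 1..K
}

# literal BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# --- simulation helper for PLS tests ----------------------------------------

planted_matrix <- function(seed, n_per_group = 12, p = 50, k = 5, shift = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p)
    y <- rep(c("control", "treated"), each = n_per_group)
    X[y == "treated", seq_len(k)] <- X[y == "treated", seq_len(k)] + shift
    list(X = X, y = y)
  })
}

noise_matrix <- function(seed, n_per_group = 12, p = 50) {
  planted_matrix(seed, n_per_group, p, k = 0, shift = 0)
}

# balanced-effect recovery panel: n_changed metabolites altered in
# offsetting up/down pairs so row-sum normalization stays undistorted
recovery_panel <- function(n_total = 20, n_changed = 4, ratio = 1.25) {
  # 0.31 steps keep every resonance at a bin center (x.xx5)
  shifts <- seq(1.005, 8.905, by = 0.31)
  shifts <- shifts[shifts < 4.4 | shifts >= 5.1]  # keep clear of water window
  shifts <- shifts[seq_len(n_total)]
  ratios <- rep(1, n_total)
  ratios[seq_len(n_changed)] <- rep(c(ratio, 1 / ratio),
                                    length.out = n_changed)
  lapply(seq_len(n_total), function(i) {
    list(name = paste0("met", i), shifts = shifts[i], weights = 1,
         base = 1, ratio = ratios[i])
  })
}
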