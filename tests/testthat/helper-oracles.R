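# Independent brute-force oracles. These deliberately avoid igraph's and
# stats' implementations of the quantities they check: centralities are
# recomputed by per-pair shortest-path counting over BFS distance/count
# tables, the hypergeometric tail by summing binomial coefficients, and
# BH by the literal step-up formula.

# adjacency list (integer indices) from an igraph object's edge list
adj_list <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# BFS from s: hop distances and number of distinct shortest paths
bfs_counts <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n); sigma <- numeric(n)
  d[s] <- 0; sigma[s] <- 1
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
      if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  list(d = d, sigma = sigma)
}

# normalized betweenness and closeness by exhaustive pair enumeration
oracle_centralities <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- adj_list(g)
  bfs <- lapply(seq_len(n), function(s) bfs_counts(adj, s))
  bc <- numeric(n); cc <- numeric(n)
  for (v in seq_len(n)) {
    dv <- bfs[[v]]$d[-v]
    dv <- dv[is.finite(dv)]
    cc[v] <- if (length(dv)) length(dv) / sum(dv) else 0
  }
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        dst <- bfs[[s]]$d[t]
        if (!is.finite(dst)) next
        for (v in seq_len(n)) {
          if (v == s || v == t) next
          if (bfs[[s]]$d[v] + bfs[[t]]$d[v] == dst) {
            bc[v] <- bc[v] +
              bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
          }
        }
      }
    }
    bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  list(BC = stats::setNames(bc, nm), CC = stats::setNames(cc, nm),
       dist = lapply(bfs, `[[`, "d"))
}

# exact hypergeometric pmf and upper tail from binomial coefficients
oracle_hyper_pmf <- function(k, K, n, N) {
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- seq(k, min(n, K))
  sum(oracle_hyper_pmf(ks, K, n, N))
}

# literal Benjamini-Hochberg step-up: q_i = min over p_j >= p_i of m*p_j/rank_j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- integer(m); ranks[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / ranks[p >= p[i]]))
  }, numeric(1))
}

# random named test graph (Erdos-Renyi), possibly disconnected
random_test_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.05, 0.5)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# random centrality table for screening property tests
random_centrality_table <- function(n) {
  tab <- data.frame(node = sprintf("N%03d", seq_len(n)),
                    DC = sample(0:30, n, replace = TRUE),
                    BC = stats::runif(n), CC = stats::runif(n),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$DC, tab$node), ]
  rownames(tab) <- NULL
  structure(tab, class = c("centrality_table", "data.frame"))
}

edge_keys_of <- function(g) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) return(character(0))
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

make_named_graph <- function(edges, isolated = character()) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}
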