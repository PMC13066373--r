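# Independent brute-force oracles used across test files.

# O(n^2) interduration extraction: for every entity, scan all contacts.
brute_interdurations <- function(contacts, level) {
  if (level == "node") {
    ids <- sort(unique(c(contacts$i, contacts$j)))
    out <- numeric(0)
    for (id in ids) {
      tt <- sort(contacts$t_start[contacts$i == id | contacts$j == id])
      if (length(tt) >= 2) out <- c(out, diff(tt))
    }
    out
  } else {
    keys <- unique(paste(contacts$i, contacts$j))
    out <- numeric(0)
    for (k in keys) {
      sel <- paste(contacts$i, contacts$j) == k
      tt <- sort(contacts$t_start[sel])
      if (length(tt) >= 2) out <- c(out, diff(tt))
    }
    out
  }
}

# brute-force graph statistics from an adjacency matrix
brute_graph_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  m <- sum(adj) / 2
  density <- m / (n * (n - 1) / 2)
  tri <- 0; triples <- 0; local_c <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k >= 2) {
      links <- sum(adj[nb, nb]) / 2
      local_c[v] <- links / choose(k, 2)
      tri <- tri + links
      triples <- triples + choose(k, 2)
    } else {
      local_c[v] <- 0
    }
  }
  list(density = density,
       clustering = mean(local_c),
       transitivity = if (triples > 0) tri / triples else NaN)
}

# modularity of a partition on an undirected graph (Newman's definition)
brute_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (membership[u] == membership[v]) {
      q <- q + adj[u, v] - deg[u] * deg[v] / (2 * m)
    }
  }
  q / (2 * m)
}
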