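# Small graph constructors used across tests.

graph_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  fc_graph(a)
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  fc_graph(a)
}

path_graph <- function(n) {
  graph_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

cycle_graph <- function(n) {
  graph_from_edges(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                        list(c(n, 1))))
}

star_graph <- function(n) {
  # node 1 is the center
  graph_from_edges(n, lapply(2:n, function(i) c(1, i)))
}

random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  fc_graph(a)
}

# Ring lattice on n nodes, each connected to its k nearest neighbours
# (k even), optionally rewired with probability p per edge endpoint
# (Watts-Strogatz construction).
watts_strogatz_graph <- function(n, k, p = 0) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(k / 2)) {
      t <- ((i - 1 + j) %% n) + 1
      a[i, t] <- 1L
      a[t, i] <- 1L
    }
  }
  if (p > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(k / 2)) {
        t <- ((i - 1 + j) %% n) + 1
        if (stats::runif(1) < p) {
          candidates <- which(a[i, ] == 0L)
          candidates <- setdiff(candidates, i)
          if (length(candidates) > 0) {
            new_t <- candidates[sample.int(length(candidates), 1)]
            a[i, t] <- 0L
            a[t, i] <- 0L
            a[i, new_t] <- 1L
            a[new_t, i] <- 1L
          }
        }
      }
    }
  }
  fc_graph(a)
}
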