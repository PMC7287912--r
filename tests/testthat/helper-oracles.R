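# Independent oracles: an established graph library (igraph) and, for small
# graphs, brute-force enumeration of simple paths. Both are kept fully
# independent of the package's own metric code.

igraph_metric_oracle <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  d <- igraph::distances(ig)
  diag(d) <- NA
  apl <- apply(d, 1, function(r) {
    f <- r[is.finite(r) & !is.na(r)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  geff <- apply(1 / d, 1, function(r) mean(r, na.rm = TRUE))
  # neighbor-subgraph local efficiency composed from library primitives
  leff <- vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(g$adjacency[i, ] == 1L)
    if (length(nb) < 2) return(0)
    dsub <- igraph::distances(igraph::induced_subgraph(ig, nb))
    mean(1 / dsub[upper.tri(dsub)])
  }, numeric(1))
  list(
    degree = as.numeric(igraph::degree(ig)),
    clustering = as.numeric(igraph::transitivity(ig, type = "local",
                                                 isolates = "zero")),
    average_path_length = as.numeric(apl),
    local_efficiency = leff,
    global_efficiency = as.numeric(geff),
    betweenness = as.numeric(igraph::betweenness(ig, directed = FALSE))
  )
}

# Brute force: enumerate every simple path between every ordered pair by
# depth-first search; derive distances, shortest-path counts, and the number
# of shortest paths through each intermediate node.
bf_path_census <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  through <- array(0, dim = c(n, n, n)) # [s, t, v]
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L))
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      best <- Inf
      shortest <- list()
      stack <- list(list(v = s, visited = s))
      while (length(stack) > 0) {
        fr <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (fr$v == t) {
          len <- length(fr$visited) - 1
          if (len < best) {
            best <- len
            shortest <- list(fr$visited)
          } else if (len == best) {
            shortest[[length(shortest) + 1]] <- fr$visited
          }
          next
        }
        for (w in nbrs[[fr$v]]) {
          if (!(w %in% fr$visited)) {
            stack[[length(stack) + 1]] <- list(v = w, visited = c(fr$visited, w))
          }
        }
      }
      dist[s, t] <- best
      sigma[s, t] <- length(shortest)
      for (pth in shortest) {
        inner <- setdiff(pth, c(s, t))
        for (v in inner) through[s, t, v] <- through[s, t, v] + 1
      }
    }
  }
  list(dist = dist, sigma = sigma, through = through)
}

bf_metric_oracle <- function(g) {
  adj <- g$adjacency
  n <- nrow(adj)
  census <- bf_path_census(adj)
  d <- census$dist
  degree <- rowSums(adj)
  clustering <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
  dd <- d
  diag(dd) <- NA
  apl <- apply(dd, 1, function(r) {
    f <- r[is.finite(r) & !is.na(r)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  geff <- apply(1 / dd, 1, function(r) mean(r, na.rm = TRUE))
  leff <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1L)
    if (length(nb) < 2) return(0)
    dsub <- bf_path_census(adj[nb, nb, drop = FALSE])$dist
    mean(1 / dsub[upper.tri(dsub)])
  }, numeric(1))
  btw <- vapply(seq_len(n), function(v) {
    total <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || census$sigma[s, t] == 0) next
        total <- total + census$through[s, t, v] / census$sigma[s, t]
      }
    }
    total
  }, numeric(1))
  list(degree = degree, clustering = clustering, average_path_length = apl,
       local_efficiency = leff, global_efficiency = geff, betweenness = btw)
}

package_metric_vectors <- function(g) {
  list(
    degree = as.numeric(node_degree(g)),
    clustering = as.numeric(node_clustering(g)),
    average_path_length = as.numeric(suppressWarnings(node_avg_path_length(g))),
    local_efficiency = as.numeric(node_local_efficiency(g)),
    global_efficiency = as.numeric(node_global_efficiency(g)),
    betweenness = as.numeric(node_betweenness(g))
  )
}

expect_metrics_match <- function(mine, oracle, tol = 1e-10) {
  for (nm in names(mine)) {
    a <- mine[[nm]]
    b <- oracle[[nm]]
    both_na <- is.na(a) & is.na(b)
    expect_true(all(both_na | abs(a - b) < tol),
                label = paste0("metric '", nm, "' matches oracle"))
  }
}

# Literal enumeration oracle for the exact Wilcoxon signed-rank p-value:
# walk all 2^m sign assignments of the ranked absolute differences.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
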