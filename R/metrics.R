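#' Nodal and global graph indexes on binary undirected graphs
#'
#' These functions implement, from first principles, the indexes commonly
#' used to characterize thresholded functional-connectivity networks:
#' degree, clustering coefficient, nodal average path length, local and
#' global efficiency, betweenness centrality, and the network-level
#' characteristic path length. All operate on [fc_graph] objects. Graphs
#' disconnected by aggressive thresholding are handled with the standard
#' connectome conventions: path-length statistics average over reachable
#' pairs only, and efficiency-type metrics treat unreachable pairs as
#' contributing zero (1/infinity).
#'
#' @param g An [fc_graph].
#' @name graph-metrics
NULL

#' @describeIn graph-metrics Number of edges incident to each node (row sums
#'   of the adjacency matrix).
#' @export
node_degree <- function(g) {
  stopifnot(inherits(g, "fc_graph"))
  k <- rowSums(g$adjacency)
  names(k) <- g$labels
  k
}

#' @describeIn graph-metrics Fraction of each node's neighbor pairs that are
#'   themselves connected: `2 t_i / (k_i (k_i - 1))` with `t_i` the triangle
#'   count through node i; zero for nodes of degree < 2.
#' @export
node_clustering <- function(g) {
  stopifnot(inherits(g, "fc_graph"))
  a <- g$adjacency
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  cc <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  names(cc) <- g$labels
  cc
}

# Breadth-first hop distances from every source; Inf marks unreachable.
#' @describeIn graph-metrics All-pairs shortest-path hop counts; `Inf`
#'   flags unreachable pairs, diagonal is zero.
#' @export
graph_distances <- function(g) {
  stopifnot(inherits(g, "fc_graph"))
  a <- g$adjacency
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] == 1L))
  d <- matrix(Inf, n, n, dimnames = list(g$labels, g$labels))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      for (w in nbrs[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

#' @describeIn graph-metrics Mean hop distance from each node to its
#'   reachable peers; `NA` (with a warning) for isolated nodes, which are
#'   excluded from downstream statistics.
#' @export
node_avg_path_length <- function(g) {
  d <- graph_distances(g)
  diag(d) <- NA
  out <- apply(d, 1, function(row) {
    finite <- row[is.finite(row) & !is.na(row)]
    if (length(finite) == 0) NA_real_ else mean(finite)
  })
  if (anyNA(out)) {
    warn(paste0("Isolated node(s) with undefined average path length: ",
                paste(names(out)[is.na(out)], collapse = ", ")))
  }
  out
}

#' @describeIn graph-metrics Mean shortest-path length over all reachable
#'   unordered node pairs of the whole graph; errors if the graph has no
#'   edges.
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "fc_graph"))
  if (g$n_edges == 0) abort("Characteristic path length undefined: graph has no edges.")
  d <- graph_distances(g)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

#' @describeIn graph-metrics Nodal global efficiency: mean over peers of the
#'   inverse shortest-path distance, with unreachable peers contributing 0.
#'   Lies in `[0, 1]`; isolated nodes score 0.
#' @export
node_global_efficiency <- function(g) {
  d <- graph_distances(g)
  inv <- 1 / d
  diag(inv) <- NA
  out <- apply(inv, 1, function(row) mean(row, na.rm = TRUE))
  # n = 1 edge case: no peers at all
  if (nrow(d) == 1) out[] <- 0
  out
}

#' @describeIn graph-metrics Local efficiency: global efficiency of the
#'   subgraph induced by each node's neighbors (the node itself excluded);
#'   0 for nodes with fewer than two neighbors.
#' @export
node_local_efficiency <- function(g) {
  stopifnot(inherits(g, "fc_graph"))
  a <- g$adjacency
  n <- nrow(a)
  out <- numeric(n)
  names(out) <- g$labels
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2) next
    sub <- fc_graph(a[nb, nb, drop = FALSE])
    dsub <- graph_distances(sub)
    inv <- 1 / dsub[upper.tri(dsub)]
    out[i] <- mean(inv)
  }
  out
}

#' @describeIn graph-metrics Betweenness centrality by Brandes'
#'   accumulation: for each node, the summed fraction of all-pairs shortest
#'   paths passing through it. Unnormalized by default; with
#'   `normalized = TRUE` divided by `(N-1)(N-2)/2`.
#' @export
node_betweenness <- function(g, normalized = FALSE) {
  stopifnot(inherits(g, "fc_graph"))
  a <- g$adjacency
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] == 1L))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    preds <- vector("list", n)
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (idx in rev(seq_len(tail))) {
      w <- queue[idx]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # undirected: each (s, t) pair was accumulated twice
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  names(bc) <- g$labels
  bc
}

#' All nodal indexes of a binary graph as a tibble
#'
#' Convenience wrapper computing the six nodal indexes in one pass.
#'
#' @param g An [fc_graph].
#' @param normalized_betweenness Normalize betweenness by `(N-1)(N-2)/2`?
#' @return A tibble with one row per node and columns `roi`, `degree`,
#'   `clustering_coefficient`, `average_path_length`, `local_efficiency`,
#'   `global_efficiency`, `betweenness_centrality`.
#' @examples
#' g <- fc_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
#' graph_metrics(g)
#' @export
graph_metrics <- function(g, normalized_betweenness = FALSE) {
  stopifnot(inherits(g, "fc_graph"))
  tibble::tibble(
    roi = g$labels,
    degree = as.numeric(node_degree(g)),
    clustering_coefficient = as.numeric(node_clustering(g)),
    average_path_length = suppressWarnings(as.numeric(node_avg_path_length(g))),
    local_efficiency = as.numeric(node_local_efficiency(g)),
    global_efficiency = as.numeric(node_global_efficiency(g)),
    betweenness_centrality = as.numeric(node_betweenness(g, normalized_betweenness))
  )
}

#' Nodal metrics for every subject, session and density of a cohort
#'
#' Runs correlation, thresholding and [graph_metrics()] over an entire
#' paired cohort, returning the long table used by [compare_cohort()].
#'
#' @param cohort An `fc_cohort` (or any tibble with `subject`, `session`,
#'   `data` columns of volumes-by-ROI matrices).
#' @param densities Connection densities to threshold at.
#' @param ranking Edge ranking convention, see [threshold_to_density()].
#' @return A long tibble (subject, session, density, roi, metric, value).
#' @export
cohort_metrics <- function(cohort, densities = seq(0.05, 0.40, by = 0.05),
                           ranking = "positive") {
  rows <- purrr::pmap(
    list(cohort$subject, as.character(cohort$session), cohort$data),
    function(subject, session, data) {
      m <- pearson_matrix(data)
      purrr::map(densities, function(k) {
        g <- threshold_to_density(m, k, ranking = ranking)
        tab <- graph_metrics(g)
        tab$subject <- subject
        tab$session <- session
        tab$density <- k
        tab
      })
    }
  )
  wide <- dplyr::bind_rows(purrr::flatten(rows))
  out <- tidyr::pivot_longer(
    wide,
    cols = c("degree", "clustering_coefficient", "average_path_length",
             "local_efficiency", "global_efficiency", "betweenness_centrality"),
    names_to = "metric", values_to = "value"
  )
  dplyr::select(out, "subject", "session", "density", "roi", "metric", "value")
}
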