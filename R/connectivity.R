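#' Pearson functional-connectivity matrix from ROI time series
#'
#' Computes the pairwise Pearson correlation between ROI columns of a
#' volumes-by-ROI time-series matrix. The diagonal is forced to zero, the
#' field's adjacency-matrix convention (self-connection is meaningless).
#'
#' @param ts A numeric matrix (volumes x ROIs) with ROI labels as column
#'   names, or the `data` entry of an `fc_cohort` row.
#' @return An `fc_connectivity` matrix: symmetric, zero diagonal, attribute
#'   `kind = "pearson"`.
#' @examples
#' ts <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' pearson_matrix(ts)
#' @export
pearson_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) abort("At least 3 volumes are required.")
  v <- apply(ts, 2, sd)
  if (any(v == 0 | is.na(v))) {
    bad <- colnames(ts)[which(v == 0 | is.na(v))]
    if (is.null(bad)) bad <- which(v == 0 | is.na(v))
    abort(paste0("Zero-variance ROI column(s): ", paste(bad, collapse = ", ")))
  }
  m <- cor(ts)
  diag(m) <- 0
  m <- (m + t(m)) / 2
  structure(m, kind = "pearson", class = c("fc_connectivity", "matrix", "array"))
}

#' Fisher z-transform of a correlation matrix
#'
#' Entry-wise `atanh`; a variance-stabilizing transform sometimes applied
#' before thresholding. It is monotone, so proportional density thresholding
#' is unaffected by it; exposed for completeness, off by default in the
#' pipeline.
#'
#' @param m An `fc_connectivity` matrix of kind `"pearson"`.
#' @return An `fc_connectivity` matrix of kind `"fisher_z"`.
#' @export
fisher_z <- function(m) {
  if (!identical(attr(m, "kind"), "pearson")) {
    abort("`fisher_z()` expects a Pearson connectivity matrix.")
  }
  vals <- unclass(m)
  if (any(abs(vals) >= 1)) {
    warn("Correlations with |r| = 1 clipped to 1 - 1e-7 before atanh.")
    vals <- pmin(pmax(vals, -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- atanh(vals)
  diag(z) <- 0
  structure(z, kind = "fisher_z", class = c("fc_connectivity", "matrix", "array"))
}

#' Binarize a connectivity matrix at a target connection density
#'
#' Keeps the `E = round(density * N(N-1)/2)` strongest edges (round half up,
#' minimum one edge) and discards the rest, yielding an undirected,
#' unweighted graph. By default edges are ranked by signed correlation
#' descending (strongest positive first), the common resting-state
#' convention; set `ranking = "absolute"` to rank by magnitude. Ties at the
#' cutoff weight are broken lexicographically on the (row, column) index
#' pair, with a warning, so results are reproducible across platforms.
#'
#' @param m Symmetric connectivity matrix (an `fc_connectivity` or plain
#'   numeric matrix).
#' @param density Target connection density in (0, 1].
#' @param ranking `"positive"` (signed, default) or `"absolute"`.
#' @return An `fc_graph`: list with `adjacency` (0/1 symmetric matrix, zero
#'   diagonal), `density` (realized), `density_target` and `labels`.
#' @examples
#' m <- pearson_matrix(matrix(rnorm(400), 100, 4))
#' g <- threshold_to_density(m, 0.5)
#' g$density
#' @export
threshold_to_density <- function(m, density, ranking = c("positive", "absolute")) {
  ranking <- match.arg(ranking)
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m) || max(abs(m - t(m))) > 1e-10) {
    abort("`m` must be a symmetric square matrix.")
  }
  if (!is_scalar_number(density) || density <= 0 || density > 1) {
    abort("`density` must lie in (0, 1].")
  }
  n_pairs <- n * (n - 1) / 2
  n_edges <- max(1L, as.integer(round_half_up(density * n_pairs)))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  if (ranking == "absolute") w <- abs(w)
  # order: weight descending, then lexicographic (i, j) for determinism
  ord <- order(-w, ut[, 1], ut[, 2])
  if (n_edges < n_pairs && isTRUE(w[ord[n_edges]] == w[ord[n_edges + 1]])) {
    warn("Ties span the density cutoff; broken lexicographically on node indices.")
  }
  keep <- ord[seq_len(n_edges)]
  adj <- matrix(0L, n, n, dimnames = dimnames(m))
  idx <- ut[keep, , drop = FALSE]
  adj[idx] <- 1L
  adj[idx[, c(2, 1), drop = FALSE]] <- 1L
  fc_graph(adj, density_target = density)
}

#' Construct a binary graph object from a 0/1 adjacency matrix
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param density_target Optional nominal density recorded alongside the
#'   realized density.
#' @return An `fc_graph` object.
#' @export
fc_graph <- function(adjacency, density_target = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) abort("Adjacency must be square.")
  if (any(adjacency != 0 & adjacency != 1)) abort("Adjacency must be 0/1.")
  if (any(diag(adjacency) != 0)) abort("Self-loops are not allowed.")
  if (max(abs(adjacency - t(adjacency))) > 0) abort("Adjacency must be symmetric.")
  storage.mode(adjacency) <- "integer"
  n_edges <- sum(adjacency) / 2
  structure(
    list(
      adjacency = adjacency,
      n_nodes = n,
      n_edges = as.integer(n_edges),
      density = if (n > 1) n_edges / (n * (n - 1) / 2) else 0,
      density_target = density_target,
      labels = rownames(adjacency) %||% as.character(seq_len(n))
    ),
    class = "fc_graph"
  )
}

#' @export
print.fc_graph <- function(x, ...) {
  cat(sprintf("<fc_graph> %d nodes, %d edges (density %.3f)\n",
              x$n_nodes, x$n_edges, x$density))
  invisible(x)
}

#' Edge list of a binary graph
#'
#' @param g An `fc_graph`.
#' @return Tibble with columns `from`, `to` (ROI labels, upper triangle).
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "fc_graph"))
  idx <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  tibble::tibble(from = g$labels[idx[, 1]], to = g$labels[idx[, 2]])
}

#' Write a connectivity matrix as labeled CSV
#' @param m Connectivity matrix with ROI dimnames.
#' @param path Output file.
#' @export
write_connectivity_csv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) {
    dimnames(m) <- list(paste0("V", seq_len(nrow(m))),
                        paste0("V", seq_len(ncol(m))))
  }
  df <- tibble::as_tibble(m, rownames = "roi")
  readr::write_csv(df, path)
  invisible(path)
}

#' Write a binary graph as an edge-list TSV
#' @param g An `fc_graph`.
#' @param path Output file.
#' @export
write_edgelist_tsv <- function(g, path) {
  readr::write_tsv(graph_edges(g), path)
  invisible(path)
}

#' Write a binary graph as GraphML
#' @param g An `fc_graph`.
#' @param path Output file.
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "fc_graph"))
  edges <- graph_edges(g)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"/>', g$labels),
    sprintf('    <edge source="%s" target="%s"/>', edges$from, edges$to),
    "  </graph>",
    "</graphml>"
  )
  writeLines(lines, path)
  invisible(path)
}
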