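#' Null-model configuration for small-worldness estimation
#'
#' @param rewires_per_edge Attempted degree-preserving double-edge swaps per
#'   edge (default 1000).
#' @param ensemble_size Number of independent rewired reference networks to
#'   average over. The default of 1 mirrors the single-reference convention
#'   common in small clinical studies; 20 or more gives a much less noisy
#'   reference and is recommended.
#' @param seed Optional seed for the null-model random stream, decoupled
#'   from any cohort seed.
#' @return An `fc_null_config` list.
#' @export
null_config <- function(rewires_per_edge = 1000, ensemble_size = 1, seed = NULL) {
  stopifnot(rewires_per_edge >= 1, ensemble_size >= 1)
  structure(
    list(rewires_per_edge = as.integer(rewires_per_edge),
         ensemble_size = as.integer(ensemble_size),
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "fc_null_config"
  )
}

#' Degree-preserving random rewiring of a binary graph
#'
#' Generates a randomized reference network with exactly the same degree
#' sequence and edge count as the input, by `rewires_per_edge * E` attempted
#' double-edge swaps (Maslov–Sneppen). Swaps that would introduce a
#' self-loop or multi-edge are skipped, so the graph stays simple; graphs
#' that are the unique realization of their degree sequence (e.g. complete
#' graphs) are returned unchanged.
#'
#' @param g An [fc_graph] with at least 2 edges.
#' @param cfg An [null_config()]. If `cfg$seed` is set, the swap stream is
#'   seeded locally; otherwise the current RNG state is consumed.
#' @return A rewired [fc_graph].
#' @export
rewire_preserving_degree <- function(g, cfg = null_config()) {
  stopifnot(inherits(g, "fc_graph"), inherits(cfg, "fc_null_config"))
  if (g$n_edges < 2) abort("Rewiring needs at least 2 edges.")
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  idx <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  edges <- rewire_edgelist_cpp(idx, g$n_nodes,
                               as.double(cfg$rewires_per_edge) * g$n_edges)
  adj <- matrix(0L, g$n_nodes, g$n_nodes,
                dimnames = dimnames(g$adjacency))
  adj[edges] <- 1L
  adj[edges[, c(2, 1), drop = FALSE]] <- 1L
  fc_graph(adj, density_target = g$density_target)
}

# Mean clustering over all nodes (isolates contribute 0) and characteristic
# path length over reachable pairs: the two network-level summaries entering
# the small-worldness ratio.
graph_cl_summary <- function(g) {
  list(C = mean(node_clustering(g)), L = characteristic_path_length(g))
}

#' Small-worldness of one binary graph against a degree-matched null
#'
#' Computes the real network's mean clustering coefficient `C_real` and
#' characteristic path length `L_real`, the same quantities averaged over an
#' ensemble of degree-preserving rewired reference networks (`C_rand`,
#' `L_rand`), and the ratios `g = C_real/C_rand`, `l = L_real/L_rand` and
#' small-worldness `s = g/l`. A value of `s` above 1 indicates small-world
#' organization (more clustered than random at comparable path length).
#'
#' If the null ensemble is triangle-free (`C_rand = 0`), `g` and `s` are
#' undefined and returned as `NA` with a warning.
#'
#' @param g An [fc_graph] with at least one reachable pair.
#' @param cfg An [null_config()].
#' @param null_graphs Optional list of [fc_graph]s to use as the reference
#'   ensemble instead of generating one (testing hook).
#' @return A one-row tibble: `density`, `C_real`, `L_real`, `C_rand`,
#'   `L_rand`, `g`, `l`, `s`.
#' @export
smallworld_record <- function(g, cfg = null_config(), null_graphs = NULL) {
  stopifnot(inherits(g, "fc_graph"))
  if (g$n_edges == 0) abort("Small-worldness undefined: graph has no edges.")
  real <- graph_cl_summary(g)
  if (is.null(null_graphs)) {
    if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
    cfg_inner <- null_config(cfg$rewires_per_edge, 1)
    null_graphs <- lapply(seq_len(cfg$ensemble_size), function(i) {
      rewire_preserving_degree(g, cfg_inner)
    })
  }
  nulls <- lapply(null_graphs, graph_cl_summary)
  C_rand <- mean(vapply(nulls, `[[`, numeric(1), "C"))
  L_rand <- mean(vapply(nulls, `[[`, numeric(1), "L"))
  if (C_rand == 0) {
    warn("Triangle-free null ensemble: small-worldness undefined, recorded as NA.")
    gg <- NA_real_
  } else {
    gg <- real$C / C_rand
  }
  ll <- real$L / L_rand
  tibble::tibble(
    density = g$density_target %||% g$density,
    C_real = real$C, L_real = real$L,
    C_rand = C_rand, L_rand = L_rand,
    g = gg, l = ll, s = gg / ll
  )
}

#' Small-worldness curve over a density sweep
#'
#' Thresholds one connectivity matrix at each requested density and computes
#' a [smallworld_record()] for each resulting graph.
#'
#' @param m Symmetric connectivity matrix.
#' @param densities Vector of densities in (0, 1]; default 5% to 40% in 5%
#'   steps.
#' @param cfg An [null_config()].
#' @param ranking Edge ranking convention, see [threshold_to_density()].
#' @return An `fc_sweep` tibble, one row per density.
#' @examples
#' m <- pearson_matrix(matrix(rnorm(150 * 14), 150, 14))
#' smallworld_sweep(m, densities = c(0.2, 0.25), cfg = null_config(50))
#' @export
smallworld_sweep <- function(m, densities = seq(0.05, 0.40, by = 0.05),
                             cfg = null_config(), ranking = "positive") {
  if (length(densities) == 0) abort("`densities` must be non-empty.")
  if (any(densities <= 0 | densities > 1)) abort("Densities must lie in (0, 1].")
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  cfg_inner <- null_config(cfg$rewires_per_edge, cfg$ensemble_size)
  out <- dplyr::bind_rows(lapply(densities, function(k) {
    g <- threshold_to_density(m, k, ranking = ranking)
    smallworld_record(g, cfg_inner)
  }))
  class(out) <- c("fc_sweep", class(out))
  out
}

#' Plot a small-worldness sweep
#'
#' @param object An `fc_sweep` tibble (possibly row-bound over sessions with
#'   a `session` column).
#' @param ... Unused.
#' @return A ggplot of `s` against density, with the `s = 1` reference line.
#' @method autoplot fc_sweep
#' @export
autoplot.fc_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$density, y = .data$s))
  if ("session" %in% names(object)) {
    p <- p + ggplot2::aes(colour = .data$session, group = .data$session)
  }
  p +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "connection density", y = "small-worldness s(k)")
}
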