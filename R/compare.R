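#' Small-worldness sweeps for every subject and session of a cohort
#'
#' @param cohort An `fc_cohort` (or compatible tibble).
#' @param densities Densities for the sweep.
#' @param cfg An [null_config()]; per-session null streams are derived from
#'   `cfg$seed` when set.
#' @param ranking Edge ranking convention.
#' @return Tibble (subject, session, density, C_real, L_real, C_rand,
#'   L_rand, g, l, s), classed `fc_sweep`.
#' @export
cohort_sweep <- function(cohort, densities = seq(0.05, 0.40, by = 0.05),
                         cfg = null_config(), ranking = "positive") {
  rows <- purrr::pmap(
    list(cohort$subject, as.character(cohort$session), cohort$data,
         seq_len(nrow(cohort))),
    function(subject, session, data, i) {
      m <- pearson_matrix(data)
      cfg_i <- null_config(
        cfg$rewires_per_edge, cfg$ensemble_size,
        seed = if (!is.null(cfg$seed)) derive_seed(cfg$seed, i, 3L)
      )
      sw <- smallworld_sweep(m, densities, cfg_i, ranking = ranking)
      sw$subject <- subject
      sw$session <- session
      sw
    }
  )
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "subject", "session", dplyr::everything())
  class(out) <- c("fc_sweep", class(out))
  out
}

#' Paired pre/post comparison of every graph index
#'
#' Runs a Wilcoxon signed-rank test per (ROI, metric) cell — at the
#' reference density by default — and per density for small-worldness, and
#' flags cells with `p < alpha`. The direction of a flagged change is the
#' sign of the median within-subject difference (`increase` / `decrease`).
#'
#' No multiple-comparison correction is applied by default, matching the
#' uncorrected per-cell reporting convention of small exploratory imaging
#' studies; `correction = "BH"` applies Benjamini–Hochberg across all rows
#' for stricter modern use.
#'
#' @param metrics Long metric table from [cohort_metrics()].
#' @param sweep Optional small-worldness table from [cohort_sweep()].
#' @param alpha Significance level (default 0.05).
#' @param density_mode `"reference"` (default; nodal indexes compared at
#'   `reference_density` only), `"each"` (one row per density) or
#'   `"aggregate"` (indexes averaged over the sweep before testing).
#' @param reference_density Density highlighted for nodal comparisons
#'   (default 0.25).
#' @param mode Wilcoxon mode, see [wilcoxon_signed_rank()].
#' @param correction `"none"` (default) or `"BH"`.
#' @return An `fc_comparison` tibble: `roi`, `metric`, `density`, `n_pairs`,
#'   `W`, `p_value`, `direction`, `median_pre`, `median_post`,
#'   `significant`; attribute `alpha`.
#' @export
compare_cohort <- function(metrics, sweep = NULL, alpha = 0.05,
                           density_mode = c("reference", "each", "aggregate"),
                           reference_density = 0.25,
                           mode = "auto",
                           correction = c("none", "BH")) {
  density_mode <- match.arg(density_mode)
  correction <- match.arg(correction)
  metrics <- tibble::as_tibble(metrics)

  complete <- metrics |>
    dplyr::distinct(.data$subject, .data$session) |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n == 2)
  all_subjects <- unique(metrics$subject)
  dropped <- setdiff(all_subjects, complete$subject)
  if (length(dropped) > 0) {
    warn(paste0("Excluding subject(s) without both sessions: ",
                paste(dropped, collapse = ", ")))
    metrics <- dplyr::filter(metrics, !.data$subject %in% dropped)
  }
  subjects <- sort(complete$subject)
  if (length(subjects) < 2) abort("Fewer than 2 complete pre/post pairs.")

  nodal <- switch(density_mode,
    reference = {
      if (!any(abs(metrics$density - reference_density) < 1e-9)) {
        abort("`reference_density` not present in the metric table.")
      }
      dplyr::filter(metrics, abs(.data$density - reference_density) < 1e-9)
    },
    each = metrics,
    aggregate = metrics |>
      dplyr::group_by(.data$subject, .data$session, .data$roi, .data$metric) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(density = NA_real_)
  )

  cell_test <- function(df, roi, metric, density) {
    wide <- df[order(match(df$subject, subjects)), ]
    pre <- wide$value[wide$session == "pre"][match(subjects, wide$subject[wide$session == "pre"])]
    post <- wide$value[wide$session == "post"][match(subjects, wide$subject[wide$session == "post"])]
    ok <- !is.na(pre) & !is.na(post)
    if (sum(ok) < 2) {
      # e.g. small-worldness undefined at very sparse densities
      return(tibble::tibble(
        roi = roi, metric = metric, density = density,
        n_pairs = sum(ok), W = NA_real_, p_value = NA_real_,
        direction = "none",
        median_pre = median(pre[ok]), median_post = median(post[ok])
      ))
    }
    fit <- suppressWarnings(wilcoxon_signed_rank(pre[ok], post[ok], mode = mode))
    tibble::tibble(
      roi = roi, metric = metric, density = density,
      n_pairs = sum(ok), W = fit$statistic, p_value = fit$p_value,
      direction = fit$direction,
      median_pre = fit$median_pre, median_post = fit$median_post
    )
  }

  rows <- nodal |>
    dplyr::group_by(.data$roi, .data$metric, .data$density) |>
    dplyr::group_map(~ cell_test(.x, .y$roi, .y$metric, .y$density)) |>
    dplyr::bind_rows()

  if (!is.null(sweep)) {
    sw <- tibble::as_tibble(sweep) |>
      dplyr::filter(!.data$subject %in% dropped) |>
      dplyr::mutate(roi = "network", metric = "small_worldness",
                    value = .data$s) |>
      dplyr::select("subject", "session", "density", "roi", "metric", "value")
    sw_rows <- sw |>
      dplyr::group_by(.data$roi, .data$metric, .data$density) |>
      dplyr::group_map(~ cell_test(.x, .y$roi, .y$metric, .y$density)) |>
      dplyr::bind_rows()
    rows <- dplyr::bind_rows(rows, sw_rows)
  }

  if (correction == "BH") {
    rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "BH")
    rows$significant <- !is.na(rows$p_adjusted) & rows$p_adjusted < alpha
  } else {
    rows$significant <- !is.na(rows$p_value) & rows$p_value < alpha
  }
  attr(rows, "alpha") <- alpha
  class(rows) <- c("fc_comparison", class(rows))
  rows
}

#' Summarize a cohort comparison
#' @param x An `fc_comparison`.
#' @param ... Unused.
#' @return One-row tibble: number of cells, number significant, alpha.
#' @method glance fc_comparison
#' @export
glance.fc_comparison <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' Pre-normalized medians for a radar-chart summary
#'
#' For each significant cell, expresses the post-treatment median index as a
#' fraction of the pre-treatment median, so all indexes share a common unit
#' contour at 1: values above 1 increased after treatment, below 1
#' decreased.
#'
#' @param rows An `fc_comparison`.
#' @param only_significant Restrict to flagged cells (default `TRUE`, as a
#'   radar summary of candidate markers).
#' @return Tibble `roi`, `metric`, `density`, `normalized_post`.
#' @export
radar_normalize <- function(rows, only_significant = TRUE) {
  rows <- tibble::as_tibble(rows)
  if (only_significant) rows <- dplyr::filter(rows, .data$significant)
  zero <- !is.na(rows$median_pre) & rows$median_pre == 0
  if (any(zero)) {
    warn(paste0("Skipping row(s) with zero pre-treatment median: ",
                paste(paste(rows$roi[zero], rows$metric[zero], sep = "/"),
                      collapse = ", ")))
    rows <- rows[!zero, ]
  }
  tibble::tibble(
    roi = rows$roi, metric = rows$metric, density = rows$density,
    normalized_post = rows$median_post / rows$median_pre
  )
}

#' Radar-style plot of pre-normalized indexes
#'
#' @param radar Output of [radar_normalize()].
#' @return A ggplot: one spoke per (ROI, metric), post/pre ratio as radius,
#'   with the unit contour marked.
#' @export
plot_radar <- function(radar) {
  radar <- tibble::as_tibble(radar)
  radar$spoke <- paste(radar$roi, radar$metric, sep = "\n")
  ggplot2::ggplot(radar,
                  ggplot2::aes(x = .data$spoke, y = .data$normalized_post,
                               group = 1)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_polygon(fill = NA, colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "post / pre (median index)")
}

#' Boxplot of one metric cell before and after treatment
#'
#' @param metrics Long metric table from [cohort_metrics()].
#' @param roi,metric Cell to plot.
#' @param density Density to plot at (default 0.25).
#' @return A ggplot with one box per session.
#' @export
plot_metric_boxplot <- function(metrics, roi, metric, density = 0.25) {
  df <- dplyr::filter(tibble::as_tibble(metrics),
                      .data$roi == !!roi, .data$metric == !!metric,
                      abs(.data$density - !!density) < 1e-9)
  if (nrow(df) == 0) abort("No rows match the requested cell.")
  df$session <- factor(df$session, levels = c("pre", "post"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::labs(title = paste0(metric, " at ", roi),
                  x = NULL, y = metric)
}
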