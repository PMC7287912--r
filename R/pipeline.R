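#' Analysis run configuration
#'
#' Bundles every tunable of the end-to-end analysis: the density sweep (5%
#' to 40% in 5% steps by default), the reference density highlighted in
#' reports (25%), the null-model settings, and the test settings.
#'
#' @param roi_set ROI table; default [default_roi_set()].
#' @param densities Density sweep; default `seq(0.05, 0.40, by = 0.05)`.
#' @param reference_density Reference density; must belong to the sweep.
#' @param null Null-model settings, an [null_config()].
#' @param alpha Significance level for flagging (default 0.05).
#' @param density_mode Nodal comparison mode, see [compare_cohort()].
#' @param wilcoxon_mode `"auto"`, `"exact"` or `"approx"`.
#' @param correction `"none"` or `"BH"`.
#' @param ranking Edge ranking convention, see [threshold_to_density()].
#' @param use_fisher_z Apply the Fisher z-transform before thresholding?
#'   Off by default (thresholding is invariant to it).
#' @param seed Seed for the analysis-stage randomness (null models).
#' @return An `fc_run_config` list.
#' @export
run_config <- function(roi_set = default_roi_set(),
                       densities = seq(0.05, 0.40, by = 0.05),
                       reference_density = 0.25,
                       null = null_config(),
                       alpha = 0.05,
                       density_mode = "reference",
                       wilcoxon_mode = "auto",
                       correction = "none",
                       ranking = "positive",
                       use_fisher_z = FALSE,
                       seed = 1L) {
  if (any(densities <= 0 | densities > 1)) abort("Densities must lie in (0, 1].")
  if (is.unsorted(densities)) abort("`densities` must be increasing.")
  if (!any(abs(densities - reference_density) < 1e-9)) {
    abort("`reference_density` must be one of the sweep densities.")
  }
  structure(
    list(roi_set = validate_roi_set(roi_set), densities = densities,
         reference_density = reference_density, null = null, alpha = alpha,
         density_mode = density_mode, wilcoxon_mode = wilcoxon_mode,
         correction = correction, ranking = ranking,
         use_fisher_z = use_fisher_z, seed = as.integer(seed)),
    class = "fc_run_config"
  )
}

#' Read one subject-session ROI time-series CSV
#'
#' Expects a header row of ROI labels and one row per volume. Columns are
#' matched to the ROI set by label and reordered if necessary (with a
#' message); missing, duplicated or non-numeric columns are errors.
#'
#' @param path CSV file path.
#' @param roi_set ROI table the columns must match.
#' @param subject,session Identifiers attached to the result.
#' @param tr Repetition time in seconds.
#' @return A one-row tibble (subject, session, data, tr) compatible with
#'   `fc_cohort` rows.
#' @export
read_timeseries_csv <- function(path, roi_set = default_roi_set(),
                                subject = NA_character_,
                                session = NA_character_, tr = NA_real_) {
  if (!file.exists(path)) abort(paste0("Time-series file not found: ", path))
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double()))
  )
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("Malformed time-series CSV ", path, ": ",
                 prob$expected[1], " vs ", prob$actual[1],
                 " at line ", prob$row[1] + 1))
  }
  roi_set <- validate_roi_set(roi_set)
  labels <- names(df)
  if (anyDuplicated(labels)) {
    abort(paste0("Duplicate ROI column(s) in ", path, ": ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (!setequal(labels, roi_set$label)) {
    abort(paste0(
      "ROI columns of ", path, " do not match the ROI set.\n",
      "  file:    ", paste(labels, collapse = ", "), "\n",
      "  roi set: ", paste(roi_set$label, collapse = ", ")
    ))
  }
  if (!identical(labels, roi_set$label)) {
    inform(paste0("Reordering columns of ", path, " to match the ROI set."))
    df <- df[, roi_set$label]
  }
  if (anyNA(df)) abort(paste0("Missing values in ", path, "; no imputation is performed."))
  m <- as.matrix(df)
  tibble::tibble(subject = subject, session = session, data = list(m), tr = tr)
}

#' Read a cohort from a manifest JSON
#'
#' The manifest (as written by [write_cohort()]) lists one entry per
#' subject-session with a relative CSV path.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param roi_set ROI table the files must match.
#' @return An `fc_cohort` tibble.
#' @export
read_cohort <- function(manifest_path, roi_set = default_roi_set()) {
  manifest <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  tr <- manifest$config$tr %||% NA_real_
  rows <- purrr::map(manifest$sessions, function(e) {
    path <- file.path(dir, e$path)
    if (!file.exists(path)) {
      abort(paste0("Missing session file for subject ", e$subject,
                   ", session ", e$session, ": ", path))
    }
    read_timeseries_csv(path, roi_set, subject = e$subject,
                        session = e$session, tr = tr)
  })
  out <- dplyr::bind_rows(rows)
  out$session <- factor(out$session, levels = c("pre", "post"))
  attr(out, "roi_set") <- validate_roi_set(roi_set)
  class(out) <- c("fc_cohort", class(out))
  out
}

#' Run the full paired connectivity analysis
#'
#' Executes, for every subject and session: Pearson connectivity, the
#' density-threshold sweep, all nodal graph indexes, degree-matched null
#' models with the small-worldness curve; then the paired pre/post Wilcoxon
#' comparison and the pre-normalized radar summary. Deterministic for a
#' fixed `config$seed`.
#'
#' @param cohort An `fc_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config An [run_config()].
#' @return An `fc_result` list: `connectivity` (tibble subject, session,
#'   matrix list-column), `metrics`, `sweep`, `comparison`, `radar`, and a
#'   `provenance` block (config echo, seed, package version) sufficient to
#'   re-run bit-identically.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 3, n_volumes = 40))
#' res <- run_pipeline(cohort, run_config(null = null_config(20)))
#' glance(res$comparison)
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "fc_run_config"))
  cohort <- validate_cohort(cohort, config$roi_set)

  conn <- cohort
  conn$matrix <- purrr::map(cohort$data, function(d) {
    m <- pearson_matrix(d)
    if (config$use_fisher_z) m <- fisher_z(m)
    m
  })
  conn <- dplyr::select(tibble::as_tibble(conn), "subject", "session", "matrix")

  metrics <- cohort_metrics(cohort, config$densities, ranking = config$ranking)
  null_cfg <- null_config(config$null$rewires_per_edge,
                          config$null$ensemble_size,
                          seed = config$null$seed %||% config$seed)
  sweep <- cohort_sweep(cohort, config$densities, null_cfg,
                        ranking = config$ranking)
  comparison <- compare_cohort(
    metrics, sweep,
    alpha = config$alpha, density_mode = config$density_mode,
    reference_density = config$reference_density,
    mode = config$wilcoxon_mode, correction = config$correction
  )
  radar <- suppressWarnings(radar_normalize(comparison))
  structure(
    list(
      connectivity = conn, metrics = metrics, sweep = sweep,
      comparison = comparison, radar = radar,
      provenance = list(
        seed = config$seed,
        config = config,
        n_subjects = length(unique(cohort$subject)),
        package_version = as.character(utils::packageVersion("fcgraph")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "fc_result"
  )
}

validate_cohort <- function(cohort, roi_set) {
  cohort <- tibble::as_tibble(cohort)
  needed <- c("subject", "session", "data")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("Cohort is missing column(s): ", paste(missing, collapse = ", ")))
  }
  n <- nrow(roi_set)
  for (i in seq_len(nrow(cohort))) {
    d <- cohort$data[[i]]
    if (ncol(d) != n) {
      abort(sprintf("Session %s/%s has %d ROI columns; ROI set has %d.",
                    cohort$subject[i], cohort$session[i], ncol(d), n))
    }
    if (!is.null(colnames(d)) && !setequal(colnames(d), roi_set$label)) {
      abort(sprintf(
        "Session %s/%s columns do not match the ROI set.\n  data:    %s\n  roi set: %s",
        cohort$subject[i], cohort$session[i],
        paste(colnames(d), collapse = ", "),
        paste(roi_set$label, collapse = ", ")
      ))
    }
    if (!is.null(colnames(d)) && !identical(colnames(d), roi_set$label)) {
      cohort$data[[i]] <- d[, roi_set$label]
    }
  }
  cohort
}

#' @export
print.fc_result <- function(x, ...) {
  cat(sprintf(
    "<fc_result> %d subjects; %d metric rows; %d sweep rows; %d comparison rows (%d significant)\n",
    x$provenance$n_subjects, nrow(x$metrics), nrow(x$sweep),
    nrow(x$comparison), sum(x$comparison$significant)
  ))
  invisible(x)
}

#' Write every table of an analysis result to a directory
#'
#' Emits the per-subject connectivity matrices (labeled CSV), the long
#' nodal-metric table, the small-worldness sweep, the comparison rows, the
#' radar rows, a node-annotation table (roi, direction, p for significant
#' cells at the reference density) and a provenance JSON.
#'
#' @param result An `fc_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "fc_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(result$connectivity))) {
    write_connectivity_csv(
      result$connectivity$matrix[[i]],
      file.path(dir, sprintf("connectivity_%s_%s.csv",
                             result$connectivity$subject[i],
                             result$connectivity$session[i]))
    )
  }
  readr::write_csv(result$metrics, file.path(dir, "nodal_metrics.csv"))
  readr::write_csv(result$sweep, file.path(dir, "smallworld_sweep.csv"))
  readr::write_csv(tibble::as_tibble(result$comparison),
                   file.path(dir, "comparison.csv"))
  readr::write_csv(result$radar, file.path(dir, "radar.csv"))
  annot <- result$comparison |>
    dplyr::filter(.data$significant, .data$roi != "network") |>
    dplyr::select("roi", "metric", "direction", "p_value")
  readr::write_csv(annot, file.path(dir, "node_annotation.csv"))
  cfg <- result$provenance$config
  jsonlite::write_json(
    list(
      seed = result$provenance$seed,
      package_version = result$provenance$package_version,
      n_subjects = result$provenance$n_subjects,
      densities = cfg$densities, reference_density = cfg$reference_density,
      rewires_per_edge = cfg$null$rewires_per_edge,
      ensemble_size = cfg$null$ensemble_size,
      alpha = cfg$alpha, density_mode = cfg$density_mode,
      wilcoxon_mode = cfg$wilcoxon_mode, correction = cfg$correction,
      ranking = cfg$ranking, use_fisher_z = cfg$use_fisher_z
    ),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
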