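#' Default inter-ROI correlation structure for the synthetic cohort
#'
#' A stylized resting-state correlation matrix over the 14-region
#' parcellation: homotopic (left/right counterpart) pairs correlate most
#' strongly, within-network pairs moderately (DMN somewhat above the pain
#' network, mirroring the coherence of the default-mode system at rest), and
#' between-network pairs weakly.
#'
#' @param roi_set ROI table as from [default_roi_set()].
#' @param homotopic,within_pain,within_dmn,between Target correlations for
#'   the four pair classes.
#' @return A symmetric positive semi-definite correlation matrix with unit
#'   diagonal and ROI labels as dimnames.
#' @export
default_base_connectivity <- function(roi_set = default_roi_set(),
                                      homotopic = 0.6,
                                      within_pain = 0.35,
                                      within_dmn = 0.45,
                                      between = 0.15) {
  roi_set <- validate_roi_set(roi_set)
  n <- nrow(roi_set)
  labels <- roi_set$label
  m <- matrix(between, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same_net <- roi_set$network[i] == roi_set$network[j]
      if (same_net) {
        m[i, j] <- if (roi_set$network[i] == "pain") within_pain else within_dmn
      }
    }
  }
  # homotopic pairs: same label stem, opposite hemisphere
  stem <- sub("_(L|R)$", "", labels)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && stem[i] == stem[j]) m[i, j] <- homotopic
    }
  }
  diag(m) <- 1
  repair_psd_correlation(m)
}

#' Specify an injectable connectivity effect
#'
#' Describes a treatment-like change applied to the post session of every
#' subject: the correlation between `target_roi` and each ROI in
#' `partner_rois` is shifted by `delta`.
#'
#' @param target_roi ROI label receiving the effect.
#' @param partner_rois Character vector of partner ROI labels, or `"ALL"`
#'   for every other ROI.
#' @param delta Signed correlation increment.
#' @param session Session the effect applies to (only `"post"` supported).
#' @return An `fc_effect` list.
#' @export
effect_spec <- function(target_roi, partner_rois = "ALL", delta, session = "post") {
  stopifnot(is.character(target_roi), length(target_roi) == 1,
            is_scalar_number(delta))
  session <- match.arg(session, "post")
  structure(
    list(target_roi = target_roi, partner_rois = partner_rois,
         delta = delta, session = session),
    class = "fc_effect"
  )
}

#' Apply a connectivity effect to a correlation matrix
#'
#' Adds `effect$delta` to every (target, partner) entry, clips the result to
#' \eqn{[-0.99, 0.99]} (with a warning when clipping occurs), and repairs the
#' matrix to the nearest positive semi-definite correlation matrix if the
#' shift broke positive semi-definiteness.
#'
#' @param cov Symmetric correlation matrix with ROI labels as dimnames.
#' @param effect An [effect_spec()].
#' @return The modified symmetric PSD correlation matrix.
#' @export
apply_effect <- function(cov, effect) {
  stopifnot(inherits(effect, "fc_effect"), is.matrix(cov))
  labels <- rownames(cov)
  if (is.null(labels)) abort("`cov` must carry ROI labels as dimnames.")
  if (!effect$target_roi %in% labels) {
    abort(paste0("Unknown target ROI in effect: ", effect$target_roi))
  }
  partners <- effect$partner_rois
  if (identical(partners, "ALL")) {
    partners <- setdiff(labels, effect$target_roi)
  }
  unknown <- setdiff(partners, labels)
  if (length(unknown) > 0) {
    abort(paste0("Unknown partner ROI(s) in effect: ", paste(unknown, collapse = ", ")))
  }
  partners <- setdiff(partners, effect$target_roi)
  out <- cov
  ti <- match(effect$target_roi, labels)
  pi <- match(partners, labels)
  shifted <- out[ti, pi] + effect$delta
  if (any(abs(shifted) > 0.99)) {
    warn("Effect pushed correlation(s) outside [-0.99, 0.99]; clipped.")
    shifted <- pmin(pmax(shifted, -0.99), 0.99)
  }
  out[ti, pi] <- shifted
  out[pi, ti] <- shifted
  if (min_eigenvalue(out) < -1e-8) {
    out <- repair_psd_correlation(out)
  }
  out
}

#' Configuration for the synthetic paired cohort
#'
#' Defines the study conditions the generator emulates: a paired cohort of
#' `n_subjects` subjects, each scanned pre and post treatment, with
#' `n_volumes` BOLD volumes per session at repetition time `tr` over the
#' ROI set. Signals are zero-mean Gaussian with the target inter-ROI
#' correlation structure, optionally temporally smoothed by a first-order
#' autoregressive filter (re-standardized so the cross-ROI correlation
#' target is preserved). Per-subject heterogeneity is additive Gaussian
#' jitter on the off-diagonal correlations, shared between a subject's two
#' sessions so the paired design is meaningful.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param n_volumes Volumes per session (default 150; a 7 min 30 s scan at
#'   TR 3 s).
#' @param tr Repetition time in seconds (default 3).
#' @param roi_set ROI table; default [default_roi_set()].
#' @param base_connectivity Target correlation matrix;
#'   default [default_base_connectivity()].
#' @param subject_jitter Standard deviation of the per-subject perturbation
#'   of the base correlations (default 0.05).
#' @param ar_coefficient Lag-1 autoregressive coefficient in `[0, 1)`
#'   (default 0.3).
#' @param effects List of [effect_spec()] objects applied to post sessions.
#' @param seed Master seed; all subject/session streams derive from it by
#'   fixed offsets.
#' @return An `fc_cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 8,
                          n_volumes = 150,
                          tr = 3,
                          roi_set = default_roi_set(),
                          base_connectivity = NULL,
                          subject_jitter = 0.05,
                          ar_coefficient = 0.3,
                          effects = list(),
                          seed = 1L) {
  roi_set <- validate_roi_set(roi_set)
  if (is.null(base_connectivity)) {
    base_connectivity <- default_base_connectivity(roi_set)
  }
  n <- nrow(roi_set)
  if (!is.matrix(base_connectivity) || any(dim(base_connectivity) != n)) {
    abort("`base_connectivity` must be a square matrix matching the ROI set.")
  }
  if (is.null(rownames(base_connectivity))) {
    dimnames(base_connectivity) <- list(roi_set$label, roi_set$label)
  }
  if (max(abs(base_connectivity - t(base_connectivity))) > 1e-10) {
    abort("`base_connectivity` must be symmetric.")
  }
  if (any(abs(diag(base_connectivity) - 1) > 1e-10)) {
    abort("`base_connectivity` must have unit diagonal.")
  }
  if (any(abs(base_connectivity) > 1 + 1e-10)) {
    abort("`base_connectivity` entries must lie in [-1, 1].")
  }
  repaired <- repair_psd_correlation(base_connectivity)
  if (sqrt(sum((repaired - base_connectivity)^2)) > 0.25) {
    abort("`base_connectivity` is too far from positive semi-definite to repair.")
  }
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  if (n_volumes < 10) abort("`n_volumes` must be at least 10.")
  if (!is_scalar_number(ar_coefficient) || ar_coefficient < 0 || ar_coefficient >= 1) {
    abort("`ar_coefficient` must lie in [0, 1).")
  }
  if (!is_scalar_number(subject_jitter) || subject_jitter < 0) {
    abort("`subject_jitter` must be a non-negative scalar.")
  }
  if (inherits(effects, "fc_effect")) effects <- list(effects)
  for (ef in effects) {
    if (!inherits(ef, "fc_effect")) abort("`effects` must be a list of effect_spec() objects.")
    if (!ef$target_roi %in% roi_set$label) {
      abort(paste0("Unknown ROI label in effect: ", ef$target_roi))
    }
    if (!identical(ef$partner_rois, "ALL")) {
      unknown <- setdiff(ef$partner_rois, roi_set$label)
      if (length(unknown) > 0) {
        abort(paste0("Unknown ROI label(s) in effect: ", paste(unknown, collapse = ", ")))
      }
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_volumes = as.integer(n_volumes),
         tr = tr, roi_set = roi_set, base_connectivity = repaired,
         subject_jitter = subject_jitter, ar_coefficient = ar_coefficient,
         effects = effects, seed = as.integer(seed)),
    class = "fc_cohort_config"
  )
}

# Draw one session: stationary AR(1) process with innovation covariance
# chosen so the cross-ROI correlation equals `sigma` at every lag-0 pair.
simulate_session <- function(sigma, n_volumes, ar, seed) {
  withr::local_seed(seed)
  n <- ncol(sigma)
  ch <- chol(sigma + diag(1e-10, n))
  z <- matrix(rnorm(n_volumes * n), n_volumes, n) %*% ch
  if (ar > 0) {
    x <- z
    s <- sqrt(1 - ar^2)
    for (t in 2:n_volumes) {
      x[t, ] <- ar * x[t - 1, ] + s * z[t, ]
    }
    z <- x
  }
  colnames(z) <- colnames(sigma)
  z
}

#' Generate a synthetic paired pre/post cohort
#'
#' Draws, for every subject, a subject-specific correlation matrix (base
#' structure plus shared jitter, PSD-repaired), then simulates one pre and
#' one post session of ROI time series from it. Effects listed in the
#' configuration perturb only the post-session correlation matrix. Fully
#' deterministic for a fixed seed, independent of evaluation order: each
#' subject/session consumes its own derived random stream.
#'
#' @param config An [cohort_config()].
#' @return An `fc_cohort` tibble with one row per subject-session and
#'   columns `subject`, `session` (`"pre"`/`"post"`), `data` (list of
#'   volumes-by-ROI matrices) and `tr`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2, n_volumes = 30))
#' dim(cohort$data[[1]])
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "fc_cohort_config"))
  n <- nrow(config$roi_set)
  rows <- vector("list", config$n_subjects * 2L)
  k <- 0L
  for (i in seq_len(config$n_subjects)) {
    sigma_i <- config$base_connectivity
    if (config$subject_jitter > 0) {
      withr::local_seed(derive_seed(config$seed, i, 0))
      noise <- matrix(rnorm(n * n, sd = config$subject_jitter), n, n)
      noise[lower.tri(noise, diag = TRUE)] <- 0
      noise <- noise + t(noise)
      sigma_i <- sigma_i + noise
      sigma_i <- pmin(pmax(sigma_i, -0.99), 0.99)
      diag(sigma_i) <- 1
      sigma_i <- repair_psd_correlation(sigma_i)
    }
    sigma_post <- sigma_i
    for (ef in config$effects) {
      sigma_post <- apply_effect(sigma_post, ef)
    }
    for (sess in c("pre", "post")) {
      sess_idx <- if (sess == "pre") 1L else 2L
      sigma <- if (sess == "pre") sigma_i else sigma_post
      dat <- simulate_session(sigma, config$n_volumes, config$ar_coefficient,
                              derive_seed(config$seed, i, sess_idx))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        subject = sprintf("sub-%02d", i),
        session = sess,
        data = list(dat),
        tr = config$tr
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$session <- factor(out$session, levels = c("pre", "post"))
  attr(out, "roi_set") <- config$roi_set
  attr(out, "config") <- config
  class(out) <- c("fc_cohort", class(out))
  out
}

#' Write a cohort to per-session CSV files plus a JSON manifest
#'
#' Each session becomes `sub-<id>_<pre|post>.csv` (header row of ROI labels,
#' one row per volume). The manifest lists subjects, sessions, file paths,
#' the master seed and an echo of the generator configuration.
#'
#' @param cohort An `fc_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- attr(cohort, "config")
  entries <- purrr::pmap(
    list(cohort$subject, as.character(cohort$session), cohort$data),
    function(subject, session, data) {
      path <- file.path(dir, paste0(subject, "_", session, ".csv"))
      readr::write_csv(tibble::as_tibble(data), path)
      list(subject = subject, session = session, path = basename(path))
    }
  )
  manifest <- list(
    subjects = unique(cohort$subject),
    sessions = entries,
    seed = if (!is.null(config)) config$seed else NA_integer_,
    config = if (!is.null(config)) {
      list(
        n_subjects = config$n_subjects, n_volumes = config$n_volumes,
        tr = config$tr, subject_jitter = config$subject_jitter,
        ar_coefficient = config$ar_coefficient,
        roi_labels = config$roi_set$label
      )
    }
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}
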