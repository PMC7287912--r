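test_that("cohort generation is bit-identical for a fixed seed", {
  cfg <- cohort_config(n_subjects = 2, n_volumes = 30, seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_equal(nrow(a), 4)
  expect_true(all(vapply(a$data, nrow, integer(1)) == 30))
  expect_true(all(vapply(a$data, ncol, integer(1)) == 14))
  c2 <- generate_cohort(cohort_config(n_subjects = 2, n_volumes = 30, seed = 12L))
  expect_false(identical(a$data[[1]], c2$data[[1]]))
})

test_that("generated series reproduce the target correlation at large n", {
  roi <- tibble::tibble(label = c("a", "b"), network = c("pain", "DMN"),
                        hemisphere = c("L", "R"))
  base <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(roi$label, roi$label))
  cfg <- cohort_config(n_subjects = 2, n_volumes = 50000, roi_set = roi,
                       base_connectivity = base, subject_jitter = 0,
                       ar_coefficient = 0, seed = 5L)
  cohort <- generate_cohort(cfg)
  r <- cor(cohort$data[[1]])[1, 2]
  expect_lt(abs(r - 0.5), 0.02)
})

test_that("empirical correlation converges to the target as volumes grow", {
  roi <- default_roi_set()[1:4, ]
  base <- default_base_connectivity(roi)
  frob <- vapply(c(500, 5000, 50000), function(nv) {
    cfg <- cohort_config(n_subjects = 2, n_volumes = nv, roi_set = roi,
                         base_connectivity = base, subject_jitter = 0,
                         ar_coefficient = 0, seed = 3L)
    cohort <- generate_cohort(cfg)
    sqrt(sum((cor(cohort$data[[1]]) - base)^2))
  }, numeric(1))
  expect_true(all(diff(frob) < 0))
})

test_that("autoregressive filtering controls lag-1 autocorrelation", {
  roi <- default_roi_set()[1:3, ]
  base <- default_base_connectivity(roi)
  lag1 <- function(ar) {
    cfg <- cohort_config(n_subjects = 2, n_volumes = 10000, roi_set = roi,
                         base_connectivity = base, subject_jitter = 0,
                         ar_coefficient = ar, seed = 9L)
    x <- generate_cohort(cfg)$data[[1]][, 1]
    cor(x[-1], x[-length(x)])
  }
  expect_lt(abs(lag1(0)), 0.05)
  expect_lt(abs(lag1(0.5) - 0.5), 0.05)
})

test_that("pre and post share the subject covariance when no effect is injected", {
  cfg <- cohort_config(n_subjects = 3, n_volumes = 5000, subject_jitter = 0.05,
                       seed = 21L)
  cohort <- generate_cohort(cfg)
  pre <- cor(cohort$data[[1]])
  post <- cor(cohort$data[[2]])
  # same target matrix, independent draws: entries agree up to sampling noise
  expect_lt(max(abs(pre - post)), 0.15)
  expect_false(identical(cohort$data[[1]], cohort$data[[2]]))
})

test_that("apply_effect changes only the targeted entries", {
  base <- default_base_connectivity()
  expect_equal(apply_effect(base, effect_spec("mPFC", "PCC", delta = 0)), base)

  ef <- effect_spec("mPFC", "PCC", delta = 0.3)
  shifted <- apply_effect(base, ef)
  expect_equal(shifted["mPFC", "PCC"], base["mPFC", "PCC"] + 0.3)
  expect_equal(shifted["PCC", "mPFC"], shifted["mPFC", "PCC"])
  mask <- matrix(TRUE, 14, 14, dimnames = dimnames(base))
  mask["mPFC", "PCC"] <- mask["PCC", "mPFC"] <- FALSE
  expect_equal(shifted[mask], base[mask])
})

test_that("apply_effect clips out-of-range correlations and repairs PSD", {
  roi <- tibble::tibble(label = c("a", "b", "c"), network = "pain",
                        hemisphere = "L")
  base <- diag(3) * 0.5 + 0.5
  dimnames(base) <- list(roi$label, roi$label)
  expect_warning(
    out <- apply_effect(base, effect_spec("a", "b", delta = 0.9)),
    "clipped"
  )
  expect_gte(min_eig <- min(eigen(out, symmetric = TRUE)$values), -1e-8)
  expect_lte(max(abs(out[upper.tri(out)])), 0.99)
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(cohort_config(n_subjects = 1), "at least 2")
  expect_error(cohort_config(n_volumes = 5), "at least 10")
  expect_error(cohort_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(
    cohort_config(effects = list(effect_spec("NotAnRoi", "PCC", delta = 0.1))),
    "NotAnRoi"
  )
  bad <- default_base_connectivity()
  bad[1, 2] <- 0.9
  expect_error(cohort_config(base_connectivity = bad), "symmetric")
  anti <- matrix(-0.9, 4, 4)
  diag(anti) <- 1
  expect_error(
    cohort_config(roi_set = default_roi_set()[1:4, ], base_connectivity = anti),
    "positive semi-definite"
  )
})

test_that("cohort CSV export writes one file per session plus a manifest", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_config(n_subjects = 2, n_volumes = 20, seed = 2L))
  manifest <- write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "sub-01_pre.csv")))
  expect_true(file.exists(file.path(dir, "sub-02_post.csv")))
  parsed <- jsonlite::read_json(manifest)
  expect_length(parsed$sessions, 4)
  expect_equal(parsed$seed, 2L)
})
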