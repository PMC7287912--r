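# Shared fixture: small cohort metric/sweep tables computed once per run.
set.seed(50)
cohort_fix <- generate_cohort(cohort_config(n_subjects = 4, n_volumes = 60,
                                            seed = 50L))
metrics_fix <- cohort_metrics(cohort_fix, densities = c(0.20, 0.25))
sweep_fix <- cohort_sweep(cohort_fix, densities = c(0.20, 0.25),
                          cfg = null_config(30, seed = 50))

test_that("an identity cohort (pre duplicated as post) flags nothing", {
  dup <- metrics_fix
  pre_rows <- dup[dup$session == "pre", ]
  post_rows <- pre_rows
  post_rows$session <- "post"
  ident <- dplyr::bind_rows(pre_rows, post_rows)
  cmp <- suppressWarnings(compare_cohort(ident, alpha = 0.05))
  expect_true(all(cmp$p_value == 1))
  expect_false(any(cmp$significant))
  expect_true(all(cmp$direction == "none"))
})

test_that("comparison output is invariant to subject ordering", {
  shuffled <- metrics_fix[sample(nrow(metrics_fix)), ]
  a <- suppressWarnings(compare_cohort(metrics_fix, sweep_fix))
  b <- suppressWarnings(compare_cohort(shuffled, sweep_fix))
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("comparison covers every ROI-metric cell plus small-worldness rows", {
  cmp <- suppressWarnings(compare_cohort(metrics_fix, sweep_fix))
  nodal <- cmp[cmp$roi != "network", ]
  expect_equal(nrow(nodal), 14 * 6)
  expect_true(all(nodal$density == 0.25))
  sw <- cmp[cmp$roi == "network", ]
  expect_equal(sw$density, c(0.20, 0.25))
  expect_true(all(cmp$W[!is.na(cmp$W)] <=
                    cmp$n_pairs[!is.na(cmp$W)] * (cmp$n_pairs[!is.na(cmp$W)] + 1) / 2))
  expect_true(all(cmp$direction %in% c("increase", "decrease", "none")))
})

test_that("density modes control the nodal comparison granularity", {
  each <- suppressWarnings(compare_cohort(metrics_fix, density_mode = "each"))
  expect_equal(nrow(each), 14 * 6 * 2)
  agg <- suppressWarnings(compare_cohort(metrics_fix, density_mode = "aggregate"))
  expect_equal(nrow(agg), 14 * 6)
  expect_true(all(is.na(agg$density)))
})

test_that("incomplete subjects are dropped with a warning; too few pairs error", {
  incomplete <- metrics_fix[!(metrics_fix$subject == "sub-01" &
                                metrics_fix$session == "post"), ]
  expect_warning(cmp <- compare_cohort(incomplete), "sub-01")
  # at most 3 complete pairs remain (fewer where a nodal value is undefined)
  expect_true(all(cmp$n_pairs <= 3))
  expect_true(any(cmp$n_pairs == 3))
  only_one <- metrics_fix[metrics_fix$subject %in% c("sub-01", "sub-02"), ]
  only_one <- only_one[!(only_one$subject == "sub-02" & only_one$session == "post"), ]
  expect_error(suppressWarnings(compare_cohort(only_one)), "Fewer than 2")
})

test_that("Benjamini-Hochberg correction is monotone and more conservative", {
  cmp <- suppressWarnings(compare_cohort(metrics_fix, sweep_fix,
                                         correction = "BH"))
  expect_true(all(cmp$p_adjusted >= cmp$p_value, na.rm = TRUE))
  expect_equal(cmp$p_adjusted[!is.na(cmp$p_value)],
               stats::p.adjust(cmp$p_value[!is.na(cmp$p_value)], "BH"))
})

test_that("radar normalization divides post medians by pre medians", {
  rows <- tibble::tibble(
    roi = c("A", "B", "C"), metric = c("m1", "m2", "m3"),
    density = 0.25, n_pairs = 8, W = 30, p_value = c(0.01, 0.04, 0.2),
    direction = c("increase", "decrease", "none"),
    median_pre = c(2, 4, 5), median_post = c(3, 3, 5),
    significant = c(TRUE, TRUE, FALSE)
  )
  radar <- radar_normalize(rows)
  expect_equal(radar$normalized_post, c(1.5, 0.75))
  all_rows <- radar_normalize(rows, only_significant = FALSE)
  expect_equal(all_rows$normalized_post, c(1.5, 0.75, 1))

  rows$median_pre[1] <- 0
  expect_warning(skipped <- radar_normalize(rows), "zero pre-treatment")
  expect_equal(nrow(skipped), 1)
})

test_that("an injected connectivity effect is detected in the right direction", {
  partners <- c("BA1_L", "BA1_R", "BA2_L", "BA2_R", "BA3_L", "BA3_R")
  cfg <- cohort_config(
    n_subjects = 8, n_volumes = 150, subject_jitter = 0.05, seed = 77L,
    effects = list(effect_spec("LateralParietal_L", partners, delta = 0.35))
  )
  boosted <- generate_cohort(cfg)
  met <- cohort_metrics(boosted, densities = 0.25)
  cmp <- suppressWarnings(compare_cohort(met))
  cell <- cmp[cmp$roi == "LateralParietal_L" & cmp$metric == "degree", ]
  expect_true(cell$significant)
  expect_equal(cell$direction, "increase")
})

test_that("plot helpers return ggplot objects", {
  cmp <- suppressWarnings(compare_cohort(metrics_fix, sweep_fix))
  radar <- suppressWarnings(radar_normalize(cmp, only_significant = FALSE))
  expect_s3_class(plot_radar(radar), "ggplot")
  expect_s3_class(plot_metric_boxplot(metrics_fix, "mPFC", "degree"), "ggplot")
  expect_s3_class(autoplot(sweep_fix), "ggplot")
  expect_error(plot_metric_boxplot(metrics_fix, "nope", "degree"), "No rows")
})
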