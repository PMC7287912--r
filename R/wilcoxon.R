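#' Paired Wilcoxon signed-rank test
#'
#' Tests the symmetry of within-pair differences `post - pre` about zero.
#' Zero differences are dropped (Wilcoxon's original convention), the
#' remaining absolute differences are ranked with mid-ranks for ties, and
#' the statistic `W` is the sum of ranks of the positive differences.
#'
#' The two-sided p-value is computed exactly — by the full distribution of
#' `W` over all `2^m` sign assignments — whenever `m <= 12` pairs remain and
#' the absolute differences are tie-free; at the small sample sizes of
#' paired imaging studies the normal approximation is unreliable, so the
#' exact path is the default. With ties or larger `m`, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param pre,post Equal-length numeric vectors (length >= 2).
#' @param mode `"auto"` (default: exact when feasible), `"exact"` or
#'   `"approx"`.
#' @param correct Apply a continuity correction of 1/2 in the normal
#'   approximation? Off by default: the approximate path uses the plain
#'   tie-corrected large-sample statistic, so the two paths agree closely
#'   where both are usable. Set `TRUE` to match the more conservative
#'   continuity-corrected convention.
#' @return An `fc_wilcoxon` object: list with `statistic` (W), `p_value`,
#'   `n_pairs` (input pairs), `m` (nonzero differences used), `method`,
#'   `direction` (`"increase"`, `"decrease"` or `"none"` by the median of
#'   `post - pre`), `median_pre`, `median_post`.
#' @examples
#' fit <- wilcoxon_signed_rank(pre = 1:8, post = 1:8 + runif(8))
#' tidy(fit)
#' @export
wilcoxon_signed_rank <- function(pre, post, mode = c("auto", "exact", "approx"),
                                 correct = FALSE) {
  mode <- match.arg(mode)
  if (length(pre) != length(post)) abort("`pre` and `post` must have equal length.")
  if (length(pre) < 2) abort("At least 2 pairs are required.")
  d <- post - pre
  med_d <- median(d)
  direction <- if (med_d > 0) "increase" else if (med_d < 0) "decrease" else "none"
  keep <- d != 0
  m <- sum(keep)
  if (m == 0) {
    warn("All paired differences are zero; p = 1.")
    return(new_fc_wilcoxon(0, 1, length(pre), 0L, "degenerate", "none",
                           median(pre), median(post)))
  }
  dn <- d[keep]
  r <- rank(abs(dn))
  w <- sum(r[dn > 0])
  ties <- anyDuplicated(abs(dn)) > 0
  use_exact <- switch(mode,
    auto = m <= 12 && !ties,
    exact = TRUE,
    approx = FALSE
  )
  if (use_exact && ties) {
    abort("Exact mode requires tie-free absolute differences.")
  }
  if (use_exact) {
    p <- exact_signed_rank_p(w, m)
    method <- "exact"
  } else {
    p <- approx_signed_rank_p(w, r, correct)
    method <- "normal approximation"
  }
  new_fc_wilcoxon(w, p, length(pre), as.integer(m), method, direction,
                  median(pre), median(post))
}

# Exact null distribution of W by enumeration of all 2^m sign assignments,
# organized as an iterated convolution over ranks 1..m (each rank is either
# in the positive set or not); counts[w + 1] = number of assignments with
# statistic w.
exact_signed_rank_p <- function(w, m) {
  max_w <- m * (m + 1) / 2
  counts <- numeric(max_w + 1)
  counts[1] <- 1
  for (rk in seq_len(m)) {
    shifted <- c(numeric(rk), counts[seq_len(max_w + 1 - rk)])
    counts <- counts + shifted
  }
  total <- 2^m
  p_le <- sum(counts[seq_len(w + 1)]) / total
  p_ge <- sum(counts[seq(w + 1, max_w + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction on the rank variance; optional
# continuity correction of 1/2 toward the mean.
approx_signed_rank_p <- function(w, r, correct = FALSE) {
  m <- length(r)
  mu <- m * (m + 1) / 4
  tie_table <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_table^3 - tie_table) / 48
  if (sigma2 <= 0) return(1)
  cc <- if (correct) sign(w - mu) * 0.5 else 0
  z <- (w - mu - cc) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

new_fc_wilcoxon <- function(statistic, p_value, n_pairs, m, method, direction,
                            median_pre, median_post) {
  structure(
    list(statistic = statistic, p_value = p_value, n_pairs = n_pairs, m = m,
         method = method, direction = direction,
         median_pre = median_pre, median_post = median_post),
    class = "fc_wilcoxon"
  )
}

#' @export
print.fc_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (%s): W = %g, p = %.5g, n = %d pairs (%d nonzero), %s\n",
    x$method, x$statistic, x$p_value, x$n_pairs, x$m, x$direction
  ))
  invisible(x)
}

#' Tidy a Wilcoxon signed-rank fit
#' @param x An `fc_wilcoxon` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `n_pairs`, `m`,
#'   `method`, `direction`, `median_pre`, `median_post`.
#' @method tidy fc_wilcoxon
#' @export
tidy.fc_wilcoxon <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value,
    n_pairs = x$n_pairs, m = x$m, method = x$method,
    direction = x$direction,
    median_pre = x$median_pre, median_post = x$median_post
  )
}

#' @rdname tidy.fc_wilcoxon
#' @method glance fc_wilcoxon
#' @export
glance.fc_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n_pairs = x$n_pairs, method = x$method)
}
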