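# Internal numerical helpers shared across modules.

# Nearest-correlation surrogate: clip eigenvalues at `floor`, reconstruct,
# and rescale to unit diagonal. Cheap and adequate at 14 x 14.
repair_psd_correlation <- function(m, floor = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) {
    diag(m) <- 1
    return(m)
  }
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

min_eigenvalue <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# Deterministic sub-seed from a master seed and fixed integer offsets, kept
# inside the 32-bit signed range so set.seed() accepts it on any platform.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  x <- as.double(seed) %% 2147483647
  mult <- c(1000003, 7919, 104729, 611953)
  for (i in seq_along(offs)) {
    x <- (x * 31 + as.double(offs[i]) * mult[((i - 1) %% length(mult)) + 1]) %% 2147483647
  }
  as.integer(x)
}

# Round half up, the convention used for edge-count selection.
round_half_up <- function(x) floor(x + 0.5)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
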