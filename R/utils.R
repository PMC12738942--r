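# Internal helpers shared across modules.

BAND_NAMES <- c("R_RGB", "G_RGB", "B_RGB", "G_MS", "R_MS", "RE_MS", "NIR_MS")
CLASS_LEVELS <- c("NG", "LG", "MG", "SG")

# Derive a per-stage seed from one global seed; keeps every stage
# independently re-runnable. Result always a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offsets <- c(
    samples = 101, raster = 211, rank = 307, aifs = 401,
    split = 503, fit = 601, roi = 701, null = 907
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) %% 1e6) * 1009 + offsets[[stage]]) %% 2147483647L
}

# Stratified fold assignment: within each class, shuffle and deal fold ids
# round-robin so fold sizes differ by at most one per class.
make_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  if (k < 2) stop("k must be >= 2")
  if (min(table(labels)) < k) {
    stop("k_folds exceeds the smallest class count")
  }
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# z-score parameters from a training matrix; constant columns get scale 1 so
# they standardize to 0 rather than NaN.
std_params <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_std <- function(x, p) {
  sweep(sweep(x, 2, p$center, "-"), 2, p$scale, "/")
}

# Elementwise division with NA (undefined-marker) where the denominator is 0.
div0 <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
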