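# Shared fixtures, all generated in code.

band_names <- c("R_RGB", "G_RGB", "B_RGB", "G_MS", "R_MS", "RE_MS", "NIR_MS")

# A fixed single sample with easy-to-hand-check band values.
fixed_sample <- function() {
  data.frame(R_RGB = 120, G_RGB = 150, B_RGB = 90,
             G_MS = 0.12, R_MS = 0.10, RE_MS = 0.20, NIR_MS = 0.40)
}

# Down-scaled default scenario for fast tests.
small_scenario <- function(n_per_class = 40L, seed = 1L, ...) {
  synthetic_scenario(profiles = default_profiles(n_per_class), seed = seed,
                     ...)
}

# Feature matrix of the raw bands (no indices), labels attached.
band_fm <- function(df, cols = band_names) {
  feature_matrix(as.matrix(df[cols]), labels = df$label)
}

# AIFS audit fixture: 3 informative bands + 5 pure-noise + 2 near-duplicate
# columns on the full balanced design.
aifs_fixture <- function(seed = 1L, n_per_class = 180L) {
  sc <- synthetic_scenario(
    profiles = default_profiles(n_per_class),
    n_noise_features = 5L, n_duplicate_features = 2L,
    duplicate_sources = c("NIR_MS", "R_RGB"), seed = seed
  )
  df <- generate_samples(sc)
  cols <- c("R_RGB", "R_MS", "NIR_MS", paste0("noise", 1:5),
            "dup1_NIR_MS", "dup2_R_RGB")
  band_fm(df, cols)
}

# Random uniform band table for property-style loops.
random_bands <- function(n, seed) {
  set.seed(seed)
  data.frame(
    R_RGB = runif(n, 1, 255), G_RGB = runif(n, 1, 255),
    B_RGB = runif(n, 1, 255),
    G_MS = runif(n, 0.01, 0.99), R_MS = runif(n, 0.01, 0.99),
    RE_MS = runif(n, 0.01, 0.99), NIR_MS = runif(n, 0.01, 0.99)
  )
}

# Tiny linearly separable 2-class feature matrix.
separable_fm <- function(n_per_class = 20L, seed = 3L) {
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per_class, -3, 0.3), rnorm(n_per_class, -3, 0.3)),
    cbind(rnorm(n_per_class, 3, 0.3), rnorm(n_per_class, 3, 0.3))
  )
  colnames(x) <- c("f1", "f2")
  feature_matrix(x, labels = factor(rep(c("A", "B"), each = n_per_class)))
}
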