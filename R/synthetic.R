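#' Class-conditional spectral profile
#'
#' Describes one grazing-intensity class as independent truncated Gaussians
#' per band: three visible digital-number channels (0-255 scale) and four
#' multispectral reflectance channels (0-1 scale). An optional per-class
#' covariance matrix can replace the independence assumption.
#'
#' @param class_label One of `"NG"`, `"LG"`, `"MG"`, `"SG"`.
#' @param band_means Named numeric vector of length 7 over
#'   `c("R_RGB","G_RGB","B_RGB","G_MS","R_MS","RE_MS","NIR_MS")`. DN means
#'   must lie in (0, 255), reflectance means in (0, 1).
#' @param band_sds Named non-negative numeric vector, same names (zero gives
#'   a degenerate noiseless band, useful for testing).
#' @param n_samples Positive integer, samples drawn for this class.
#' @param cov_matrix Optional 7x7 covariance matrix; when supplied it
#'   overrides `band_sds` and draws are multivariate normal (then truncated
#'   to physical range).
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(class_label, band_means, band_sds, n_samples = 180L,
                          cov_matrix = NULL) {
  if (!class_label %in% CLASS_LEVELS) {
    stop("class_label must be one of ", paste(CLASS_LEVELS, collapse = ", "))
  }
  band_means <- band_means[BAND_NAMES]
  band_sds <- band_sds[BAND_NAMES]
  if (anyNA(band_means) || anyNA(band_sds)) {
    stop("band_means and band_sds must be named over all 7 bands")
  }
  if (any(band_sds < 0)) stop("band_sds must all be >= 0")
  dn <- band_means[1:3]
  refl <- band_means[4:7]
  if (any(dn <= 0 | dn >= 255)) stop("DN means must lie in (0, 255)")
  if (any(refl <= 0 | refl >= 1)) stop("reflectance means must lie in (0, 1)")
  if (n_samples < 1) stop("n_samples must be positive")
  structure(
    list(
      class_label = class_label, band_means = band_means,
      band_sds = band_sds, n_samples = as.integer(n_samples),
      cov_matrix = cov_matrix
    ),
    class = "class_profile"
  )
}

#' Default grazing-trial spectral profiles
#'
#' The shipped preset encodes the qualitative band responses of a sandy
#' grassland grazing gradient: visible digital numbers rise with grazing
#' (soil exposure brightens the scene) but dip again under severe grazing
#' (trampling crusts, litter); multispectral green and red reflectance rise
#' monotonically; red-edge and near-infrared reflectance fall with canopy
#' loss but rebound under severe grazing (high-albedo soil). Overlap is
#' placed so the visible channels confuse light vs severe grazing while the
#' multispectral channels resolve that pair — the two sources carry
#' complementary information.
#'
#' @param n_per_class Samples per class (default 180, a balanced 720-sample
#'   four-class design).
#' @return Named list of four [class_profile()] objects.
#' @export
default_profiles <- function(n_per_class = 180L) {
  means <- list(
    NG = c(R_RGB = 90, G_RGB = 105, B_RGB = 70,
           G_MS = 0.08, R_MS = 0.06, RE_MS = 0.24, NIR_MS = 0.42),
    LG = c(R_RGB = 120, G_RGB = 128, B_RGB = 95,
           G_MS = 0.10, R_MS = 0.09, RE_MS = 0.21, NIR_MS = 0.36),
    MG = c(R_RGB = 150, G_RGB = 152, B_RGB = 125,
           G_MS = 0.13, R_MS = 0.13, RE_MS = 0.17, NIR_MS = 0.30),
    SG = c(R_RGB = 110, G_RGB = 118, B_RGB = 85,
           G_MS = 0.15, R_MS = 0.16, RE_MS = 0.20, NIR_MS = 0.34)
  )
  sds <- c(R_RGB = 12, G_RGB = 12, B_RGB = 10,
           G_MS = 0.015, R_MS = 0.015, RE_MS = 0.02, NIR_MS = 0.025)
  lapply(stats::setNames(CLASS_LEVELS, CLASS_LEVELS), function(cl) {
    class_profile(cl, means[[cl]], sds, n_per_class)
  })
}

#' Synthetic study scenario
#'
#' Bundles four class profiles with optional nuisance columns: pure-noise
#' features (standard normal, label-independent) and near-duplicate features
#' (a configured band plus small noise, correlating with its source at
#' |rho| > 0.9).
#'
#' @param profiles Named list of four [class_profile()]s (default
#'   [default_profiles()]).
#' @param n_noise_features Number of pure-noise columns appended.
#' @param n_duplicate_features Number of near-copy columns appended; sources
#'   cycle through `duplicate_sources`.
#' @param duplicate_sources Band names the duplicates copy (recycled).
#' @param seed Integer seed controlling all draws (samples stream first,
#'   then rasters).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(profiles = default_profiles(),
                               n_noise_features = 0L,
                               n_duplicate_features = 0L,
                               duplicate_sources = c("NIR_MS", "R_RGB"),
                               seed = 1L) {
  if (length(profiles) != 4L ||
      !setequal(vapply(profiles, `[[`, "", "class_label"), CLASS_LEVELS)) {
    stop("profiles must cover exactly the four classes NG, LG, MG, SG")
  }
  if (n_noise_features < 0 || n_duplicate_features < 0) {
    stop("noise/duplicate counts must be >= 0")
  }
  names(profiles) <- vapply(profiles, `[[`, "", "class_label")
  structure(
    list(
      profiles = profiles[CLASS_LEVELS],
      n_noise_features = as.integer(n_noise_features),
      n_duplicate_features = as.integer(n_duplicate_features),
      duplicate_sources = duplicate_sources,
      seed = as.integer(seed)
    ),
    class = "synthetic_scenario"
  )
}

# Draw n truncated-normal values on [lo, hi] by redrawing out-of-range values.
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

draw_class_bands <- function(profile, n) {
  out <- matrix(NA_real_, n, 7, dimnames = list(NULL, BAND_NAMES))
  if (!is.null(profile$cov_matrix)) {
    ch <- chol(profile$cov_matrix)
    z <- matrix(stats::rnorm(n * 7), n, 7) %*% ch
    out[] <- sweep(z, 2, profile$band_means, "+")
    for (j in 1:3) out[, j] <- pmin(pmax(out[, j], 0), 255)
    for (j in 4:7) out[, j] <- pmin(pmax(out[, j], 0), 1)
    return(out)
  }
  for (j in seq_along(BAND_NAMES)) {
    lo <- 0
    hi <- if (j <= 3) 255 else 1
    sdj <- profile$band_sds[[j]]
    if (sdj == 0) {
      out[, j] <- rep(profile$band_means[[j]], n)
    } else {
      out[, j] <- rtnorm(n, profile$band_means[[j]], sdj, lo, hi)
    }
  }
  out
}

#' Generate a labeled synthetic band table
#'
#' Draws independent per-class Gaussian band values truncated to each band's
#' physical range, then appends any configured noise and duplicate columns.
#' The same scenario (including seed) always yields an identical table.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A data.frame with the 7 band columns, any `noise*` / `dup*`
#'   columns, and a `label` factor with levels NG < LG < MG < SG.
#' @export
generate_samples <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(derive_seed(scenario$seed, "samples"))
  blocks <- lapply(scenario$profiles, function(p) {
    cbind(
      as.data.frame(draw_class_bands(p, p$n_samples)),
      label = rep(p$class_label, p$n_samples)
    )
  })
  df <- do.call(rbind, blocks)
  rownames(df) <- NULL
  df$label <- factor(df$label, levels = CLASS_LEVELS)
  n <- nrow(df)
  if (scenario$n_noise_features > 0) {
    for (i in seq_len(scenario$n_noise_features)) {
      df[[paste0("noise", i)]] <- stats::rnorm(n)
    }
  }
  if (scenario$n_duplicate_features > 0) {
    src <- rep_len(scenario$duplicate_sources, scenario$n_duplicate_features)
    for (i in seq_len(scenario$n_duplicate_features)) {
      base <- df[[src[i]]]
      df[[paste0("dup", i, "_", src[i])]] <-
        base + stats::rnorm(n, 0, 0.2 * stats::sd(base))
    }
  }
  # keep label as the last column
  df <- df[c(setdiff(names(df), "label"), "label")]
  df
}

#' Generate a co-registered synthetic raster scene
#'
#' Lays the four classes out as quadrants of a square grid (NG top-left, LG
#' top-right, MG bottom-left, SG bottom-right), draws every pixel from its
#' quadrant's class profile, and returns the band stack together with the
#' ground-truth label raster. Raster draws come after the sample stream in
#' the scenario's seed ordering, so tables and rasters generated from one
#' scenario are independent but jointly reproducible.
#'
#' @param scenario A [synthetic_scenario()] (noise/duplicate columns are not
#'   rasterized; only the 7 bands).
#' @param pixels_per_side Edge length of the square grid (>= 8, even so the
#'   quadrants tile exactly).
#' @return List with `stack` (array `pixels_per_side` x `pixels_per_side` x 7,
#'   band names on the third dimension) and `labels` (a [label_raster()] of
#'   true classes).
#' @export
generate_raster <- function(scenario, pixels_per_side = 64L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  p <- as.integer(pixels_per_side)
  if (p < 8) stop("pixels_per_side must be >= 8")
  if (p %% 2 != 0) stop("pixels_per_side must be even (quadrant layout)")
  set.seed(derive_seed(scenario$seed, "raster"))
  half <- p %/% 2
  stack <- array(NA_real_, c(p, p, 7), dimnames = list(NULL, NULL, BAND_NAMES))
  grid <- matrix(NA_integer_, p, p)
  legend <- stats::setNames(0:3, CLASS_LEVELS)
  quads <- list(
    NG = list(rows = 1:half, cols = 1:half),
    LG = list(rows = 1:half, cols = (half + 1):p),
    MG = list(rows = (half + 1):p, cols = 1:half),
    SG = list(rows = (half + 1):p, cols = (half + 1):p)
  )
  for (cl in CLASS_LEVELS) {
    q <- quads[[cl]]
    npix <- length(q$rows) * length(q$cols)
    vals <- draw_class_bands(scenario$profiles[[cl]], npix)
    for (b in seq_len(7)) {
      stack[q$rows, q$cols, b] <- matrix(vals[, b], length(q$rows))
    }
    grid[q$rows, q$cols] <- legend[[cl]]
  }
  list(stack = stack, labels = label_raster(grid, legend = legend))
}

#' Quadrant regions of interest matching [generate_raster()]
#'
#' @param pixels_per_side Grid edge length used for the raster.
#' @return List of labeled polygons (each `list(label=, xy=)` with vertices
#'   in pixel-center coordinates, x = column - 0.5, y = row - 0.5) suitable
#'   for [extract_roi_samples()].
#' @export
quadrant_rois <- function(pixels_per_side) {
  p <- as.integer(pixels_per_side)
  h <- p / 2
  rect <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  list(
    list(label = "NG", xy = rect(0, 0, h, h)),
    list(label = "LG", xy = rect(h, 0, p, h)),
    list(label = "MG", xy = rect(0, h, h, p)),
    list(label = "SG", xy = rect(h, h, p, p))
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  n <- sum(vapply(x$profiles, `[[`, 1L, "n_samples"))
  cat("Synthetic grazing scenario\n")
  cat("  classes:", paste(names(x$profiles), collapse = " "),
      sprintf("(%d samples total)\n", n))
  cat("  extra features:", x$n_noise_features, "noise,",
      x$n_duplicate_features, "duplicates\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
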