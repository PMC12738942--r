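#' Chromatic-coordinate normalization of visible bands
#'
#' Divides each visible digital-number channel by the channel sum, removing
#' overall brightness so visible and reflectance features contribute on
#' comparable scales when fused. A zero channel sum marks the sample invalid:
#' all three coordinates become `NA` (never a silent zero).
#'
#' @param R_RGB,G_RGB,B_RGB Numeric vectors of visible digital numbers (>= 0).
#' @return data.frame with columns `r_norm`, `g_norm`, `b_norm`; valid rows
#'   sum to 1.
#' @export
normalize_rgb <- function(R_RGB, G_RGB, B_RGB) {
  s <- R_RGB + G_RGB + B_RGB
  bad <- !is.finite(s) | s <= 0
  s[bad] <- NA_real_
  data.frame(r_norm = R_RGB / s, g_norm = G_RGB / s, b_norm = B_RGB / s)
}

# The index registry. Each entry evaluates on a band environment `bd` holding
# vis R/G/B (chromatic coordinates by default, raw DN if rgb_mode = "raw"),
# the chromatic coordinates r/g/b themselves (mode-independent), the four
# reflectance bands, and options (SAVI soil factor L, idx14 RGB scaling).
# Order defines FeatureMatrix column order: visible, multispectral, then the
# purpose-built fusion indices.
nd <- function(a, b) div0(a - b, a + b)

index_defs <- function() {
  list(
    list(name = "ExG", family = "visible", source = "rgb",
         fun = function(bd) 2 * bd$G - bd$R - bd$B),
    list(name = "VARI", family = "visible", source = "rgb",
         fun = function(bd) div0(bd$G - bd$R, bd$G + bd$R - bd$B)),
    list(name = "ExGR", family = "visible", source = "rgb",
         fun = function(bd) (2 * bd$G - bd$R - bd$B) - (1.4 * bd$R - bd$G)),
    list(name = "RGBVI", family = "visible", source = "rgb",
         fun = function(bd) nd(bd$G^2, bd$R * bd$B)),
    list(name = "NDVI", family = "multispectral", source = "ms",
         fun = function(bd) nd(bd$NIR_MS, bd$R_MS)),
    list(name = "GNDVI", family = "multispectral", source = "ms",
         fun = function(bd) nd(bd$NIR_MS, bd$G_MS)),
    list(name = "SAVI", family = "multispectral", source = "ms",
         fun = function(bd) {
           L <- bd$savi_L
           div0((1 + L) * (bd$NIR_MS - bd$R_MS), bd$NIR_MS + bd$R_MS + L)
         }),
    list(name = "MSAVI", family = "multispectral", source = "ms",
         fun = function(bd) {
           sq <- (2 * bd$NIR_MS + 1)^2 - 8 * (bd$NIR_MS - bd$R_MS)
           sq[sq < 0] <- NA_real_
           (2 * bd$NIR_MS + 1 - sqrt(sq)) / 2
         }),
    list(name = "NDRE", family = "multispectral", source = "ms",
         fun = function(bd) nd(bd$NIR_MS, bd$RE_MS)),
    list(name = "EVI2", family = "multispectral", source = "ms",
         fun = function(bd) {
           div0(2.5 * (bd$NIR_MS - bd$R_MS), bd$NIR_MS + 2.4 * bd$R_MS + 1)
         }),
    list(name = "idx1", family = "self", source = "rgb",
         fun = function(bd) div0(bd$G, bd$B)),
    list(name = "idx2", family = "self", source = "rgb",
         fun = function(bd) div0(bd$G, bd$R)),
    list(name = "idx3", family = "self", source = "ms",
         fun = function(bd) div0(bd$NIR_MS, bd$RE_MS)),
    list(name = "idx4", family = "self", source = "ms",
         fun = function(bd) div0(bd$NIR_MS, bd$R_MS)),
    list(name = "idx5", family = "self", source = "ms",
         fun = function(bd) nd(bd$NIR_MS, bd$G_MS)),
    list(name = "idx6", family = "self", source = "ms",
         fun = function(bd) div0(bd$RE_MS - bd$R_MS, bd$RE_MS + bd$R_MS)),
    list(name = "idx7", family = "self", source = "mixed",
         fun = function(bd) nd(bd$b, bd$RE_MS)),
    list(name = "idx8", family = "self", source = "mixed",
         fun = function(bd) div0(bd$g * bd$NIR_MS, bd$R_MS * bd$RE_MS)),
    list(name = "idx9", family = "self", source = "mixed",
         fun = function(bd) div0(bd$b * bd$NIR_MS, bd$r * bd$g)),
    list(name = "idx10", family = "self", source = "ms",
         fun = function(bd) div0(bd$R_MS * bd$RE_MS, bd$G_MS * bd$NIR_MS)),
    list(name = "idx11", family = "self", source = "rgb",
         fun = function(bd) bd$r),
    list(name = "idx12", family = "self", source = "rgb",
         fun = function(bd) bd$g),
    list(name = "idx13", family = "self", source = "rgb",
         fun = function(bd) bd$b),
    list(name = "idx14", family = "self", source = "mixed",
         fun = function(bd) {
           m <- if (identical(bd$idx14_mode, "scaled")) {
             (bd$R_dn + bd$G_dn + bd$B_dn) / (3 * 255)
           } else {
             (bd$r + bd$g + bd$b) / 3
           }
           nd(bd$NIR_MS, m)
         })
  )
}

#' Spectral-index registry
#'
#' Lists the 24 registered indices: 4 conventional visible-light indices,
#' 6 conventional multispectral indices, and 14 purpose-built fusion indices.
#' `source` records which sensor's bands an index needs (`rgb`, `ms`, or
#' `mixed`), which drives the `visible` / `multi` set selections.
#'
#' @return data.frame with columns `name`, `family`, `source`.
#' @export
index_registry <- function() {
  defs <- index_defs()
  data.frame(
    name = vapply(defs, `[[`, "", "name"),
    family = vapply(defs, `[[`, "", "family"),
    source = vapply(defs, `[[`, "", "source"),
    stringsAsFactors = FALSE
  )
}

# Resolve an index-set keyword (or explicit name vector) to registry names.
resolve_index_set <- function(set) {
  reg <- index_registry()
  if (length(set) == 1 && set %in% c("all", "visible", "multi", "new",
                                     "rgb_multi")) {
    return(switch(set,
      all = reg$name,
      visible = reg$name[reg$source == "rgb"],
      multi = reg$name[reg$source == "ms"],
      new = reg$name[reg$family == "self"],
      rgb_multi = reg$name[reg$family %in% c("visible", "multispectral")]
    ))
  }
  unknown <- setdiff(set, reg$name)
  if (length(unknown) > 0) {
    stop("unknown index name(s): ", paste(unknown, collapse = ", "))
  }
  reg$name[reg$name %in% set] # registry order
}

band_env <- function(samples, rgb_mode, savi_L, idx14_mode) {
  cc <- normalize_rgb(samples$R_RGB, samples$G_RGB, samples$B_RGB)
  vis <- if (rgb_mode == "raw") {
    list(R = samples$R_RGB, G = samples$G_RGB, B = samples$B_RGB)
  } else {
    list(R = cc$r_norm, G = cc$g_norm, B = cc$b_norm)
  }
  list(
    R = vis$R, G = vis$G, B = vis$B,
    r = cc$r_norm, g = cc$g_norm, b = cc$b_norm,
    R_dn = samples$R_RGB, G_dn = samples$G_RGB, B_dn = samples$B_RGB,
    G_MS = samples$G_MS, R_MS = samples$R_MS,
    RE_MS = samples$RE_MS, NIR_MS = samples$NIR_MS,
    savi_L = savi_L, idx14_mode = idx14_mode
  )
}

#' Compute one spectral index
#'
#' @param name Registered index name (see [index_registry()]).
#' @param samples data.frame (or one-row list) with the 7 band columns.
#' @param rgb_mode `"chromatic"` (default) evaluates visible-light indices on
#'   chromatic coordinates; `"raw"` uses digital numbers directly.
#' @param savi_L Soil-adjustment factor for SAVI (default 0.5).
#' @param idx14_mode `"literal"` (default): the visible term of idx14 is the
#'   mean of the chromatic coordinates (constant 1/3 for valid pixels);
#'   `"scaled"`: mean of DN/255, which varies with brightness.
#' @return Numeric vector of index values; `NA` marks undefined results
#'   (zero denominators, invalid RGB sums).
#' @export
compute_index <- function(name, samples, rgb_mode = c("chromatic", "raw"),
                          savi_L = 0.5, idx14_mode = c("literal", "scaled")) {
  rgb_mode <- match.arg(rgb_mode)
  idx14_mode <- match.arg(idx14_mode)
  samples <- as.data.frame(samples)
  missing_bands <- setdiff(BAND_NAMES, names(samples))
  if (length(missing_bands) > 0) {
    stop("missing band column(s): ", paste(missing_bands, collapse = ", "))
  }
  defs <- index_defs()
  hit <- which(vapply(defs, `[[`, "", "name") == name)
  if (length(hit) == 0) stop("unknown index name: ", name)
  bd <- band_env(samples, rgb_mode, savi_L, idx14_mode)
  as.numeric(defs[[hit]]$fun(bd))
}

#' Build the fused feature matrix
#'
#' Evaluates a selection of registered indices on a band table, producing the
#' n x m matrix downstream modules consume. Columns follow registry order
#' (visible, multispectral, purpose-built); rows align with the input; the
#' label column, when present, is carried through. Extra non-band columns of
#' the input (e.g. the synthetic generator's noise/duplicate features) can be
#' appended unchanged with `keep_extra = TRUE`.
#'
#' @param samples Band table: data.frame with the 7 band columns, optional
#'   `label`, optional extra numeric columns.
#' @param indices Index-set keyword (`"all"`, `"visible"`, `"multi"`,
#'   `"new"`, `"rgb_multi"`) or explicit vector of registered names.
#' @param keep_extra Append non-band, non-label numeric columns as features.
#' @inheritParams compute_index
#' @return A `feature_matrix`: list with `values` (numeric matrix), `labels`
#'   (factor or NULL), `families` (named character).
#' @export
build_feature_matrix <- function(samples, indices = "all",
                                 rgb_mode = c("chromatic", "raw"),
                                 savi_L = 0.5,
                                 idx14_mode = c("literal", "scaled"),
                                 keep_extra = FALSE) {
  rgb_mode <- match.arg(rgb_mode)
  idx14_mode <- match.arg(idx14_mode)
  samples <- as.data.frame(samples)
  if (nrow(samples) < 1) stop("need at least one sample")
  sel <- resolve_index_set(indices)
  if (length(sel) == 0) stop("empty index selection")
  defs <- index_defs()
  names(defs) <- vapply(defs, `[[`, "", "name")
  bd <- band_env(samples, rgb_mode, savi_L, idx14_mode)
  values <- vapply(sel, function(nm) as.numeric(defs[[nm]]$fun(bd)),
                   numeric(nrow(samples)))
  values <- matrix(values, nrow = nrow(samples),
                   dimnames = list(NULL, sel))
  families <- stats::setNames(
    vapply(defs[sel], `[[`, "", "family"), sel
  )
  if (keep_extra) {
    extra <- setdiff(names(samples), c(BAND_NAMES, "label"))
    extra <- extra[vapply(samples[extra], is.numeric, TRUE)]
    if (length(extra) > 0) {
      values <- cbind(values, as.matrix(samples[extra]))
      families <- c(families, stats::setNames(rep("extra", length(extra)),
                                              extra))
    }
  }
  labels <- if ("label" %in% names(samples)) {
    factor(samples$label,
           levels = if (all(samples$label %in% CLASS_LEVELS))
             CLASS_LEVELS else sort(unique(as.character(samples$label))))
  }
  if (all(!is.finite(values))) stop("all samples invalid for all indices")
  feature_matrix(values, labels, families)
}

#' Construct a feature matrix object
#'
#' @param values Numeric matrix (n x m) with unique column names; `NA`
#'   marks undefined entries.
#' @param labels Optional factor of length n.
#' @param families Optional named character giving each feature's family.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = NULL, families = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique column names")
  }
  if (!is.null(labels) && length(labels) != nrow(values)) {
    stop("labels length must equal nrow(values)")
  }
  structure(
    list(values = values, labels = labels,
         families = families %||%
           stats::setNames(rep("unknown", ncol(values)), colnames(values))),
    class = "feature_matrix"
  )
}

#' Subset the features of a feature matrix
#' @param fm A `feature_matrix`.
#' @param features Character vector of column names to keep (order kept as
#'   given).
#' @export
select_features <- function(fm, features) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing <- setdiff(features, colnames(fm$values))
  if (length(missing) > 0) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  feature_matrix(fm$values[, features, drop = FALSE], fm$labels,
                 fm$families[features])
}

#' Subset the rows of a feature matrix
#' @param fm A `feature_matrix`.
#' @param rows Integer/logical row index.
#' @export
subset_rows <- function(fm, rows) {
  stopifnot(inherits(fm, "feature_matrix"))
  feature_matrix(fm$values[rows, , drop = FALSE],
                 if (!is.null(fm$labels)) fm$labels[rows], fm$families)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  df <- as.data.frame(x$values)
  if (!is.null(x$labels)) df$label <- x$labels
  df
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  fam <- table(x$families)
  cat("  families:", paste(sprintf("%s=%d", names(fam), fam),
                           collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb),
                           collapse = ", "), "\n")
  }
  nas <- sum(is.na(x$values))
  if (nas > 0) cat("  undefined entries:", nas, "\n")
  invisible(x)
}

#' Write a feature matrix as CSV
#' @param fm A `feature_matrix`.
#' @param path Output file.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}
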