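#' Categorical label raster
#'
#' A 2-D grid of integer class codes with a legend and a nodata code.
#'
#' @param grid Integer matrix of class codes (nodata cells allowed).
#' @param legend Named integer vector mapping class names to codes.
#' @param nodata Integer nodata code (default 255, 8-bit export convention).
#' @return Object of class `label_raster`.
#' @export
label_raster <- function(grid, legend, nodata = 255L) {
  grid <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  legend <- stats::setNames(as.integer(legend), names(legend))
  if (nodata %in% legend) stop("nodata code collides with the legend")
  vals <- unique(grid[!is.na(grid)])
  bad <- setdiff(vals, c(legend, nodata))
  if (length(bad) > 0) {
    stop("grid contains codes outside the legend: ",
         paste(bad, collapse = ", "))
  }
  structure(list(grid = grid, legend = legend, nodata = as.integer(nodata)),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("Label raster %d x %d\n", nrow(x$grid), ncol(x$grid)))
  for (cl in names(x$legend)) {
    cat(sprintf("  %s (code %d): %d px\n", cl, x$legend[[cl]],
                sum(x$grid == x$legend[[cl]], na.rm = TRUE)))
  }
  nd <- sum(x$grid == x$nodata, na.rm = TRUE)
  if (nd > 0) cat("  nodata:", nd, "px\n")
  invisible(x)
}

# Even-odd (ray casting) point-in-polygon test; vertices as a 2-column
# matrix. Points exactly on a horizontal boundary follow the half-open
# convention of the crossing test.
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Flatten a band stack (h x w x 7) into a band table in column-major pixel
# order, the order classify_raster and stack_from_table share.
stack_to_table <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  bands <- dimnames(stack)[[3]]
  out <- as.data.frame(lapply(stats::setNames(bands, bands),
                              function(b) as.vector(stack[, , b])))
  out
}

#' Assemble a band stack from a band table
#'
#' Inverse of the flattening used by [classify_raster()]: fills an
#' `nrow x ncol` grid in column-major pixel order from the table rows, one
#' layer per band.
#'
#' @param samples Band table with the 7 band columns.
#' @param nrow,ncol Grid shape; `nrow * ncol` must equal the table rows.
#' @return 3-D array (`nrow x ncol x 7`).
#' @export
stack_from_table <- function(samples, nrow, ncol) {
  samples <- as.data.frame(samples)
  if (nrow * ncol != base::nrow(samples)) {
    stop("grid shape does not match number of rows")
  }
  stack <- array(NA_real_, c(nrow, ncol, length(BAND_NAMES)),
                 dimnames = list(NULL, NULL, BAND_NAMES))
  for (b in BAND_NAMES) stack[, , b] <- matrix(samples[[b]], nrow, ncol)
  stack
}

#' Extract labeled samples from a raster under ROI polygons
#'
#' Selects the pixels whose centers fall inside each labeled region of
#' interest (pixel-center convention: the center of cell `[row, col]` is at
#' `x = col - 0.5`, `y = row - 0.5`, 0-based grid coordinates). With the
#' stratified-random strategy, `n_per_class` pixels are drawn per class with
#' a fixed seed; classes sharing several polygons pool their pixels first.
#'
#' @param stack Band stack array (h x w x 7).
#' @param rois List of polygons, each `list(label =, xy =)` with `xy` a
#'   2-column vertex matrix (see [quadrant_rois()]).
#' @param strategy `"per_pixel"` (every covered pixel) or
#'   `"stratified_random"`.
#' @param n_per_class Pixels drawn per class under stratified sampling.
#' @param seed Integer seed for the stratified draw.
#' @return Band table data.frame with a `label` column (and `row`/`col`
#'   pixel coordinates).
#' @export
extract_roi_samples <- function(stack, rois,
                                strategy = c("per_pixel",
                                             "stratified_random"),
                                n_per_class = 180L, seed = 1L) {
  strategy <- match.arg(strategy)
  h <- dim(stack)[1]
  w <- dim(stack)[2]
  centers <- expand.grid(row = seq_len(h), col = seq_len(w))
  cx <- centers$col - 0.5
  cy <- centers$row - 0.5
  tab <- stack_to_table(stack) # column-major == expand.grid order
  picked <- list()
  labels_seen <- unique(vapply(rois, `[[`, "", "label"))
  for (lab in labels_seen) {
    inside <- rep(FALSE, nrow(centers))
    for (roi in rois) {
      if (roi$label != lab) next
      xy <- roi$xy
      if (all(xy[, 1] < 0) || all(xy[, 1] > w) ||
          all(xy[, 2] < 0) || all(xy[, 2] > h)) {
        stop("polygon for class ", lab, " lies outside the raster extent")
      }
      inside <- inside | point_in_polygon(cx, cy, xy)
    }
    idx <- which(inside)
    if (length(idx) == 0) next
    if (strategy == "stratified_random") {
      if (length(idx) < n_per_class) {
        stop("class ", lab, " covers only ", length(idx), " pixels")
      }
      set.seed(derive_seed(seed, "roi") + match(lab, labels_seen))
      idx <- sort(sample(idx, n_per_class))
    }
    block <- tab[idx, , drop = FALSE]
    block$row <- centers$row[idx]
    block$col <- centers$col[idx]
    block$label <- lab
    picked[[lab]] <- block
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  lv <- if (all(out$label %in% CLASS_LEVELS)) CLASS_LEVELS else
    sort(unique(out$label))
  out$label <- factor(out$label, levels = lv)
  out
}

#' Pixel-level classification of a band stack
#'
#' Computes the model's index features for every pixel and predicts its
#' class. Pixels with any undefined feature (e.g. zero RGB sum) become
#' nodata. The legend maps the model's class levels to codes 0, 1, 2, ...
#' in level order.
#'
#' @param model A `graze_model`.
#' @param stack Band stack array (h x w x 7).
#' @param indices Index selection passed to [build_feature_matrix()]; must
#'   cover the model's features (default `"all"`).
#' @param ... Further arguments to [build_feature_matrix()] (rgb_mode, etc.).
#' @return A [label_raster()] of predicted classes.
#' @export
classify_raster <- function(model, stack, indices = "all", ...) {
  stopifnot(inherits(model, "graze_model"))
  h <- dim(stack)[1]
  w <- dim(stack)[2]
  tab <- stack_to_table(stack)
  fm <- build_feature_matrix(tab, indices = indices, ...)
  pred <- predict(model, fm)
  legend <- stats::setNames(seq_along(model$levels) - 1L, model$levels)
  codes <- legend[as.character(pred)]
  codes[is.na(codes)] <- 255L
  label_raster(matrix(codes, h, w), legend = legend, nodata = 255L)
}

#' 3x3 categorical mode filter
#'
#' Replaces every cell by the modal class of its 3x3 neighborhood (edge
#' cells use the valid sub-window). Nodata cells never vote. Ties in the
#' maximal count keep the center value unchanged (stability); a nodata
#' center with at least one valid neighbor takes the modal neighbor class
#' (ties there resolve to the smallest code). Idempotent on uniform rasters
#' and never introduces a code absent from the legend.
#'
#' @param raster A [label_raster()].
#' @return Filtered [label_raster()] with the same legend and shape.
#' @export
mode_filter_3x3 <- function(raster) {
  stopifnot(inherits(raster, "label_raster"))
  g <- raster$grid
  h <- nrow(g)
  w <- ncol(g)
  codes <- sort(unname(raster$legend))
  # per-code neighbor counts via shifted sums (window includes the center)
  counts <- array(0L, c(h, w, length(codes)))
  for (ci in seq_along(codes)) {
    ind <- matrix(0L, h + 2, w + 2) # zero padding outside the grid
    inner <- (!is.na(g)) & g == codes[ci]
    ind[2:(h + 1), 2:(w + 1)][inner] <- 1L
    acc <- matrix(0L, h, w)
    for (dr in 0:2) {
      for (dc in 0:2) {
        acc <- acc + ind[dr + seq_len(h), dc + seq_len(w)]
      }
    }
    counts[, , ci] <- acc
  }
  out <- g
  total <- apply(counts, c(1, 2), sum)
  mx <- apply(counts, c(1, 2), max)
  n_at_max <- apply(counts, c(1, 2), function(v) sum(v == max(v)))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (total[i, j] == 0) next # no valid votes anywhere in the window
      center_nodata <- is.na(g[i, j]) || g[i, j] == raster$nodata
      if (n_at_max[i, j] > 1 && !center_nodata) next # tie: keep center
      win <- which(counts[i, j, ] == mx[i, j])[1] # smallest code on tie
      out[i, j] <- codes[win]
    }
  }
  label_raster(out, legend = raster$legend, nodata = raster$nodata)
}

#' Agreement between two label rasters
#'
#' Fraction of pixels (valid in both rasters) assigned the same code —
#' handy for comparing a predicted map with its reference.
#'
#' @param a,b `label_raster`s of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
raster_agreement <- function(a, b) {
  stopifnot(inherits(a, "label_raster"), inherits(b, "label_raster"),
            all(dim(a$grid) == dim(b$grid)))
  ok <- !is.na(a$grid) & !is.na(b$grid) &
    a$grid != a$nodata & b$grid != b$nodata
  if (!any(ok)) return(NA_real_)
  mean(a$grid[ok] == b$grid[ok])
}
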