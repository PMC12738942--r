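#' SPXY train/test partitioning
#'
#' Sample-set Partitioning based on joint X-Y distances: a Kennard-Stone
#' selection on the normalized joint distance
#' `d_xy(i,j) = d_x(i,j)/max(d_x) + d_y(i,j)/max(d_y)`, where `d_x` is the
#' Euclidean distance between feature vectors and `d_y` the distance between
#' responses. The two mutually farthest samples seed the training set; each
#' subsequent training sample is the one whose minimum joint distance to the
#' already-selected set is largest. The procedure is fully deterministic.
#'
#' Class labels enter the Y-distance as integer codes in level order
#' (NG=0, LG=1, MG=2, SG=3) by default; `y_coding = "onehot"` uses one-hot
#' vectors instead, which makes all between-class distances equal.
#'
#' @param fm A labeled `feature_matrix`.
#' @param train_fraction Fraction of samples assigned to training
#'   (0 < f < 1; the training size is `round(f * n)`).
#' @param y_coding `"integer"` (default) or `"onehot"`.
#' @return Object of class `split_result`: list with `train_indices`,
#'   `test_indices`, `method`, `train_fraction`.
#' @export
spxy_split <- function(fm, train_fraction = 0.7,
                       y_coding = c("integer", "onehot")) {
  stopifnot(inherits(fm, "feature_matrix"))
  y_coding <- match.arg(y_coding)
  if (is.null(fm$labels)) stop("labels are required")
  n <- nrow(fm$values)
  if (n < 4) stop("need at least 4 samples")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  x <- fm$values
  if (anyNA(x)) stop("SPXY requires a complete feature matrix")
  dx <- as.matrix(stats::dist(x))
  if (max(dx) == 0) stop("degenerate input: all samples identical in X")
  ycodes <- if (y_coding == "integer") {
    matrix(as.numeric(fm$labels) - 1, ncol = 1)
  } else {
    stats::model.matrix(~ fm$labels - 1)
  }
  dy <- as.matrix(stats::dist(ycodes))
  d <- dx / max(dx) + if (max(dy) > 0) dy / max(dy) else 0
  n_train <- round(train_fraction * n)
  # seed with the mutually farthest pair (ties: smallest indices)
  far <- which(d == max(d), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  sel <- sort(unique(as.integer(far[1, ])))
  remaining <- setdiff(seq_len(n), sel)
  min_d <- apply(d[remaining, sel, drop = FALSE], 1, min)
  while (length(sel) < n_train && length(remaining) > 0) {
    pick <- remaining[which.max(min_d)]
    sel <- c(sel, pick)
    keep <- remaining != pick
    remaining <- remaining[keep]
    min_d <- pmin(min_d[keep], d[remaining, pick])
  }
  sel <- sort(sel)
  structure(
    list(train_indices = sel, test_indices = setdiff(seq_len(n), sel),
         method = "spxy", train_fraction = train_fraction),
    class = "split_result"
  )
}

#' Random stratified train/test partitioning
#'
#' Seeded alternative to [spxy_split()] drawing `round(f * n)` training rows
#' with per-class proportional allocation.
#'
#' @inheritParams spxy_split
#' @param seed Integer seed.
#' @export
random_split <- function(fm, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required")
  n <- nrow(fm$values)
  n_train <- round(train_fraction * n)
  set.seed(seed)
  # proportional per class, then top up at random to hit n_train exactly
  sel <- integer(0)
  for (cl in levels(fm$labels)) {
    idx <- which(fm$labels == cl)
    sel <- c(sel, sample(idx, floor(train_fraction * length(idx))))
  }
  pool <- setdiff(seq_len(n), sel)
  if (length(sel) < n_train) {
    sel <- c(sel, sample(pool, n_train - length(sel)))
  }
  sel <- sort(sel)
  structure(
    list(train_indices = sel, test_indices = setdiff(seq_len(n), sel),
         method = "random", train_fraction = train_fraction),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("%s split: %d train / %d test (fraction %.2f)\n",
              toupper(x$method), length(x$train_indices),
              length(x$test_indices), x$train_fraction))
  invisible(x)
}

#' Model specification with hyperparameter grid
#'
#' The default grids are the standard search ranges for this workflow:
#' KNN neighbors {3,5,7,9} x metrics {euclidean, manhattan, cosine};
#' RBF-SVM kernel scale {0.1,0.5,1,2} x box constraint C {0.1,1,10}
#' (kernel scale s maps to the RBF width via gamma = 1/s^2); RF trees
#' {100,200,300} x minimum leaf size {1,5,10}.
#'
#' @param family `"knn"`, `"svm_rbf"`, or `"rf"`.
#' @param grid data.frame of hyperparameter combinations; default per family.
#' @param cv_folds Stratified CV folds for the grid search (default 5).
#' @param seed Integer seed (fold assignment + stochastic fits).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("svm_rbf", "knn", "rf"), grid = NULL,
                       cv_folds = 5L, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      knn = expand.grid(k = c(3, 5, 7, 9),
                        metric = c("euclidean", "manhattan", "cosine"),
                        stringsAsFactors = FALSE),
      svm_rbf = expand.grid(kernel_scale = c(0.1, 0.5, 1, 2),
                            cost = c(0.1, 1, 10)),
      rf = expand.grid(n_trees = c(100, 200, 300), min_leaf = c(1, 5, 10))
    )
  }
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  structure(
    list(family = family, grid = grid, cv_folds = as.integer(cv_folds),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

# Distance-weighted KNN prediction. Weights are 1/d; a query coinciding with
# one or more training points (d = 0) takes the majority class among its
# zero-distance neighbors (infinite-weight convention). Cosine distance is
# 1 - cosine similarity; zero-norm vectors get distance 1 to everything.
knn_predict <- function(train_x, train_y, test_x, k, metric = "euclidean") {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  lv <- levels(train_y)
  dmat <- switch(metric,
    euclidean = {
      cross <- tcrossprod(test_x, train_x)
      d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") - 2 * cross
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      out <- matrix(0, nrow(test_x), nrow(train_x))
      for (j in seq_len(ncol(train_x))) {
        out <- out + abs(outer(test_x[, j], train_x[, j], "-"))
      }
      out
    },
    cosine = {
      ntr <- sqrt(rowSums(train_x^2))
      nte <- sqrt(rowSums(test_x^2))
      sim <- tcrossprod(test_x, train_x) / outer(nte, ntr)
      sim[!is.finite(sim)] <- 0
      1 - sim
    },
    stop("unknown metric: ", metric)
  )
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- dmat[i, ]
    nn <- order(d)[seq_len(min(k, length(d)))]
    dn <- d[nn]
    if (any(dn == 0)) {
      votes <- table(train_y[nn[dn == 0]])
    } else {
      w <- 1 / dn
      votes <- tapply(w, factor(as.character(train_y[nn]), levels = lv),
                      sum, default = 0)
    }
    pred[i] <- names(votes)[which.max(votes)]
  }
  factor(pred, levels = lv)
}

fit_one <- function(family, params, x, y, seed) {
  switch(family,
    knn = list(train_x = x, train_y = y, k = params$k,
               metric = as.character(params$metric)),
    svm_rbf = {
      set.seed(seed)
      e1071::svm(x, y, kernel = "radial",
                 gamma = 1 / params$kernel_scale^2, cost = params$cost,
                 scale = FALSE)
    },
    rf = {
      set.seed(seed)
      randomForest::randomForest(x, y, ntree = params$n_trees,
                                 nodesize = params$min_leaf)
    }
  )
}

predict_one <- function(family, fit, x) {
  switch(family,
    knn = knn_predict(fit$train_x, fit$train_y, x, fit$k, fit$metric),
    svm_rbf = stats::predict(fit, x),
    rf = stats::predict(fit, x)
  )
}

#' Fit a classifier with exhaustive grid search
#'
#' Standardizes features (z-score with training-set statistics, reapplied
#' identically at prediction time), evaluates every grid point by stratified
#' k-fold cross-validated overall accuracy on the training set, picks the
#' best (ties: first in grid order), and refits on the full training set.
#'
#' @param train A labeled `feature_matrix` (>= 2 classes).
#' @param spec A [model_spec()].
#' @return Object of class `graze_model`: list with `family`, `best_params`,
#'   `cv_oa` (best grid-point CV accuracy), `grid_oa` (per grid point),
#'   `std` (standardization parameters), `fit`, `levels`, `feature_names`.
#' @export
fit_classifier <- function(train, spec) {
  stopifnot(inherits(train, "feature_matrix"), inherits(spec, "model_spec"))
  if (is.null(train$labels)) stop("labels are required")
  y <- droplevels(train$labels)
  if (nlevels(y) < 2) stop("need >= 2 classes in training labels")
  x <- train$values
  if (anyNA(x)) stop("training matrix contains undefined entries")
  std <- std_params(x)
  xs <- apply_std(x, std)
  folds <- make_folds(y, spec$cv_folds, spec$seed)
  grid_oa <- numeric(nrow(spec$grid))
  for (g in seq_len(nrow(spec$grid))) {
    params <- spec$grid[g, , drop = FALSE]
    correct <- 0L
    for (i in seq_len(spec$cv_folds)) {
      tr <- folds != i
      if (nlevels(droplevels(y[tr])) < nlevels(y)) {
        stop("a CV fold is missing a class; reduce cv_folds")
      }
      fit <- fit_one(spec$family, params, xs[tr, , drop = FALSE], y[tr],
                     spec$seed + i)
      pred <- predict_one(spec$family, fit, xs[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    grid_oa[g] <- correct / length(y)
  }
  best <- which.max(grid_oa) # first maximum in grid order
  best_params <- spec$grid[best, , drop = FALSE]
  fit <- fit_one(spec$family, best_params, xs, y, spec$seed)
  structure(
    list(family = spec$family, best_params = best_params,
         cv_oa = grid_oa[best],
         grid_oa = cbind(spec$grid, cv_oa = grid_oa),
         std = std, fit = fit, levels = levels(y),
         feature_names = colnames(x), seed = spec$seed),
    class = "graze_model"
  )
}

#' Predict grazing classes for new samples
#'
#' @param object A `graze_model`.
#' @param newdata `feature_matrix` or numeric matrix with the training
#'   feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes; rows with undefined features give
#'   `NA`.
#' @export
predict.graze_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(x))
  if (length(missing) > 0) {
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, object$feature_names, drop = FALSE]
  ok <- stats::complete.cases(x)
  out <- factor(rep(NA_character_, nrow(x)), levels = object$levels)
  if (any(ok)) {
    xs <- apply_std(x[ok, , drop = FALSE], object$std)
    out[ok] <- predict_one(object$family, object$fit, xs)
  }
  out
}

#' @export
print.graze_model <- function(x, ...) {
  cat(sprintf("Grazing classifier: %s\n", x$family))
  cat("  best params:",
      paste(names(x$best_params), unlist(lapply(x$best_params, format)),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  grid-search CV OA: %.4f\n", x$cv_oa))
  invisible(x)
}

#' Confusion-matrix evaluation: overall accuracy and Cohen's kappa
#'
#' Builds the confusion matrix (rows = reference, columns = predicted), the
#' overall accuracy OA = trace/n, the chance-expected agreement
#' `p_e = sum_i row_i * col_i / n^2`, and kappa = (OA - p_e)/(1 - p_e)
#' (undefined when p_e = 1).
#'
#' @param model A `graze_model`.
#' @param test A labeled `feature_matrix` with the training feature schema.
#' @return Object of class `classification_report`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "graze_model"), inherits(test, "feature_matrix"))
  if (is.null(test$labels)) stop("test labels are required")
  if (nrow(test$values) == 0) stop("empty test set")
  pred <- predict(model, test)
  classification_report(
    reference = factor(as.character(test$labels), levels = model$levels),
    predicted = pred, best_params = model$best_params, family = model$family
  )
}

#' Build a classification report from reference and predicted labels
#'
#' @param reference,predicted Factors on a common level set.
#' @param best_params,family Optional provenance carried into the report.
#' @return Object of class `classification_report`: `confusion` (reference
#'   rows x predicted columns), `oa`, `kappa`, `per_class_recall`, `n`.
#' @export
classification_report <- function(reference, predicted, best_params = NULL,
                                  family = NULL) {
  lv <- levels(reference)
  predicted <- factor(as.character(predicted), levels = lv)
  cm <- table(reference = reference, predicted = predicted)
  n <- sum(cm)
  oa <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe == 1) NA_real_ else (oa - pe) / (1 - pe)
  recall <- diag(cm) / rowSums(cm)
  structure(
    list(confusion = cm, oa = oa, kappa = kappa,
         per_class_recall = recall, n = as.integer(n),
         best_params = best_params, family = family),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report")
  if (!is.null(x$family)) cat(" (", x$family, ")", sep = "")
  cat("\n")
  cat(sprintf("  n = %d, OA = %.4f (%.2f%%), Kappa = %.4f (%.2f%%)\n",
              x$n, x$oa, 100 * x$oa, x$kappa, 100 * x$kappa))
  cat("  confusion matrix (rows = reference):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize a classification report to JSON (+ confusion CSV)
#' @param report A `classification_report`.
#' @param path JSON output file; the confusion matrix also goes to
#'   `<path>.confusion.csv`.
#' @export
write_classification_report <- function(report, path) {
  jsonlite::write_json(
    list(oa = report$oa, kappa = report$kappa, n = report$n,
         per_class_recall = as.list(report$per_class_recall),
         best_params = if (!is.null(report$best_params))
           as.list(report$best_params),
         family = report$family),
    path, auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   paste0(path, ".confusion.csv"))
  invisible(path)
}
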