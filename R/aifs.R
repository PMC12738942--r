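#' Random-forest out-of-bag permutation importance ranking
#'
#' Grows a random forest on the labeled feature matrix and scores each
#' feature j by the mean over trees of the increase in out-of-bag error when
#' feature j is permuted within that tree's OOB set (the raw, unscaled
#' permutation importance). Features are returned in descending score order;
#' ties keep original column order (stable sort). Scores can be slightly
#' negative for uninformative features (permutation noise).
#'
#' Rows containing undefined entries are dropped with a warning before
#' fitting.
#'
#' @param fm A labeled `feature_matrix`.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; fixed seed gives a fixed ranking.
#' @return Object of class `importance_ranking`: list with `feature_names`
#'   (descending importance), `scores` (same order), `n_trees`, `seed`.
#' @export
rank_importance <- function(fm, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required")
  if (n_trees < 1) stop("n_trees must be >= 1")
  x <- fm$values
  ok <- stats::complete.cases(x)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with undefined entries dropped")
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("no complete rows left")
  y <- droplevels(fm$labels[ok])
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees, importance = TRUE)
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-raw) # stable: ties keep column order
  structure(
    list(feature_names = colnames(x)[ord], scores = unname(raw[ord]),
         n_trees = as.integer(n_trees), seed = as.integer(seed)),
    class = "importance_ranking"
  )
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("RF permutation-importance ranking (%d trees)\n", x$n_trees))
  for (i in seq_along(x$feature_names)) {
    cat(sprintf("  %2d. %-12s %+.5f\n", i, x$feature_names[i], x$scores[i]))
  }
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' rho = cov(x, y) / (sd(x) sd(y)). Returns `NA` when either vector is
#' constant (the selection gate treats that as rho = 0, i.e. non-blocking).
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return Scalar in `[-1, 1]`, or `NA` for constant input.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
}

# k-fold CV overall accuracy of the gate classifier on a feature subset.
# Folds are supplied (fixed for the whole selection run); the classifier is
# re-seeded deterministically per fold so any evaluation can be replayed.
# Zero-variance columns are dropped before fitting: a constant feature can
# then never change the CV accuracy.
cv_gate_oa <- function(x, y, features, folds, seed, gate = "rf",
                       n_trees = 100L) {
  xs <- x[, features, drop = FALSE]
  keep <- apply(xs, 2, function(v) stats::sd(v) > 0)
  xs <- xs[, keep, drop = FALSE]
  if (ncol(xs) == 0) return(0)
  k <- max(folds)
  correct <- 0L
  for (i in seq_len(k)) {
    tr <- folds != i
    te <- !tr
    set.seed(seed + i)
    pred <- switch(gate,
      rf = {
        fit <- randomForest::randomForest(xs[tr, , drop = FALSE],
                                          droplevels(y[tr]),
                                          ntree = n_trees)
        stats::predict(fit, xs[te, , drop = FALSE])
      },
      svm = {
        fit <- e1071::svm(xs[tr, , drop = FALSE], droplevels(y[tr]),
                          kernel = "radial", scale = TRUE)
        stats::predict(fit, xs[te, , drop = FALSE])
      },
      knn = {
        knn_predict(xs[tr, , drop = FALSE], droplevels(y[tr]),
                    xs[te, , drop = FALSE], k = 5, metric = "euclidean")
      },
      stop("unknown gate classifier: ", gate)
    )
    correct <- correct + sum(as.character(pred) == as.character(y[te]))
  }
  correct / length(y)
}

#' Automatic incremental feature selection (AIFS)
#'
#' Walks the importance-ranked candidates in order and grows a subset under
#' two gates. (1) Correlation gate: a candidate whose absolute Pearson
#' correlation with any already-selected feature exceeds `rho_thresh` is
#' rejected as redundant. (2) Accuracy gate: the surviving candidate is
#' provisionally added and the k-fold cross-validated overall accuracy (OA)
#' of the gate classifier is computed on the enlarged subset; the candidate
#' is retained only if OA strictly improves on the best OA so far. Every
#' decision is recorded so the run can be audited or replayed.
#'
#' Folds are stratified by class and fixed once per run from `seed`;
#' correlations are computed on the full matrix handed in. Constant
#' candidates pass the correlation gate (undefined rho treated as 0) but can
#' never pass the accuracy gate.
#'
#' @param fm A labeled `feature_matrix` (complete rows; rows with undefined
#'   entries are dropped with a warning, matching [rank_importance()]).
#' @param ranking An `importance_ranking` covering `fm`'s columns, or NULL to
#'   compute one here.
#' @param rho_thresh Correlation-gate threshold in (0, 1]; default 0.8.
#' @param k_folds CV folds for the accuracy gate; default 5.
#' @param seed Integer seed (folds + gate classifier).
#' @param gate Gate classifier: `"rf"` (default), `"svm"`, or `"knn"`.
#' @param n_trees Trees for the RF gate (and default ranking); default 100.
#' @param delta Minimum OA improvement to accept (default 0: any strict
#'   improvement).
#' @return Object of class `aifs_result`: list with `ranking`, `trajectory`
#'   (data.frame: step, feature, decision, max_abs_rho, cv_accuracy_after),
#'   `selected`, `rho_thresh`, `k_folds`, `seed`, `gate`, `n_trees`,
#'   `best_oa`.
#' @export
incremental_select <- function(fm, ranking = NULL, rho_thresh = 0.8,
                               k_folds = 5L, seed = 1L, gate = "rf",
                               n_trees = 100L, delta = 0) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required")
  if (rho_thresh <= 0 || rho_thresh > 1) stop("rho_thresh must be in (0, 1]")
  if (k_folds < 2) stop("k_folds must be >= 2")
  ok <- stats::complete.cases(fm$values)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with undefined entries dropped")
    fm <- subset_rows(fm, ok)
  }
  if (is.null(ranking)) {
    ranking <- rank_importance(fm, n_trees = max(n_trees, 500L), seed = seed)
  }
  if (!setequal(ranking$feature_names, colnames(fm$values))) {
    stop("ranking does not cover the feature matrix columns")
  }
  x <- fm$values
  y <- droplevels(fm$labels)
  folds <- make_folds(y, k_folds, seed)
  selected <- character(0)
  best_oa <- 0
  traj <- list()
  for (step in seq_along(ranking$feature_names)) {
    cand <- ranking$feature_names[step]
    max_rho <- if (length(selected) == 0) 0 else {
      rhos <- vapply(selected, function(s) {
        r <- pearson(x[, cand], x[, s])
        if (is.na(r)) 0 else abs(r)
      }, numeric(1))
      max(rhos)
    }
    if (max_rho > rho_thresh) {
      decision <- "rejected_correlation"
      oa <- NA_real_
    } else {
      oa <- cv_gate_oa(x, y, c(selected, cand), folds, seed + 97L * step,
                       gate, n_trees)
      if (oa > best_oa + delta) {
        decision <- "accepted"
        selected <- c(selected, cand)
        best_oa <- oa
      } else {
        decision <- "rejected_no_gain"
      }
    }
    traj[[step]] <- data.frame(
      step = step, feature = cand, decision = decision,
      max_abs_rho = max_rho, cv_accuracy_after = oa,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      ranking = ranking, trajectory = do.call(rbind, traj),
      selected = selected, rho_thresh = rho_thresh,
      k_folds = as.integer(k_folds), seed = as.integer(seed),
      gate = gate, n_trees = as.integer(n_trees), delta = delta,
      best_oa = best_oa
    ),
    class = "aifs_result"
  )
}

#' Audit an AIFS run by independent replay
#'
#' Re-derives every accept/reject decision of a recorded trajectory from
#' scratch: correlations are recomputed with [pearson()] against the subset
#' selected so far, and every accuracy-gate evaluation is recomputed with the
#' recorded fold seed and gate classifier. Returns the audit table and
#' whether the full decision sequence reproduces.
#'
#' @param fm The same labeled `feature_matrix` handed to
#'   [incremental_select()].
#' @param result The `aifs_result` to audit.
#' @return List with `ok` (logical scalar), `audit` (data.frame comparing
#'   recorded vs replayed decision and OA per step).
#' @export
replay_aifs <- function(fm, result) {
  stopifnot(inherits(result, "aifs_result"))
  ok_rows <- stats::complete.cases(fm$values)
  if (!all(ok_rows)) fm <- subset_rows(fm, ok_rows)
  x <- fm$values
  y <- droplevels(fm$labels)
  folds <- make_folds(y, result$k_folds, result$seed)
  selected <- character(0)
  best_oa <- 0
  tr <- result$trajectory
  audit <- tr
  audit$replay_decision <- NA_character_
  audit$replay_oa <- NA_real_
  for (i in seq_len(nrow(tr))) {
    cand <- tr$feature[i]
    max_rho <- if (length(selected) == 0) 0 else {
      max(vapply(selected, function(s) {
        r <- pearson(x[, cand], x[, s])
        if (is.na(r)) 0 else abs(r)
      }, numeric(1)))
    }
    if (max_rho > result$rho_thresh) {
      dec <- "rejected_correlation"
      oa <- NA_real_
    } else {
      oa <- cv_gate_oa(x, y, c(selected, cand), folds,
                       result$seed + 97L * tr$step[i], result$gate,
                       result$n_trees)
      if (oa > best_oa + result$delta) {
        dec <- "accepted"
        selected <- c(selected, cand)
        best_oa <- oa
      } else {
        dec <- "rejected_no_gain"
      }
    }
    audit$replay_decision[i] <- dec
    audit$replay_oa[i] <- oa
  }
  same <- identical(audit$decision, audit$replay_decision) &&
    isTRUE(all.equal(audit$cv_accuracy_after, audit$replay_oa)) &&
    identical(selected, result$selected)
  list(ok = same, audit = audit)
}

#' @export
print.aifs_result <- function(x, ...) {
  cat("AIFS result\n")
  cat(sprintf("  rho_thresh = %g, %d-fold CV, gate = %s\n",
              x$rho_thresh, x$k_folds, x$gate))
  cat(sprintf("  selected %d / %d features (best CV OA = %.4f):\n",
              length(x$selected), nrow(x$trajectory), x$best_oa))
  cat("   ", paste(x$selected, collapse = ", "), "\n")
  rej <- table(x$trajectory$decision)
  cat("  decisions:", paste(sprintf("%s=%d", names(rej), rej),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an AIFS result to JSON
#' @param result An `aifs_result`.
#' @param path Output file.
#' @export
write_aifs_result <- function(result, path) {
  jsonlite::write_json(
    list(
      ranking = data.frame(feature = result$ranking$feature_names,
                           importance = result$ranking$scores),
      trajectory = result$trajectory,
      selected = result$selected,
      rho_thresh = result$rho_thresh, k_folds = result$k_folds,
      seed = result$seed, gate = result$gate, best_oa = result$best_oa
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
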