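#' Per-class descriptive statistics
#'
#' Sample mean and sample variance (n-1 denominator) for every class x
#' feature cell, with undefined entries (`NA`) excluded pairwise and the
#' exclusion count reported.
#'
#' @param fm A `feature_matrix` with labels; every class needs at least 2
#'   valid values per feature.
#' @return data.frame with columns `feature`, `class`, `n`, `n_excluded`,
#'   `mean`, `var`.
#' @export
class_stats <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required")
  classes <- levels(fm$labels)
  out <- expand.grid(feature = colnames(fm$values), class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_
  out$n_excluded <- NA_integer_
  out$mean <- NA_real_
  out$var <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- fm$values[fm$labels == out$class[i], out$feature[i]]
    ok <- v[is.finite(v)]
    if (length(ok) < 2) {
      stop(sprintf("class %s has < 2 valid values for feature %s",
                   out$class[i], out$feature[i]))
    }
    out$n[i] <- length(ok)
    out$n_excluded[i] <- length(v) - length(ok)
    out$mean[i] <- mean(ok)
    out$var[i] <- stats::var(ok)
  }
  out
}

#' Pairwise M-statistic
#'
#' M = |mean_a - mean_b| / sqrt(var_a + var_b), a normalized two-class mean
#' separation: larger M means less distributional overlap between the two
#' classes on that feature. Variances use the sample (n-1) estimator.
#' Symmetric in its arguments. When both variances are zero the statistic is
#' 0 for equal means and undefined (`NA`, with a warning) otherwise.
#'
#' @param values_a,values_b Numeric vectors (>= 2 finite values each).
#' @return Scalar M >= 0, or `NA` in the degenerate unequal-constant case.
#' @export
m_statistic <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 finite values")
  va <- stats::var(a)
  vb <- stats::var(b)
  dm <- abs(mean(a) - mean(b))
  if (va + vb == 0) {
    if (dm == 0) return(0)
    warning("both variances zero with unequal means: M undefined")
    return(NA_real_)
  }
  dm / sqrt(va + vb)
}

#' M-statistic for every class pair and feature
#'
#' @param fm A labeled `feature_matrix`.
#' @return data.frame with `feature`, `class_a`, `class_b`, `M` for all
#'   C(4,2)=6 pairs (generally C(k,2)), in level order.
#' @export
m_pairwise <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required")
  classes <- levels(fm$labels)
  pairs <- utils::combn(classes, 2)
  rows <- list()
  for (f in colnames(fm$values)) {
    for (p in seq_len(ncol(pairs))) {
      a <- fm$values[fm$labels == pairs[1, p], f]
      b <- fm$values[fm$labels == pairs[2, p], f]
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, class_a = pairs[1, p], class_b = pairs[2, p],
        M = m_statistic(a, b), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' One-way ANOVA and Tukey multiple comparisons per feature
#'
#' Fixed-effects one-way ANOVA of each feature on the class factor, followed
#' by Tukey's HSD pairwise comparisons at level `alpha`. Zero-total-variance
#' features are flagged and excluded from testing rather than producing
#' degenerate F statistics.
#'
#' @param fm A labeled `feature_matrix` (>= 2 classes, each >= 2 samples).
#' @param alpha Familywise significance level for the Tukey flags
#'   (default 0.05).
#' @return List with `anova` (data.frame: feature, F, p, excluded) and
#'   `tukey` (data.frame: feature, class_a, class_b, diff, p_adj, significant).
#' @export
anova_tukey <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("labels are required")
  if (nlevels(droplevels(fm$labels)) < 2) stop("need >= 2 classes")
  an <- list()
  tk <- list()
  for (f in colnames(fm$values)) {
    v <- fm$values[, f]
    ok <- is.finite(v)
    d <- data.frame(value = v[ok], class = droplevels(fm$labels[ok]))
    if (stats::var(d$value) == 0) {
      an[[f]] <- data.frame(feature = f, F = NA_real_, p = NA_real_,
                            excluded = TRUE, stringsAsFactors = FALSE)
      next
    }
    fit <- stats::aov(value ~ class, data = d)
    s <- summary(fit)[[1]]
    an[[f]] <- data.frame(feature = f, F = s[["F value"]][1],
                          p = s[["Pr(>F)"]][1], excluded = FALSE,
                          stringsAsFactors = FALSE)
    hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$class
    pr <- strsplit(rownames(hsd), "-", fixed = TRUE)
    tk[[f]] <- data.frame(
      feature = f,
      class_a = vapply(pr, `[`, "", 2),
      class_b = vapply(pr, `[`, "", 1),
      diff = unname(hsd[, "diff"]),
      p_adj = unname(hsd[, "p adj"]),
      significant = unname(hsd[, "p adj"]) < alpha,
      stringsAsFactors = FALSE
    )
  }
  list(anova = do.call(rbind, c(an, list(make.row.names = FALSE))),
       tukey = do.call(rbind, c(tk, list(make.row.names = FALSE))))
}

#' Full class-separability report
#'
#' Combines per-class statistics, ANOVA + Tukey tests, and the pairwise
#' M-statistic screen with per-feature min/mean/max M summaries, so either a
#' max-M or mean-M reading of feature separability is available.
#'
#' @inheritParams anova_tukey
#' @return Object of class `separability_report`: list with `class_stats`,
#'   `anova`, `tukey`, `m` (pairwise), `m_summary` (feature, M_min, M_mean,
#'   M_max), and `alpha`.
#' @export
separability_report <- function(fm, alpha = 0.05) {
  cs <- class_stats(fm)
  at <- anova_tukey(fm, alpha)
  m <- m_pairwise(fm)
  ms <- do.call(rbind, lapply(split(m, m$feature), function(d) {
    data.frame(feature = d$feature[1], M_min = min(d$M), M_mean = mean(d$M),
               M_max = max(d$M), stringsAsFactors = FALSE)
  }))
  ms <- ms[match(colnames(fm$values), ms$feature), ]
  rownames(ms) <- NULL
  structure(
    list(class_stats = cs, anova = at$anova, tukey = at$tukey,
         m = m, m_summary = ms, alpha = alpha),
    class = "separability_report"
  )
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("Separability report: %d features, alpha = %g\n",
              nrow(x$m_summary), x$alpha))
  nsig <- sum(x$anova$p < x$alpha, na.rm = TRUE)
  cat(sprintf("  ANOVA significant features: %d / %d\n", nsig,
              sum(!x$anova$excluded)))
  top <- x$m_summary[order(-x$m_summary$M_max), ][1:min(5, nrow(x$m_summary)), ]
  cat("  top features by max M:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-8s M_max = %.2f  M_mean = %.2f\n",
                top$feature[i], top$M_max[i], top$M_mean[i]))
  }
  invisible(x)
}

#' Write a separability report as tidy CSV
#' @param report A `separability_report`.
#' @param path Output file (long format: feature, class_pair, M, tukey
#'   significance, ANOVA F and p).
#' @export
write_separability_report <- function(report, path) {
  m <- report$m
  key <- paste(m$feature, m$class_a, m$class_b)
  tkey <- paste(report$tukey$feature, report$tukey$class_a,
                report$tukey$class_b)
  m$tukey_sig <- report$tukey$significant[match(key, tkey)]
  m$anova_F <- report$anova$F[match(m$feature, report$anova$feature)]
  m$anova_p <- report$anova$p[match(m$feature, report$anova$feature)]
  m$class_pair <- paste(m$class_a, m$class_b, sep = "-")
  utils::write.csv(
    m[c("feature", "class_pair", "M", "tukey_sig", "anova_F", "anova_p")],
    path, row.names = FALSE
  )
  invisible(path)
}
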