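test_that("SPXY at fraction 0.7 partitions 720 samples into 504/216", {
  df <- generate_samples(synthetic_scenario(seed = 1))
  fm <- build_feature_matrix(df)
  sp <- spxy_split(fm, 0.7)
  expect_length(sp$train_indices, 504)
  expect_length(sp$test_indices, 216)
  expect_setequal(c(sp$train_indices, sp$test_indices), seq_len(720))
  expect_length(intersect(sp$train_indices, sp$test_indices), 0)
  # deterministic
  sp2 <- spxy_split(fm, 0.7)
  expect_identical(sp$train_indices, sp2$train_indices)
})

test_that("SPXY partitions exactly for assorted sizes and fractions", {
  set.seed(51)
  for (case in list(c(10, 0.5), c(23, 0.3), c(57, 0.8), c(16, 0.25))) {
    n <- case[1]
    x <- matrix(rnorm(n * 3), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    fm <- feature_matrix(x, labels = factor(rep_len(c("NG", "LG", "MG",
                                                      "SG"), n)))
    sp <- spxy_split(fm, case[2])
    expect_length(sp$train_indices, round(case[2] * n))
    expect_setequal(c(sp$train_indices, sp$test_indices), seq_len(n))
  }
})

test_that("SPXY seeds the training set with the farthest joint pair", {
  x <- matrix(c(0, 0, 0.1, 0, 5, 0, 5.1, 0), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  fm <- feature_matrix(x, labels = factor(c("NG", "NG", "SG", "SG"),
                                          levels = c("NG", "LG", "MG",
                                                     "SG")))
  sp <- spxy_split(fm, 0.5)
  # rows 1 and 4 are mutually farthest in both X and Y
  expect_setequal(sp$train_indices, c(1L, 4L))
  expect_error(
    spxy_split(feature_matrix(matrix(1, 4, 1, dimnames = list(NULL, "a")),
                              labels = factor(c("NG", "NG", "SG", "SG"))),
               0.5),
    "degenerate"
  )
})

test_that("default grids match the published search ranges", {
  expect_equal(sort(unique(model_spec("knn")$grid$k)), c(3, 5, 7, 9))
  expect_setequal(unique(model_spec("knn")$grid$metric),
                  c("euclidean", "manhattan", "cosine"))
  expect_equal(sort(unique(model_spec("svm_rbf")$grid$kernel_scale)),
               c(0.1, 0.5, 1, 2))
  expect_equal(sort(unique(model_spec("svm_rbf")$grid$cost)),
               c(0.1, 1, 10))
  expect_equal(sort(unique(model_spec("rf")$grid$n_trees)),
               c(100, 200, 300))
  expect_equal(sort(unique(model_spec("rf")$grid$min_leaf)), c(1, 5, 10))
  expect_error(model_spec("rf", grid = data.frame()), "empty")
})

test_that("every family separates a linearly separable problem", {
  fm <- separable_fm()
  for (fam in c("knn", "svm_rbf", "rf")) {
    m <- fit_classifier(fm, model_spec(fam, cv_folds = 4, seed = 2))
    expect_equal(max(m$grid_oa$cv_oa), 1, label = fam)
    expect_equal(evaluate(m, fm)$oa, 1, label = fam)
  }
})

test_that("distance-weighted KNN assigns coincident queries exactly", {
  train <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  y <- factor(c("A", "B", "B"))
  pred <- grazspec:::knn_predict(train, y, matrix(c(0, 0), ncol = 2),
                                 k = 3, metric = "euclidean")
  expect_equal(as.character(pred), "A") # zero distance dominates
  # cosine metric is scale-free along rays from the origin
  pred2 <- grazspec:::knn_predict(train[2:3, ], y[2:3],
                                  matrix(c(10, 10), ncol = 2),
                                  k = 1, metric = "cosine")
  expect_equal(as.character(pred2), "B")
})

test_that("RF grid search is deterministic under a fixed seed", {
  df <- generate_samples(small_scenario(n_per_class = 25, seed = 3))
  fm <- band_fm(df)
  spec <- model_spec("rf", grid = expand.grid(n_trees = c(50, 100),
                                              min_leaf = c(1, 5)),
                     cv_folds = 3, seed = 11)
  m1 <- fit_classifier(fm, spec)
  m2 <- fit_classifier(fm, spec)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(m1$grid_oa$cv_oa, m2$grid_oa$cv_oa)
})

test_that("evaluation formulas match hand computation", {
  lv <- c("NG", "LG", "MG", "SG")
  ref <- factor(rep(lv, each = 25), levels = lv)
  # perfect prediction
  perfect <- classification_report(ref, ref)
  expect_equal(perfect$oa, 1)
  expect_equal(perfect$kappa, 1)
  # constant predictor on balanced classes: OA = 0.25, kappa = 0
  const <- classification_report(ref, factor(rep("NG", 100), levels = lv))
  expect_equal(const$oa, 0.25)
  expect_equal(const$kappa, 0)
  # confusion [[40,10],[20,30]]: OA = 0.7, p_e = 0.5, kappa = 0.4
  ref2 <- factor(rep(c("A", "B"), c(50, 50)))
  pred2 <- factor(c(rep("A", 40), rep("B", 10), rep("A", 20),
                    rep("B", 30)), levels = c("A", "B"))
  rep2 <- classification_report(ref2, pred2)
  expect_equal(unclass(rep2$confusion),
               matrix(c(40, 20, 10, 30), 2), ignore_attr = TRUE)
  expect_equal(rep2$oa, 0.7)
  expect_equal(rep2$kappa, 0.4)
})

test_that("kappa is 1 exactly when the off-diagonal sum is 0", {
  set.seed(61)
  lv <- c("A", "B", "C")
  for (i in 1:20) {
    ref <- factor(sample(lv, 30, replace = TRUE), levels = lv)
    pred <- ref
    flip <- runif(1) < 0.5
    if (flip) {
      j <- sample(30, 3)
      pred[j] <- factor(sample(lv, 3, replace = TRUE), levels = lv)
    }
    r <- classification_report(ref, pred)
    off <- sum(r$confusion) - sum(diag(r$confusion))
    expect_equal(isTRUE(all.equal(r$kappa, 1)), off == 0)
  }
})

test_that("test-set row order does not change the report", {
  df <- generate_samples(small_scenario(n_per_class = 25, seed = 13))
  fm <- band_fm(df)
  sp <- spxy_split(fm, 0.7)
  m <- fit_classifier(subset_rows(fm, sp$train_indices),
                      model_spec("svm_rbf", cv_folds = 3, seed = 5))
  test <- subset_rows(fm, sp$test_indices)
  r1 <- evaluate(m, test)
  set.seed(71)
  perm <- sample(nrow(test$values))
  r2 <- evaluate(m, subset_rows(test, perm))
  expect_equal(unclass(r1$confusion), unclass(r2$confusion))
  expect_equal(r1$oa, r2$oa)
  expect_equal(r1$kappa, r2$kappa)
})

test_that("random stratified split hits the requested size", {
  df <- generate_samples(small_scenario(n_per_class = 30, seed = 9))
  fm <- band_fm(df)
  sp <- random_split(fm, 0.7, seed = 3)
  expect_length(sp$train_indices, round(0.7 * 120))
  expect_setequal(c(sp$train_indices, sp$test_indices), seq_len(120))
})
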