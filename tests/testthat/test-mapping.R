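legend4 <- c(NG = 0L, LG = 1L, MG = 2L, SG = 3L)

test_that("mode filter is idempotent on uniform rasters", {
  r <- label_raster(matrix(2L, 6, 6), legend = legend4)
  out <- mode_filter_3x3(r)
  expect_identical(out$grid, r$grid)
})

test_that("a single dissenting pixel is absorbed by its neighborhood", {
  g <- matrix(0L, 5, 5)
  g[3, 3] <- 3L
  out <- mode_filter_3x3(label_raster(g, legend = legend4))
  expect_equal(out$grid[3, 3], 0L)
  expect_true(all(out$grid == 0L))
})

test_that("ties in the window majority keep the center value", {
  # center A (code 0) with neighbors 4x B (1) and 4x C (2)
  g <- matrix(c(1L, 1L, 2L,
                1L, 0L, 2L,
                1L, 2L, 2L), 3, 3, byrow = TRUE)
  out <- mode_filter_3x3(label_raster(g, legend = legend4))
  expect_equal(out$grid[2, 2], 0L)
})

test_that("a nodata center with valid neighbors takes the modal class", {
  g <- matrix(1L, 3, 3)
  g[2, 2] <- 255L
  out <- mode_filter_3x3(label_raster(g, legend = legend4))
  expect_equal(out$grid[2, 2], 1L)
  # an isolated all-nodata raster stays nodata
  nd <- label_raster(matrix(255L, 3, 3), legend = legend4)
  expect_identical(mode_filter_3x3(nd)$grid, nd$grid)
})

test_that("mode filter never invents class codes", {
  set.seed(81)
  for (i in 1:10) {
    g <- matrix(sample(c(0L, 3L, 255L), 64, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)), 8, 8)
    out <- mode_filter_3x3(label_raster(g, legend = legend4))
    expect_true(all(out$grid %in% c(0L, 3L, 255L)))
  }
})

test_that("filtering a salt-noise field cannot shrink the majority class", {
  set.seed(83)
  g <- matrix(0L, 20, 20)
  flip <- sample(400, 30)
  g[flip] <- 1L
  out <- mode_filter_3x3(label_raster(g, legend = legend4))
  expect_gte(sum(out$grid == 0L), sum(g == 0L))
})

test_that("label_raster validates codes against the legend", {
  expect_error(label_raster(matrix(7L, 2, 2), legend = legend4),
               "outside the legend")
  expect_error(label_raster(matrix(0L, 2, 2),
                            legend = c(A = 0L, B = 255L)),
               "collides")
})

test_that("ROI extraction honors the pixel-center containment rule", {
  sc <- small_scenario(n_per_class = 10, seed = 5)
  scene <- generate_raster(sc, 8)
  # polygon covering exactly the center of pixel [1, 1] (x in [0,1))
  one_px <- list(list(label = "NG",
                      xy = cbind(x = c(0.1, 0.9, 0.9, 0.1),
                                 y = c(0.1, 0.1, 0.9, 0.9))))
  tab <- extract_roi_samples(scene$stack, one_px, "per_pixel")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$row, 1)
  expect_equal(tab$col, 1)
  expect_equal(tab$NIR_MS, unname(scene$stack[1, 1, "NIR_MS"]))
  out_of_extent <- list(list(label = "NG",
                             xy = cbind(x = c(100, 110, 110, 100),
                                        y = c(100, 100, 110, 110))))
  expect_error(extract_roi_samples(scene$stack, out_of_extent,
                                   "per_pixel"),
               "outside the raster extent")
})

test_that("stratified ROI sampling is balanced and seed-stable", {
  scene <- generate_raster(small_scenario(n_per_class = 10, seed = 5), 32)
  rois <- quadrant_rois(32)
  t1 <- extract_roi_samples(scene$stack, rois, "stratified_random",
                            n_per_class = 50, seed = 2)
  t2 <- extract_roi_samples(scene$stack, rois, "stratified_random",
                            n_per_class = 50, seed = 2)
  expect_identical(t1, t2)
  expect_equal(unname(table(t1$label)), rep(50L, 4), ignore_attr = TRUE)
  # per_pixel over the quadrants covers the full grid
  full <- extract_roi_samples(scene$stack, rois, "per_pixel")
  expect_equal(nrow(full), 32 * 32)
  expect_equal(unname(table(full$label)), rep(256L, 4),
               ignore_attr = TRUE)
})

test_that("noiseless quadrants are recovered almost perfectly", {
  pf <- default_profiles(40)
  for (cl in names(pf)) pf[[cl]]$band_sds[] <- 0
  sc0 <- synthetic_scenario(profiles = pf, seed = 2)
  scene <- generate_raster(sc0, 16)
  train <- generate_samples(synthetic_scenario(
    profiles = default_profiles(40), seed = 2))
  fm <- build_feature_matrix(train)
  m <- fit_classifier(fm, model_spec("svm_rbf", cv_folds = 4, seed = 3))
  pred <- classify_raster(m, scene$stack)
  expect_gte(raster_agreement(pred, scene$labels), 0.99)
})

test_that("an all-invalid stack maps to all nodata", {
  stack <- array(0, c(8, 8, 7),
                 dimnames = list(NULL, NULL, band_names))
  train <- generate_samples(small_scenario(n_per_class = 15, seed = 4))
  m <- fit_classifier(build_feature_matrix(train),
                      model_spec("svm_rbf", cv_folds = 3, seed = 1))
  pred <- classify_raster(m, stack)
  expect_true(all(pred$grid == pred$nodata))
})

test_that("raster classification reproduces tabular predictions exactly", {
  df <- generate_samples(small_scenario(n_per_class = 30, seed = 6))
  fm <- build_feature_matrix(df)
  m <- fit_classifier(fm, model_spec("rf",
                                     grid = data.frame(n_trees = 100,
                                                       min_leaf = 1),
                                     cv_folds = 3, seed = 5))
  stack <- stack_from_table(df, 12, 10)
  map <- classify_raster(m, stack)
  tab_pred <- predict(m, fm)
  codes <- map$legend[as.character(tab_pred)]
  expect_equal(as.vector(map$grid), unname(codes))
})

test_that("seeded synthetic scene maps with high reference agreement", {
  sc <- synthetic_scenario(seed = 1)
  df <- generate_samples(sc)
  fm <- build_feature_matrix(df)
  sp <- spxy_split(fm, 0.7)
  m <- fit_classifier(subset_rows(fm, sp$train_indices),
                      model_spec("svm_rbf", cv_folds = 5, seed = 5))
  scene <- generate_raster(sc, 64)
  pred <- classify_raster(m, scene$stack)
  expect_gte(raster_agreement(pred, scene$labels), 0.9)
  smoothed <- mode_filter_3x3(pred)
  expect_gte(raster_agreement(smoothed, scene$labels),
             raster_agreement(pred, scene$labels))
})
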