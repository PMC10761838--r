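test_that("training spectra extraction matches crown footprints", {
  wl <- default_wavelengths()[1:5]
  cube <- spectral_cube(array(0.4, c(20, 20, 5)), wl,
                        geo = list(px_m = 4))
  crowns <- data.frame(species_id = "spA", row = 10, col = 10,
                       diameter_m = 12, crown_id = 1L) # radius 1.5 px
  tr <- extract_training_spectra(cube, crowns)
  expect_equal(nrow(tr$spectra), 9) # 3 x 3 disc at radius 1.5
  expect_true(all(tr$labels == "spA"))

  # crown over masked pixels is skipped with a warning
  mask <- matrix(TRUE, 20, 20); mask[8:12, 8:12] <- FALSE
  crowns2 <- rbind(crowns, data.frame(species_id = "spB", row = 3, col = 3,
                                      diameter_m = 8, crown_id = 2L))
  expect_warning(tr2 <- extract_training_spectra(cube, crowns2, mask),
                 "skipped")
  expect_true(all(tr2$labels == "spB"))
  expect_error(extract_training_spectra(cube, crowns, mask), "no crowns")
})

test_that("extracted crown spectra match generator signatures", {
  scene <- tiny_scene()
  pool <- tiny_pool()
  cb <- select_classification_bands(select_usable_bands(scene$cube), scene$cube)
  set.seed(3)
  cr <- scene$crowns[sample.int(nrow(scene$crowns), 400), ]
  tr <- suppressWarnings(
    extract_training_spectra(scene$cube, cr, mask = scene$truth > 0,
                             bands = cb, core_fraction = 0.6))
  pure <- pool$species$species_id[scene$truth[tr$coords]] == tr$labels
  for (sp in unique(tr$labels[pure])) {
    m <- colMeans(tr$spectra[pure & tr$labels == sp, , drop = FALSE])
    sig <- pool$signatures[sp, cb$indices]
    # cosine similarity ignores the multiplicative brightness field
    cs <- sum(m * sig) / sqrt(sum(m^2) * sum(sig^2))
    expect_gt(cs, 0.99)
  }
})

test_that("train/test split is stratified, disjoint and deterministic", {
  labels <- rep(c("a", "b"), c(100, 40))
  tags <- split_train_test(labels, 0.75, seed = 5)
  expect_equal(sum(tags == "train" & labels == "a"), 75)
  expect_equal(sum(tags == "test" & labels == "a"), 25)
  expect_equal(sum(tags == "train" & labels == "b"), 30)
  expect_true(all(tags %in% c("train", "test")))
  expect_identical(tags, split_train_test(labels, 0.75, seed = 5))
  expect_error(split_train_test(c("a", "a", "b"), seed = 1), "'b'")
})

test_that("SMOTE balances classes by convex interpolation", {
  set.seed(6)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(20, 5), 10, 2))
  y <- rep(c("A", "B"), c(100, 10))
  bal <- smote_balance(X, y, k_neighbors = 5, seed = 1)
  expect_equal(as.vector(table(bal$y)), c(100, 100))
  # majority class untouched, original rows preserved
  expect_identical(bal$X[1:110, ], X)
  expect_setequal(unique(bal$y), c("A", "B"))
  # synthetic B samples lie inside the bounding box of original B samples
  synth <- bal$X[bal$synthetic, ]
  rng <- apply(X[y == "B", ], 2, range)
  expect_true(all(synth[, 1] >= rng[1, 1] & synth[, 1] <= rng[2, 1]))
  expect_true(all(synth[, 2] >= rng[1, 2] & synth[, 2] <= rng[2, 2]))
  # balanced input returned unchanged
  bal2 <- smote_balance(X[1:20, ], rep(c("A", "B"), each = 10), seed = 1)
  expect_identical(bal2$X, X[1:20, ])
  # k reduced with warning for very small classes
  expect_warning(smote_balance(rbind(X, X[1:3, ]), c(y, rep("C", 3)),
                               k_neighbors = 5, seed = 1), "reduced")
})

test_that("random forest separates a linearly separable toy exactly", {
  set.seed(7)
  X <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
             matrix(rnorm(100, 4, 0.3), 50, 2),
             matrix(rnorm(100, 8, 0.3), 50, 2))
  y <- rep(c("a", "b", "c"), each = 50)
  rf <- train_rf(X, y, mtry_grid = c(1, 2), ntree_grid = c(50), seed = 1)
  expect_equal(rf$oob_error, 0)
  expect_identical(predict(rf, X), y)
  # determinism under seed
  rf2 <- train_rf(X, y, mtry_grid = c(1, 2), ntree_grid = c(50), seed = 1)
  expect_identical(rf$mtry, rf2$mtry)
  expect_identical(predict(rf, X), predict(rf2, X))
  expect_error(train_rf(X, y, mtry_grid = integer(0)), "empty")
  expect_error(predict(rf, X[, 1, drop = FALSE]), "dimension mismatch")
})

test_that("map prediction handles fully masked cubes and reports area", {
  scene <- tiny_scene()
  res <- suppressWarnings(classify_scene(scene, ndvi_threshold = 0.4,
                                         n_train_crowns = 400,
                                         ntree_grid = c(60L), seed = 9))
  expect_s3_class(res$map, "classification_map")
  expect_gte(res$report$overall_accuracy, 76.92) # floor from real-data range
  expect_gte(res$report$kappa, 0.76)
  # all forest pixels labelled, masked pixels carry 0
  mask <- compute_ndvi_mask(scene$cube, 0.4)
  expect_true(all(res$map$labels[mask] > 0))
  expect_true(all(res$map$labels[!mask] == 0))
  # fully masked cube -> no labels
  empty <- predict_map(res$chain, scene$cube,
                       matrix(FALSE, nrow(scene$truth), ncol(scene$truth)))
  expect_equal(sum(empty$labels), 0)
  # area accounting: 16 m2 per pixel
  area <- species_area_km2(res$map)
  expect_equal(sum(area), sum(res$map$labels > 0) * 16 / 1e6)
})

test_that("accuracy metrics match hand-computed confusion matrices", {
  perfect <- assess_accuracy(rep(c("x", "y"), each = 50),
                             rep(c("x", "y"), each = 50))
  expect_equal(perfect$overall_accuracy, 100)
  expect_equal(perfect$kappa, 1)

  pred <- c(rep("x", 40), rep("y", 10), rep("x", 10), rep("y", 40))
  ref <- rep(c("x", "y"), each = 50)
  r <- assess_accuracy(pred, ref)
  expect_equal(r$overall_accuracy, 80) # p_o = 0.8
  expect_equal(r$kappa, 0.6)           # p_e = 0.5
  expect_equal(unname(r$producers_accuracy), c(80, 80))
  expect_equal(unname(r$users_accuracy), c(80, 80))
  # scalars always recomputable from the stored confusion matrix
  expect_equal(r$overall_accuracy, 100 * sum(diag(r$confusion)) / sum(r$confusion))

  # all-one-class predictions on balanced reference -> kappa 0
  r0 <- assess_accuracy(rep("x", 100), rep(c("x", "y"), each = 50))
  expect_equal(r0$kappa, 0)
  expect_error(assess_accuracy(character(0), character(0)), "non-empty")
})

test_that("abundant designation pools the tail into others", {
  crowns <- data.frame(species_id = rep(c("a", "b", "c", "d"),
                                        c(60, 25, 10, 5)))
  ab <- designate_abundant(crowns, coverage = 0.8)
  expect_equal(ab, c("a", "b"))
  expect_equal(designate_abundant(crowns, coverage = 1),
               c("a", "b", "c", "d"))
})
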