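make_cube <- function(vals, wl) {
  spectral_cube(array(vals, c(1, 1, length(wl))), wl)
}

test_that("usable-band selection is interval-driven", {
  cube <- spectral_cube(array(0.5, c(2, 2, 425)), default_wavelengths())
  bs <- select_usable_bands(cube)
  expect_equal(length(bs$indices), 368) # 425 - (7 + 16 + 34) on the ideal grid
  wl <- cube$wavelengths[bs$indices]
  expect_true(all(wl >= 411))
  expect_false(any(wl >= 1348 & wl <= 1428))
  expect_false(any(wl >= 1778 & wl <= 1949))
  # single bands
  expect_equal(select_usable_bands(make_cube(0.5, 2000))$indices, 1L)
  expect_error(select_usable_bands(make_cube(0.5, 1400)), "no usable bands")
})

test_that("classification-band selection keeps the four regions", {
  cube <- spectral_cube(array(0.5, c(2, 2, 425)), default_wavelengths())
  cb <- select_classification_bands(select_usable_bands(cube), cube)
  expect_equal(length(cb$indices), 224) # 21 + 101 + 51 + 51 on the ideal grid
  wl <- cube$wavelengths[cb$indices]
  expect_true(550 %in% wl)  # closed interval endpoint included
  expect_false(700 %in% wl) # between regions -> excluded
  expect_false(any(wl > 650 & wl < 750))
})

test_that("brightness normalization is unit-norm, scale-invariant, idempotent", {
  expect_equal(as.vector(brightness_normalize(matrix(c(3, 4), 1))), c(0.6, 0.8))
  set.seed(1)
  v <- matrix(runif(226, 0.01, 0.9), 1)
  b1 <- brightness_normalize(v)
  b2 <- brightness_normalize(2 * v)
  expect_equal(b1, b2, tolerance = 1e-12)
  expect_equal(sqrt(sum(b1^2)), 1, tolerance = 1e-12)
  expect_equal(brightness_normalize(b1), b1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(out <- brightness_normalize(rbind(v, 0)), "all-zero")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "dropped_rows"), 2L)
})

test_that("MNF satisfies its rank-1, inversion and whitening contracts", {
  set.seed(2)
  p <- 12; n <- 40 * 40
  coords <- as.matrix(expand.grid(row = 1:40, col = 1:40))
  # rank-1 noise-free signal (smooth over the grid so shift diffs ~ 0)
  base <- outer(sin(coords[, 1] / 6) + cos(coords[, 2] / 9), runif(p, 0.5, 1))
  m1 <- suppressMessages(fit_mnf(base, coords))
  expect_gt(m1$eigenvalues[1] / sum(m1$eigenvalues), 0.999)

  X <- base + matrix(rnorm(n * p, 0, 0.05), n, p)
  m2 <- fit_mnf(X, coords)
  expect_true(all(diff(m2$eigenvalues) <= 1e-8))
  rec <- mnf_inverse(m2, mnf_transform(m2, X))
  expect_lt(max(abs(rec - X)), 1e-8)
  # scores are empirically uncorrelated
  cc <- cor(mnf_transform(m2, X))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)

  # pure white noise: eigenvalues concentrate around 1
  W <- matrix(rnorm(10000 * 6), 10000, 6)
  cw <- as.matrix(expand.grid(row = 1:100, col = 1:100))
  m3 <- fit_mnf(W, cw)
  expect_true(all(abs(m3$eigenvalues - 1) < 0.15))
})

test_that("MNF within-group noise pairs and errors behave", {
  coords <- as.matrix(expand.grid(row = 1:30, col = 1:30))
  X <- matrix(rnorm(900 * 4), 900, 4)
  groups <- coords[, 1] # same row = same group -> horizontal pairs survive
  m <- fit_mnf(X, coords, groups = groups)
  expect_s3_class(m, "mnf_model")
  expect_error(fit_mnf(X[1:3, ], coords[1:3, ]), "band-count")
})

test_that("NDVI mask applies thresholds and handles zero denominators", {
  wl <- c(650, 860)
  mk <- function(red, nir) {
    spectral_cube(array(c(red, nir), c(1, 1, 2)), wl)
  }
  expect_true(compute_ndvi_mask(mk(0.1, 0.5), 0.4)[1, 1])  # NDVI = 0.667
  # NDVI = 0.35 masked at 0.4
  r <- (1 - 0.35) / (1 + 0.35) * 0.5
  expect_false(compute_ndvi_mask(mk(r, 0.5), 0.4)[1, 1])
  # NDVI = 0.55 masked at 0.6
  r <- (1 - 0.55) / (1 + 0.55) * 0.5
  expect_false(compute_ndvi_mask(mk(r, 0.5), 0.6)[1, 1])
  expect_false(compute_ndvi_mask(mk(0, 0), 0.4)[1, 1])
})

test_that("canopy indices match hand arithmetic", {
  wl <- c(531, 645, 650, 860, 1240)
  refl <- c(0.05, 0.03, 0.1, 0.4, 0.3)
  cube <- spectral_cube(array(refl, c(1, 1, 5)), wl)
  idx <- compute_indices(cube, par = 1)
  expect_equal(idx$CCI[1, 1], 0.25)
  ndvi <- (0.4 - 0.1) / (0.4 + 0.1)
  expect_equal(idx$NDVI[1, 1], ndvi)
  expect_equal(idx$NIRv[1, 1], ndvi * 0.4)
  expect_equal(idx$NIRvP[1, 1], ndvi * 0.4)
  expect_equal(idx$NDWI[1, 1], (0.4 - 0.3) / (0.4 + 0.3))
  expect_equal(unname(attr(idx, "wavelengths_used")["NIR"]), 860)
  # PAR scaling
  idx2 <- compute_indices(cube, par = 2)
  expect_equal(idx2$NIRvP[1, 1], 2 * idx$NIRvP[1, 1])
  # masked pixels propagate
  cube$mask[1, 1] <- FALSE
  expect_true(is.na(compute_indices(cube)$CCI[1, 1]))
})

test_that("NIRv example with unit PAR", {
  wl <- c(650, 860)
  cube <- spectral_cube(array(c(0.4 / 9, 0.4), c(1, 1, 2)), wl)
  idx <- compute_indices(cube, par = 1)
  expect_equal(idx$NDVI[1, 1], 0.8)
  expect_equal(idx$NIRv[1, 1], 0.32)
  expect_equal(idx$NIRvP[1, 1], 0.32)
})

test_that("spectral cube validates construction", {
  expect_error(spectral_cube(array(0, c(2, 2, 3)), c(1, 2)), "band count")
  expect_error(spectral_cube(array(0, c(2, 2, 2)), c(2, 1)), "increasing")
})
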