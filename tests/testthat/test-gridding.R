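test_that("grid overlay tiles the map without gaps or overlap", {
  map <- toy_map(250, 250) # 2 x 2 cells of 125 px
  g <- overlay_grid(map, 0.005)
  expect_equal(nrow(g), 4)
  expect_true(all(g$row1 - g$row0 + 1 == 125))
  # partition: pixel memberships cover each pixel exactly once
  cover <- matrix(0L, 250, 250)
  for (i in seq_len(nrow(g)))
    cover[g$row0[i]:g$row1[i], g$col0[i]:g$col1[i]] <-
      cover[g$row0[i]:g$row1[i], g$col0[i]:g$col1[i]] + 1L
  expect_true(all(cover == 1L))
  # map smaller than one cell -> a single clipped cell
  small <- toy_map(60, 60)
  g2 <- overlay_grid(small, 0.005)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$row1, 60)
  expect_error(overlay_grid(list(labels = matrix(0, 2, 2), geo = NULL)),
               "georeferenced")
})

test_that("plot extraction enforces the forest-fraction rule", {
  map <- toy_map(250, 250, forest_frac = 1)
  g <- overlay_grid(map)
  plots <- extract_plots(map, g[1, ], seed = 3)
  expect_length(plots, 3)
  expect_true(all(vapply(plots, `[[`, 0, "forest_fraction") == 1))
  expect_identical(plots, extract_plots(map, g[1, ], seed = 3))

  # a 60% forest map cannot yield qualifying plots at the 70% rule
  sparse <- toy_map(250, 250, forest_frac = 0.6, seed = 11)
  expect_true(mean(sparse$labels > 0) < 0.65)
  plots2 <- extract_plots(sparse, overlay_grid(sparse)[1, ],
                          min_forest_fraction = 0.70, max_tries = 40, seed = 4)
  ff <- vapply(plots2, `[[`, 0, "forest_fraction")
  expect_true(all(ff >= 0.70)) # any accepted plot met the rule
  # plots do not overlap
  if (length(plots) > 1) {
    pos <- t(vapply(plots, function(p) c(p$row0, p$col0), c(0, 0)))
    d <- as.matrix(dist(pos, method = "manhattan"))
    expect_true(all(d[upper.tri(d)] > 0))
  }
})

test_that("pixel-to-abundance extrapolation follows the crown-area rule", {
  spread <- c(spA = 8, spB = 10)
  counts <- c(spA = 100, spB = 0)
  ab <- pixels_to_abundance(counts, spread)
  expect_equal(unname(ab["spA"]), 32L) # round(1600 / 50.265)
  expect_equal(unname(ab["spB"]), 0L)
  # minimum-presence rule
  ab2 <- pixels_to_abundance(c(spB = 1), c(spB = 10))
  expect_equal(unname(ab2["spB"]), 1L)
  # homogeneity: doubling pixels doubles abundance (+- 1 rounding)
  ab3 <- pixels_to_abundance(c(spA = 200), spread)
  expect_lte(abs(ab3[["spA"]] - 2 * ab[["spA"]]), 1)
  expect_error(pixels_to_abundance(c(spC = 5), spread), "spC")
})

test_that("cell aggregation conserves totals", {
  plots <- list(c(A = 2L, B = 0L), c(A = 1L, B = 3L), c(A = 0L, B = 0L))
  agg <- aggregate_cell_abundance(plots)
  expect_equal(agg, c(A = 3L, B = 3L))
  expect_equal(aggregate_cell_abundance(plots[2]), plots[[2]])
  expect_equal(sum(agg), sum(unlist(plots)))
  expect_error(aggregate_cell_abundance(list()), "at least one")
})

test_that("covariate attachment is nearest-neighbour and complete", {
  grids <- tiny_grids()
  cells <- data.frame(cell_id = c("a", "b"),
                      lon = grids$origin[1] + c(0.5, 1.5) * grids$cell_size,
                      lat = grids$origin[2] - c(0.5, 0.5) * grids$cell_size)
  out <- attach_covariates(cells, grids)
  expect_equal(out$CC1, c(grids$covariates$CC1[1, 1], grids$covariates$CC1[1, 2]))
  expect_false(anyNA(out[, c(paste0("CC", 1:6), "elevation", "soil")]))
  # constant raster -> identical values
  g2 <- generate_climate_grids(n_pas = 1, cells_per_pa = c(2, 2),
                               noise_sd_frac = 0, seed = 1)
  cells2 <- data.frame(cell_id = c("a", "b"),
                       lon = g2$origin[1] + c(0.5, 1.5) * g2$cell_size,
                       lat = g2$origin[2] - c(0.5, 0.5) * g2$cell_size)
  out2 <- attach_covariates(cells2, g2)
  expect_equal(out2$CC1[1], out2$CC1[2])
  far <- data.frame(cell_id = "x", lon = 999, lat = 0)
  expect_error(attach_covariates(far, grids), "x")
})

test_that("abundance matrix construction is consistent end to end", {
  map <- toy_map(250, 250, n_classes = 4, forest_frac = 0.95)
  grids <- generate_climate_grids(n_pas = 1, cells_per_pa = c(2, 2),
                                  seed = 7, origin = c(73, 21))
  spread <- setNames(runif(4, 6, 12), map$legend)
  am <- build_abundance_matrix(map, grids, spread, seed = 5)
  expect_s3_class(am, "abundance_matrix")
  expect_true(all(am$counts >= 0))
  expect_true(all(rowSums(am$counts) > 0))
  expect_equal(nrow(am$counts), nrow(am$cells))
  # relative abundance rows sum to 1
  expect_equal(unname(rowSums(relative_abundance(am))),
               rep(1, nrow(am$counts)))
  # plot counts aggregate to cell counts
  cell_of <- sub("_p[0-9]+$", "", rownames(am$plot_counts))
  agg <- rowsum(am$plot_counts, cell_of)
  expect_equal(agg[rownames(am$counts), ], am$counts)
})

test_that("cell relative abundance tracks the niche model on a scene", {
  scene <- tiny_scene()
  pool <- tiny_pool()
  # truth map as an oracle classification, bypassing the classifier
  map <- structure(list(labels = scene$truth,
                        legend = pool$species$species_id,
                        geo = scene$cube$geo),
                   class = "classification_map")
  spread <- setNames(pool$species$mean_canopy_spread, pool$species$species_id)
  am <- build_abundance_matrix(map, tiny_grids(), spread, seed = 9)
  rel <- colSums(am$counts)[names(scene$expected_freq)]
  rel[is.na(rel)] <- 0
  expect_gte(suppressWarnings(
    cor(rel, scene$expected_freq, method = "spearman")), 0.8)
})
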