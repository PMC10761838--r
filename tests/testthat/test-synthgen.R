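test_that("species pool encodes the requested structure", {
  pool <- generate_species_pool(53, 4, 0.51, seed = 7)
  expect_equal(pool$n_pa_specific, 27)
  expect_equal(sum(rowSums(pool$membership) == 1), 27)
  expect_true(all(rowSums(pool$membership) >= 1))
  expect_equal(nrow(pool$signatures), 53)
  expect_true(all(pool$signatures >= 0 & pool$signatures <= 1))
  # evergreen species have positive rainfall niche coefficients
  expect_true(all(pool$niche[pool$species$phenology == 1, "CC1"] > 0))
  expect_true(all(pool$niche[pool$species$phenology == 0, "CC1"] < 0))
})

test_that("degenerate single-species pool works", {
  pool <- generate_species_pool(1, 1, 0.0, seed = 3)
  expect_equal(nrow(pool$species), 1)
  expect_equal(pool$n_pa_specific, 0)
  expect_true(all(pool$membership))
})

test_that("pool generation is deterministic and validates arguments", {
  p1 <- generate_species_pool(20, 4, 0.5, seed = 1)
  p2 <- generate_species_pool(20, 4, 0.5, seed = 1)
  expect_identical(p1, p2)
  expect_error(generate_species_pool(0, 1, 0.5, seed = 1), "positive")
  expect_error(generate_species_pool(3, 4, 0.5, seed = 1), "n_species >= n_pas")
  expect_error(generate_species_pool(5, 2, 1.5, seed = 1), "0, 1")
})

test_that("DBH samples honour the truncation bounds", {
  pool <- tiny_pool()
  set.seed(9)
  d <- sample_dbh(pool, pool$species$species_id[1], 500)
  expect_true(all(d >= 0.04 & d <= 1.43))
})

test_that("climate grids reproduce the configured gradient", {
  g <- generate_climate_grids(seed = 5)
  pa_rain <- tapply(g$covariates$CC1, g$pa, mean)
  expect_true(all(diff(pa_rain) > 0)) # strictly increasing PA1 -> PA4
  expect_true(all(g$covariates$CC1 >= 1140.13 & g$covariates$CC1 <= 2757.60))
  expect_true(all(g$covariates$CC4 >= 24.93 & g$covariates$CC4 <= 28.08))
  expect_true(all(g$soil %in% 0:1))
  # zero-noise config equals the PA-level means exactly
  g0 <- generate_climate_grids(noise_sd_frac = 0, seed = 5)
  for (nm in names(g0$covariates))
    expect_equal(unname(g0$covariates[[nm]][1, ]),
                 g0$pa_means[[nm]][g0$pa[1, ]])
  expect_identical(generate_climate_grids(seed = 8),
                   generate_climate_grids(seed = 8))
  expect_error(generate_climate_grids(n_pas = 0), "degenerate")
})

test_that("single-species noise-free scene carries the exact signature", {
  pool <- generate_species_pool(1, 1, 0, seed = 11)
  grids <- generate_climate_grids(n_pas = 1, cells_per_pa = c(2, 2), seed = 11)
  scene <- generate_scene(pool, grids, "PA1", size = c(48, 48), noise_sd = 0,
                          brightness_range = c(1, 1), seed = 12)
  fidx <- which(scene$truth == 1)
  expect_gt(length(fidx), 0)
  flat <- matrix(scene$cube$reflectance, ncol = length(pool$wavelengths))
  expect_equal(flat[fidx[1], ], unname(pool$signatures[1, ]), tolerance = 1e-12)
  expect_equal(flat[fidx[length(fidx)], ], unname(pool$signatures[1, ]),
               tolerance = 1e-12)
})

test_that("realized crown frequencies track the niche model", {
  scene <- tiny_scene()
  tab <- table(factor(scene$crowns$species_id, names(scene$expected_freq)))
  expect_gte(suppressWarnings(
    cor(as.numeric(tab), scene$expected_freq, method = "spearman")), 0.8)
})

test_that("scene generation is deterministic and mass-conserving", {
  s1 <- generate_scene(tiny_pool(), tiny_grids(), "PA1", size = c(64, 64), seed = 21)
  s2 <- generate_scene(tiny_pool(), tiny_grids(), "PA1", size = c(64, 64), seed = 21)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$crowns, s2$crowns)
  # forest pixels are exactly the rasterized crown area
  expect_true(all(s1$truth[s1$truth > 0] %in%
                    which(tiny_pool()$membership[, "PA1"])))
  expect_error(generate_scene(tiny_pool(), tiny_grids(), "PA1", size = c(1, 1)),
               "smaller than one crown")
  expect_error(generate_scene(tiny_pool(), tiny_grids(), "PA9"), "identifier")
})

test_that("evergreen crown share increases with rainfall", {
  pool <- generate_species_pool(16, 4, 0.25, seed = 31)
  grids <- generate_climate_grids(cells_per_pa = c(2, 2), seed = 31)
  share <- vapply(grids$pa_ids, function(pa) {
    sc <- generate_scene(pool, grids, pa, size = c(64, 64), seed = 32)
    ph <- pool$species$phenology[sc$crowns$species]
    mean(ph == 1)
  }, 0)
  rain <- grids$pa_means$CC1
  expect_gt(coef(lm(share ~ rain))[2], 0)
})

test_that("field survey records follow the > 4 cm DBH protocol", {
  scene <- tiny_scene()
  sv <- generate_field_survey(scene, 40, seed = 41)
  expect_true(all(sv$records$dbh_m > 0.04))
  expect_identical(sv, generate_field_survey(scene, 40, seed = 41))
  expect_error(generate_field_survey(scene, 0, seed = 1), ">= 1")
  # quadrat over known crowns returns exactly those crowns (plus understory)
  cr <- scene$crowns
  q <- sv$quadrats[1, ]
  inside <- cr$row >= q$row0 & cr$row < q$row0 + 2 &
    cr$col >= q$col0 & cr$col < q$col0 + 2 & cr$dbh_m > 0.04
  canopy_recs <- sv$records[sv$records$quadrat_id == 1 &
                              sv$records$canopy_spread_m > 3, ]
  expect_equal(nrow(canopy_recs), sum(inside))
})

test_that("simulated plot presence is deterministic with sane richness", {
  pp1 <- simulate_plot_presence(tiny_pool(), tiny_grids(), seed = 51)
  pp2 <- simulate_plot_presence(tiny_pool(), tiny_grids(), seed = 51)
  expect_identical(pp1, pp2)
  expect_true(all(pp1$presence %in% 0:1))
  expect_true(all(pp1$meta$region %in% c("drier", "wetter")))
})
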