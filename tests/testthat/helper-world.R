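# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; no data files are read.
.world <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.world[[key]])) .world[[key]] <- force(expr)
  .world[[key]]
}

tiny_pool <- function() memo("tiny_pool",
  generate_species_pool(8, 2, 0.25, seed = 101))

tiny_grids <- function() memo("tiny_grids",
  generate_climate_grids(n_pas = 2, cells_per_pa = c(3, 3), seed = 102))

tiny_scene <- function() memo("tiny_scene",
  generate_scene(tiny_pool(), tiny_grids(), "PA1", size = c(96, 96), seed = 103))

# a synthetic classification map with known structure (no imagery involved)
toy_map <- function(nr = 250, nc = 250, n_classes = 5, forest_frac = 0.9,
                    seed = 104) {
  set.seed(seed)
  labels <- matrix(sample(0:n_classes, nr * nc, replace = TRUE,
                          prob = c(1 - forest_frac,
                                   rep(forest_frac / n_classes, n_classes))),
                   nr, nc)
  structure(list(labels = labels,
                 legend = sprintf("sp%03d", seq_len(n_classes)),
                 geo = list(origin_lon = 73, origin_lat = 21,
                            px_deg = 0.005 / 125, px_m = 4)),
            class = "classification_map")
}
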