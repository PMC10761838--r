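test_that("central-95% trim keeps the stated share", {
  set.seed(16)
  x <- rnorm(1000)
  expect_equal(length(trim_central(x)), 950)
  expect_equal(trim_central(c(5, 5, 5)), c(5, 5, 5))
})

test_that("trait table applies the aggregation rules", {
  records <- data.frame(
    species_id = c(rep("spA", 4), rep("spB", 3)),
    pa = c(rep("PA1", 4), rep("PA1", 3)),
    dbh_m = c(0.2, 0.5, 0.9, 1.1, 0.3, 0.4, 0.6))
  pixels <- data.frame(
    species_id = c("spA", "spA", "spB", "spB"),
    pa = c("PA1", "PA2", "PA1", "PA1"),
    CCI = c(0.4, 0.6, 0.2, 0.2), NIRvP = c(0.3, 0.5, 0.1, 0.1),
    NDWI = c(0.1, 0.3, 0.05, 0.05))
  info <- data.frame(species_id = c("spA", "spB"),
                     wood_density = c(0.6, 0.7), phenology = c(1, 0))
  tt <- build_trait_table(records, pixels, info)
  # max DBH: mean of the two largest records
  expect_equal(tt$max_dbh[tt$species_id == "spA"], 1.0)
  # species in two PAs: mean of per-PA means
  expect_equal(tt$CCI[tt$species_id == "spA"], 0.5)
  expect_equal(tt$NIRvP[tt$species_id == "spA"], 0.4)
  expect_equal(tt$CCI[tt$species_id == "spB"], 0.2)
  expect_error(build_trait_table(records, pixels, info[1, ]), "spB")
})

test_that("CWM is a convex combination of trait values", {
  expect_equal(cwm(c(a = 2, b = 2), c(a = 0.3, b = 0.7)), 0.5)
  expect_equal(cwm(c(a = 5), c(a = 0.42)), 0.42)
  # 3:1 evergreen:deciduous phenology share
  expect_equal(cwm(c(a = 3, b = 1), c(a = 1, b = 0)), 0.75)
  # invariant to abundance rescaling; bounded by trait extrema
  set.seed(17)
  ab <- setNames(runif(5, 1, 10), letters[1:5])
  tr <- setNames(runif(5), letters[1:5])
  expect_equal(cwm(ab, tr), cwm(10 * ab, tr))
  expect_true(cwm(ab, tr) >= min(tr) && cwm(ab, tr) <= max(tr))
  expect_warning(out <- cwm(c(a = 0), c(a = 1)), "zero-total")
  expect_true(is.na(out))
  expect_error(cwm(c(a = 1, z = 1), c(a = 1)), "z")
})

test_that("FRic matches analytic hull volumes", {
  cube_pts <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(fric(cube_pts)$volume, 1, tolerance = 1e-9)
  expect_equal(sort(fric(cube_pts)$vertices), 1:8)
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(fric(tetra)$volume, 1 / 6, tolerance = 1e-9)
  # coplanar -> degenerate
  flat <- cbind(runif(6), runif(6), 1)
  h <- fric(flat)
  expect_true(h$degenerate)
  expect_equal(h$volume, 0)
  # duplicates collapse silently
  expect_equal(fric(rbind(tetra, tetra))$volume, 1 / 6, tolerance = 1e-9)
})

test_that("FRic is monotone under species addition and order-invariant", {
  set.seed(18)
  pts <- matrix(rnorm(30), 10, 3)
  v_all <- fric(pts)$volume
  for (drop_i in c(1, 5, 10))
    expect_lte(fric(pts[-drop_i, ])$volume, v_all + 1e-12)
  perm <- sample(10)
  expect_equal(fric(pts[perm, ])$volume, v_all, tolerance = 1e-9)
})

test_that("FDiv matches its closed form and a stepwise oracle", {
  # all species equidistant from the hull-vertex centroid -> FDiv = 1
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(fdiv(oct, c(5, 1, 3, 2, 8, 1))$fdiv, 1, tolerance = 1e-12)

  # 5-species fixture: vertex-heavy vs interior-heavy weighting
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(0.25, 0.25, 0.25))
  fdiv_oracle <- function(traits, ab) { # independent stepwise implementation
    hull <- fric(traits)
    G <- colMeans(traits[hull$vertices, , drop = FALSE])
    d <- apply(traits, 1, function(r) sqrt(sum((r - G)^2)))
    p <- ab / sum(ab)
    dbar <- mean(d)
    (sum(p * (d - dbar)) + dbar) / (sum(p * abs(d - dbar)) + dbar)
  }
  ab_vertex <- c(10, 10, 10, 10, 1)
  ab_inner <- c(1, 1, 1, 1, 40)
  expect_gt(fdiv(pts, ab_vertex)$fdiv, fdiv(pts, ab_inner)$fdiv)
  for (ab in list(ab_vertex, ab_inner, rep(1, 5)))
    expect_equal(fdiv(pts, ab)$fdiv, fdiv_oracle(pts, ab), tolerance = 1e-9)

  # zero-abundance species are excluded upstream: adding an absent species
  # to the community matrix leaves the per-community metrics unchanged
  traits5 <- pts
  rownames(traits5) <- paste0("sp", 1:5)
  counts4 <- matrix(c(2, 3, 4, 5), 1, dimnames = list("c", paste0("sp", 1:4)))
  counts5 <- cbind(counts4, sp5 = 0)
  fd4 <- compute_fd(counts4, traits5[1:4, ], standardize = FALSE)
  fd5 <- compute_fd(counts5, traits5, standardize = FALSE)
  expect_equal(fd5$fric, fd4$fric, tolerance = 1e-9)
  expect_equal(fd5$fdiv, fd4$fdiv, tolerance = 1e-9)
  expect_true(fdiv(cbind(1:5, 1, 1), 1:5)$degenerate)
})

test_that("per-community FD and group summaries behave", {
  set.seed(19)
  traits <- matrix(rnorm(24), 8, 3,
                   dimnames = list(paste0("sp", 1:8), c("t1", "t2", "t3")))
  counts <- rbind(c1 = c(2, 3, 1, 4, 0, 0, 0, 1),
                  c2 = c(0, 0, 2, 2, 3, 1, 2, 0),
                  c3 = c(1, 1, 0, 0, 0, 0, 0, 0)) # < 4 species -> degenerate
  colnames(counts) <- rownames(traits)
  fd <- compute_fd(counts, traits)
  expect_false(fd$degenerate[1] || fd$degenerate[2])
  expect_true(fd$degenerate[3])
  expect_true(all(fd$fdiv[1:2] > 0 & fd$fdiv[1:2] <= 1))
  s <- suppressWarnings(summarize_fd(fd, grouping = c("g1", "g1", "g2")))
  expect_equal(s$mean_fric[s$group == "g1"], mean(fd$fric[1:2]))
  expect_equal(s$n_degenerate[s$group == "g2"], 1)
  expect_warning(summarize_fd(fd[3, ], "g"), "no defined")
  # identical cells -> mean equals the common value
  s2 <- summarize_fd(fd[c(1, 1), ], c("g", "g"))
  expect_equal(s2$mean_fric, fd$fric[1])
})
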