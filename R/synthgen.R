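#' Ideal 5-nm wavelength grid
#'
#' 425 band centres from 380 nm at a 5 nm pitch (to 2500 nm), the idealized
#' counterpart of an airborne imaging spectrometer covering 380-2510 nm.
#' @export
default_wavelengths <- function() seq(380, by = 5, length.out = 425)

#' Smooth base vegetation reflectance spectrum
#'
#' Green peak, chlorophyll red absorption, red edge to a NIR plateau,
#' liquid-water absorption dips and a SWIR decline. Species signatures are
#' this base plus species-specific Gaussian bumps.
#' @param wl wavelengths (nm)
#' @return reflectance vector in \[0, 1\]
#' @export
base_vegetation_spectrum <- function(wl) {
  r <- 0.03 +
    0.07 * exp(-(wl - 550)^2 / (2 * 40^2)) +            # green peak
    0.45 / (1 + exp(-(wl - 710) / 18)) -                # red edge -> NIR plateau
    0.22 / (1 + exp(-(wl - 1380) / 160)) -              # SWIR decline
    0.16 * exp(-(wl - 1450)^2 / (2 * 45^2)) -           # water absorption
    0.15 * exp(-(wl - 1940)^2 / (2 * 55^2)) -
    0.06 * exp(-(wl - 1200)^2 / (2 * 35^2))
  pmin(pmax(r, 0.01), 0.95)
}

# classification windows where species bumps are placed
.class_windows <- rbind(c(550, 650), c(750, 1250), c(1500, 1750), c(2000, 2250))

.species_signature <- function(wl, base) {
  sig <- base
  for (i in seq_len(nrow(.class_windows))) {
    for (b in 1:2) {
      centre <- stats::runif(1, .class_windows[i, 1], .class_windows[i, 2])
      width <- stats::runif(1, 15, 45)
      amp <- stats::rnorm(1, 0, 0.04)
      sig <- sig + amp * exp(-(wl - centre)^2 / (2 * width^2))
    }
  }
  pmin(pmax(sig, 0.02), 0.95)
}

.min_pairwise_angle <- function(S) {
  U <- S / sqrt(rowSums(S^2))
  cc <- tcrossprod(U)
  diag(cc) <- -1
  acos(pmin(pmax(max(cc), -1), 1)) * 180 / pi
}

#' Generate a synthetic species pool
#'
#' Builds `n_species` tree species spread over `n_pas` protected areas (PAs):
#' a configurable fraction is PA-specific, the rest occur in at least two
#' PAs. Each species carries a phenology class (evergreen/deciduous), wood
#' density, mean canopy spread, a truncated log-normal DBH distribution on
#' \[0.04, 1.43\] m, a canopy reflectance signature, and niche coefficients
#' linking log-abundance to climate covariates. Evergreen species get
#' positive rainfall coefficients and deciduous species negative ones, so the
#' generated landscape encodes the evergreen-share-increases-with-rainfall
#' gradient the downstream analysis looks for.
#'
#' @param n_species number of species (>= n_pas)
#' @param n_pas number of protected areas
#' @param pa_specific_fraction fraction of species restricted to a single PA
#' @param seed integer seed; the pool is a pure function of arguments + seed
#' @param wavelengths band grid for the signatures
#' @param min_separation_deg minimum pairwise spectral angle (degrees) between
#'   unit-norm signatures over the classification windows; offending
#'   signatures are redrawn (bounded attempts).
#' @return object of class `species_pool`
#' @export
generate_species_pool <- function(n_species, n_pas, pa_specific_fraction,
                                  seed, wavelengths = default_wavelengths(),
                                  min_separation_deg = 3) {
  if (n_species < 1 || n_pas < 1) stop("n_species and n_pas must be positive")
  if (n_species < n_pas) stop("need n_species >= n_pas")
  if (pa_specific_fraction < 0 || pa_specific_fraction > 1)
    stop("pa_specific_fraction must be in [0, 1]")
  set.seed(seed)

  ids <- sprintf("sp%03d", seq_len(n_species))
  pa_ids <- paste0("PA", seq_len(n_pas))
  n_specific <- if (n_pas > 1) round(pa_specific_fraction * n_species) else 0L

  membership <- matrix(FALSE, n_species, n_pas, dimnames = list(ids, pa_ids))
  specific <- seq_len(n_specific)
  for (i in specific) membership[i, sample.int(n_pas, 1)] <- TRUE
  for (i in setdiff(seq_len(n_species), specific)) {
    size <- if (n_pas >= 2) sample(2:n_pas, 1) else 1L
    membership[i, sample.int(n_pas, size)] <- TRUE
  }
  # every PA hosts at least one species
  for (p in which(colSums(membership) == 0)) membership[sample.int(n_species, 1), p] <- TRUE

  phenology <- stats::rbinom(n_species, 1, 0.5) # 1 = evergreen
  wood_density <- pmin(pmax(stats::rnorm(n_species, 0.60, 0.12), 0.25), 1.0)
  spread <- stats::runif(n_species, 6, 14)
  dbh_meanlog <- log(stats::runif(n_species, 0.15, 0.45))
  dbh_sdlog <- stats::runif(n_species, 0.4, 0.7)

  covars <- c(paste0("CC", 1:6), "elevation", "soil")
  niche <- matrix(stats::rnorm(n_species * length(covars), 0, 0.25),
                  n_species, length(covars), dimnames = list(ids, covars))
  rain_coef <- abs(stats::rnorm(n_species, 0.8, 0.3))
  niche[, "CC1"] <- ifelse(phenology == 1, rain_coef, -rain_coef)

  base <- base_vegetation_spectrum(wavelengths)
  in_windows <- rep(FALSE, length(wavelengths))
  for (i in seq_len(nrow(.class_windows)))
    in_windows <- in_windows | (wavelengths >= .class_windows[i, 1] &
                                  wavelengths <= .class_windows[i, 2])
  sig <- t(vapply(seq_len(n_species), function(i) .species_signature(wavelengths, base),
                  numeric(length(wavelengths))))
  if (n_species > 1) {
    for (attempt in 1:50) {
      U <- sig[, in_windows, drop = FALSE]
      U <- U / sqrt(rowSums(U^2))
      cc <- tcrossprod(U); diag(cc) <- -1
      worst <- which(apply(cc, 1, max) > cos(min_separation_deg * pi / 180))
      if (!length(worst)) break
      for (i in worst) sig[i, ] <- .species_signature(wavelengths, base)
    }
  }
  rownames(sig) <- ids

  structure(list(
    species = data.frame(species_id = ids, phenology = phenology,
                         wood_density = wood_density, mean_canopy_spread = spread,
                         dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
                         stringsAsFactors = FALSE),
    membership = membership, niche = niche, signatures = sig,
    wavelengths = wavelengths, dbh_bounds = c(0.04, 1.43),
    n_pa_specific = n_specific, pa_ids = pa_ids, seed = seed),
    class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("species_pool: %d species over %d PAs (%d PA-specific), %d bands\n",
              nrow(x$species), ncol(x$membership), x$n_pa_specific,
              length(x$wavelengths)))
  invisible(x)
}

#' Sample truncated log-normal DBH values for a species
#' @param pool species_pool
#' @param species_id species identifier
#' @param n number of draws
#' @export
sample_dbh <- function(pool, species_id, n) {
  i <- match(species_id, pool$species$species_id)
  lo <- stats::plnorm(pool$dbh_bounds[1], pool$species$dbh_meanlog[i], pool$species$dbh_sdlog[i])
  hi <- stats::plnorm(pool$dbh_bounds[2], pool$species$dbh_meanlog[i], pool$species$dbh_sdlog[i])
  stats::qlnorm(stats::runif(n, lo, hi), pool$species$dbh_meanlog[i], pool$species$dbh_sdlog[i])
}

#' Generate gridded climate covariates
#'
#' Lays out `n_pas` protected-area blocks west to east on a shared 0.005
#' degree grid and fills six climate covariates (decadal mean rainfall CC1,
#' wet-season rainfall CC2, rainfall seasonality CC3, decadal mean
#' temperature CC4, maximum monthly temperature CC5, temperature seasonality
#' CC6), elevation and a binary soil class (1 = Nitisols). Rainfall increases
#' and temperature decreases monotonically across PA blocks; each cell is the
#' PA-level mean plus seeded noise, so a zero-noise configuration reproduces
#' the PA means exactly.
#'
#' @param n_pas number of protected areas
#' @param cells_per_pa c(rows, cols) of 0.005 degree cells per PA block
#' @param rainfall_range decadal rainfall range (mm) spanned by the gradient
#' @param temp_range decadal temperature range (deg C)
#' @param noise_sd_frac per-cell noise sd as a fraction of each covariate's
#'   between-PA range (0 = exact PA means)
#' @param cell_size cell size in degrees
#' @param origin c(lon, lat) of the grid's north-west corner
#' @param seed integer seed
#' @return object of class `climate_grids`
#' @export
generate_climate_grids <- function(n_pas = 4, cells_per_pa = c(8, 8),
                                   rainfall_range = c(1140.13, 2757.60),
                                   temp_range = c(24.93, 28.08),
                                   noise_sd_frac = 0.1, cell_size = 0.005,
                                   origin = c(73, 21), seed = 1) {
  if (n_pas < 1 || any(cells_per_pa < 1)) stop("degenerate extent")
  set.seed(seed)
  nr <- cells_per_pa[1]; nc <- n_pas * cells_per_pa[2]
  pa <- matrix(rep(seq_len(n_pas), each = cells_per_pa[2]), nr, nc, byrow = TRUE)
  pa_ids <- paste0("PA", seq_len(n_pas))

  shrink <- function(rng, f = 0.08) rng + c(1, -1) * f * diff(rng)
  rain_means <- seq(shrink(rainfall_range)[1], shrink(rainfall_range)[2],
                    length.out = max(n_pas, 2))[seq_len(n_pas)]
  if (n_pas == 1) rain_means <- mean(rainfall_range)
  temp_means <- rev(seq(shrink(temp_range)[1], shrink(temp_range)[2],
                        length.out = max(n_pas, 2))[seq_len(n_pas)])
  if (n_pas == 1) temp_means <- mean(temp_range)
  rsc <- (rain_means - min(rainfall_range)) / diff(rainfall_range)
  elev_means <- stats::runif(n_pas, 150, 850)

  pa_means <- data.frame(
    pa = pa_ids,
    CC1 = rain_means,
    CC2 = 0.72 * rain_means,
    CC3 = 95 - 45 * rsc,
    CC4 = temp_means,
    CC5 = temp_means + 4.2,
    CC6 = 3.6 - 1.8 * rsc,
    elevation = elev_means,
    soil = as.integer(rain_means >= stats::median(rain_means)))

  field <- function(var, clip = NULL) {
    base <- matrix(pa_means[[var]][pa], nr, nc)
    sdv <- noise_sd_frac * max(diff(range(pa_means[[var]])), 1e-8)
    out <- base + matrix(stats::rnorm(nr * nc, 0, sdv), nr, nc)
    if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
    out
  }
  covariates <- list(
    CC1 = field("CC1", rainfall_range),
    CC2 = field("CC2"),
    CC3 = field("CC3"),
    CC4 = field("CC4", temp_range),
    CC5 = field("CC5"),
    CC6 = field("CC6"))
  elevation <- field("elevation")
  soil <- matrix(pa_means$soil[pa], nr, nc)

  structure(list(covariates = covariates, elevation = elevation, soil = soil,
                 pa = pa, pa_ids = pa_ids, cell_size = cell_size,
                 origin = origin, cells_per_pa = cells_per_pa,
                 pa_means = pa_means, seed = seed),
            class = "climate_grids")
}

#' @export
print.climate_grids <- function(x, ...) {
  cat(sprintf("climate_grids: %d x %d cells (%.3f deg), %d PAs; rainfall %.0f-%.0f mm\n",
              nrow(x$pa), ncol(x$pa), x$cell_size, length(x$pa_ids),
              min(x$covariates$CC1), max(x$covariates$CC1)))
  invisible(x)
}

#' All covariates of a climate grid as a cell table
#' @param grids climate_grids
#' @return data.frame with cell row/col, lon/lat, pa, CC1..CC6, elevation, soil
#' @export
climate_cell_table <- function(grids) {
  nr <- nrow(grids$pa); nc <- ncol(grids$pa)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  out <- data.frame(
    row = idx$row, col = idx$col,
    lon = grids$origin[1] + (idx$col - 0.5) * grids$cell_size,
    lat = grids$origin[2] - (idx$row - 0.5) * grids$cell_size,
    pa = grids$pa_ids[grids$pa[cbind(idx$row, idx$col)]])
  for (nm in names(grids$covariates))
    out[[nm]] <- grids$covariates[[nm]][cbind(idx$row, idx$col)]
  out$elevation <- grids$elevation[cbind(idx$row, idx$col)]
  out$soil <- grids$soil[cbind(idx$row, idx$col)]
  out
}

# pixels per 0.005 degree climate cell at 4 m resolution (0.005 deg == 500 m
# by construction in the synthetic world)
.px_per_cell <- function(cell_size, px_m) round(cell_size / 0.005 * 500 / px_m)

#' Generate a synthetic hyperspectral scene for one protected area
#'
#' Places tree crowns (circular discs at the species' canopy spread,
#' taller-tree-wins on overlap, matching a canopy-dominant airborne view)
#' with species sampled at probability proportional to
#' exp(niche coefficients x standardized local covariates). Forest pixels get
#' the species signature scaled by a smooth multiplicative brightness field
#' and additive sensor noise; the non-forest background is spectrally flat so
#' NDVI masking removes it.
#'
#' @param pool species_pool
#' @param grids climate_grids sharing the pool's PA identifiers
#' @param pa_id which PA to render (e.g. "PA1")
#' @param size c(rows, cols) in 4 m pixels
#' @param noise_sd additive reflectance noise sd
#' @param brightness_range c(min, max) of the multiplicative brightness field
#' @param cover target forest cover fraction
#' @param px_m pixel size in metres
#' @param seed integer seed
#' @return object of class `synthetic_scene` with fields cube, truth (integer
#'   matrix, 0 = non-forest, otherwise index into the pool), crowns registry,
#'   and `expected_freq` (the niche-model species frequencies the placement
#'   sampler used).
#' @export
generate_scene <- function(pool, grids, pa_id, size = c(256, 256),
                           noise_sd = 0.005, brightness_range = c(0.8, 1.2),
                           cover = 0.9, px_m = 4, seed = 1) {
  if (!pa_id %in% grids$pa_ids || !pa_id %in% colnames(pool$membership))
    stop("pool and grids must share PA identifier ", pa_id)
  pa_idx <- match(pa_id, grids$pa_ids)
  avail <- which(pool$membership[, pa_id])
  min_diam_px <- min(pool$species$mean_canopy_spread[avail]) / px_m
  if (any(size < min_diam_px)) stop("scene smaller than one crown")
  set.seed(seed)

  nr <- size[1]; nc <- size[2]
  ppc <- .px_per_cell(grids$cell_size, px_m)
  px_deg <- grids$cell_size / ppc
  block_col0 <- (pa_idx - 1) * grids$cells_per_pa[2] # 0-based cell col offset
  origin_lon <- grids$origin[1] + block_col0 * grids$cell_size
  origin_lat <- grids$origin[2]

  # per-climate-cell species sampling probabilities from the niche model
  tab <- climate_cell_table(grids)
  covars <- colnames(pool$niche)
  Z <- scale(as.matrix(tab[, covars]))
  Z[is.nan(Z)] <- 0
  eta <- pool$niche[avail, , drop = FALSE] %*% t(Z) # species x all cells
  W <- exp(eta - matrix(apply(eta, 2, max), nrow(eta), ncol(eta), byrow = TRUE))
  W <- sweep(W, 2, colSums(W), "/")

  cell_of <- function(r, c) { # scene pixel -> row index into tab
    cr <- pmin(pmax(ceiling(r / ppc), 1), nrow(grids$pa))
    cc <- pmin(pmax(block_col0 + ceiling(c / ppc), 1), ncol(grids$pa))
    (cc - 1L) * nrow(grids$pa) + cr
  }

  truth <- matrix(0L, nr, nc)
  height_map <- matrix(-Inf, nr, nc)
  crowns <- list()
  target_px <- cover * nr * nc
  mean_crown_px <- mean(pi * (pool$species$mean_canopy_spread[avail] / 2 / px_m)^2)
  n_placed <- 0L

  for (round_i in 1:25) {
    forest_px <- sum(truth > 0L)
    if (forest_px >= target_px) break
    n_new <- max(50L, ceiling((target_px - forest_px) / mean_crown_px))
    rs <- stats::runif(n_new, 0.5, nr + 0.5)
    cs <- stats::runif(n_new, 0.5, nc + 0.5)
    cells <- cell_of(rs, cs)
    sp <- integer(n_new)
    for (cell in unique(cells)) {
      sel <- which(cells == cell)
      sp[sel] <- avail[sample.int(length(avail), length(sel), replace = TRUE,
                                  prob = W[, cell])]
    }
    diam <- pmax(stats::rnorm(n_new, pool$species$mean_canopy_spread[sp],
                              0.12 * pool$species$mean_canopy_spread[sp]), 4.2)
    dbh <- numeric(n_new)
    for (s in unique(sp)) {
      sel <- which(sp == s)
      dbh[sel] <- sample_dbh(pool, pool$species$species_id[s], length(sel))
    }
    hgt <- 5 + 28 * (dbh / pool$dbh_bounds[2])^0.6 + stats::rnorm(n_new, 0, 1.5)
    crowns[[round_i]] <- data.frame(species = sp, row = rs, col = cs,
                                    diameter_m = diam, height_m = hgt, dbh_m = dbh)
    # rasterize, taller tree wins
    ord <- order(hgt)
    for (k in ord) {
      rad <- diam[k] / 2 / px_m
      r0 <- max(1L, floor(rs[k] - rad)); r1 <- min(nr, ceiling(rs[k] + rad))
      c0 <- max(1L, floor(cs[k] - rad)); c1 <- min(nc, ceiling(cs[k] + rad))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      inside <- outer((rr - rs[k])^2, (cc - cs[k])^2, "+") <= rad^2
      win_h <- height_map[rr, cc, drop = FALSE]
      put <- inside & (hgt[k] > win_h)
      if (any(put)) {
        win_t <- truth[rr, cc, drop = FALSE]
        win_t[put] <- sp[k]
        win_h[put] <- hgt[k]
        truth[rr, cc] <- win_t
        height_map[rr, cc] <- win_h
      }
    }
    n_placed <- n_placed + n_new
  }
  crowns <- do.call(rbind, crowns)
  crowns$crown_id <- seq_len(nrow(crowns))
  crowns$species_id <- pool$species$species_id[crowns$species]
  crowns$lon <- origin_lon + (crowns$col - 0.5) * px_deg
  crowns$lat <- origin_lat - (crowns$row - 0.5) * px_deg

  # smooth multiplicative brightness field
  if (diff(brightness_range) > 0) {
    ph <- stats::runif(4, 0, 2 * pi)
    bf <- outer(sin(2 * pi * (1:nr) / nr + ph[1]) + 0.6 * sin(4 * pi * (1:nr) / nr + ph[2]),
                sin(2 * pi * (1:nc) / nc + ph[3]) + 0.6 * sin(4 * pi * (1:nc) / nc + ph[4]),
                "+")
    bf <- (bf - min(bf)) / max(diff(range(bf)), 1e-12)
    bright <- brightness_range[1] + bf * diff(brightness_range)
  } else {
    bright <- matrix(brightness_range[1], nr, nc)
  }

  nb <- length(pool$wavelengths)
  bg <- 0.25 + 0.01 * sin(pool$wavelengths / 200) # flat background, NDVI ~ 0
  flat <- matrix(bg, nr * nc, nb, byrow = TRUE)
  fidx <- which(truth > 0L)
  if (length(fidx))
    flat[fidx, ] <- pool$signatures[truth[fidx], , drop = FALSE] * bright[fidx]
  if (noise_sd > 0)
    flat <- flat + stats::rnorm(length(flat), 0, noise_sd)
  flat[flat < 0] <- 0
  flat[flat > 1] <- 1

  cube <- spectral_cube(array(flat, c(nr, nc, nb)), pool$wavelengths,
                        geo = list(origin_lon = origin_lon, origin_lat = origin_lat,
                                   px_deg = px_deg, px_m = px_m))

  # niche-model expected frequencies over this PA's climate cells
  block_cells <- which(tab$pa == pa_id)
  ef <- rowMeans(W[, block_cells, drop = FALSE])
  expected_freq <- stats::setNames(ef, pool$species$species_id[avail])

  structure(list(cube = cube, truth = truth, crowns = crowns, pa_id = pa_id,
                 pool = pool, expected_freq = expected_freq, seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene %s: %d x %d px, %.1f%% forest, %d crowns, %d species\n",
              x$pa_id, nrow(x$truth), ncol(x$truth),
              100 * mean(x$truth > 0), nrow(x$crowns),
              length(unique(x$truth[x$truth > 0]))))
  invisible(x)
}

#' Simulate a field survey of 8 m x 8 m quadrats
#'
#' Quadrats (2 x 2 pixels at 4 m) are placed at seeded random positions.
#' Every registered crown whose centre falls inside a footprint is recorded
#' with its DBH, height and canopy spread; a small number of understory stems
#' is simulated per quadrat, and individuals with DBH <= 0.04 m are excluded
#' from the records (the field protocol records trees > 4 cm DBH only).
#'
#' @param scene synthetic_scene
#' @param n_quadrats number of quadrats (>= 1)
#' @param seed integer seed
#' @param quadrat_px quadrat edge in pixels (2 = 8 m at 4 m pixels)
#' @param understory_rate Poisson mean of simulated understory stems per quadrat
#' @return object of class `field_survey`: quadrat table + record table
#' @export
generate_field_survey <- function(scene, n_quadrats, seed, quadrat_px = 2L,
                                  understory_rate = 2) {
  if (n_quadrats < 1) stop("n_quadrats must be >= 1")
  set.seed(seed)
  nr <- nrow(scene$truth); nc <- ncol(scene$truth)
  if (nr < quadrat_px || nc < quadrat_px) stop("scene smaller than one quadrat")
  r0 <- sample.int(nr - quadrat_px + 1L, n_quadrats, replace = TRUE)
  c0 <- sample.int(nc - quadrat_px + 1L, n_quadrats, replace = TRUE)
  quadrats <- data.frame(quadrat_id = seq_len(n_quadrats), row0 = r0, col0 = c0)

  recs <- list()
  avail_sp <- scene$pool$species$species_id[which(scene$pool$membership[, scene$pa_id])]
  for (q in seq_len(n_quadrats)) {
    inside <- scene$crowns$row >= r0[q] & scene$crowns$row < r0[q] + quadrat_px &
      scene$crowns$col >= c0[q] & scene$crowns$col < c0[q] + quadrat_px
    cr <- scene$crowns[inside, , drop = FALSE]
    canopy <- data.frame(quadrat_id = rep(q, nrow(cr)), species_id = cr$species_id,
                         dbh_m = cr$dbh_m, height_m = cr$height_m,
                         canopy_spread_m = cr$diameter_m, stringsAsFactors = FALSE)
    n_under <- stats::rpois(1, understory_rate)
    under <- if (n_under > 0) data.frame(
      quadrat_id = q,
      species_id = sample(avail_sp, n_under, replace = TRUE),
      dbh_m = stats::runif(n_under, 0.01, 0.09),
      height_m = stats::runif(n_under, 2, 8),
      canopy_spread_m = stats::runif(n_under, 1, 3), stringsAsFactors = FALSE)
    else NULL
    recs[[q]] <- rbind(canopy, under)
  }
  records <- do.call(rbind, recs)
  records <- records[records$dbh_m > 0.04, , drop = FALSE] # field protocol: > 4 cm
  rownames(records) <- NULL

  structure(list(quadrats = quadrats, records = records, pa_id = scene$pa_id,
                 seed = seed),
            class = "field_survey")
}

#' @export
print.field_survey <- function(x, ...) {
  cat(sprintf("field_survey %s: %d quadrats, %d records (> 4 cm DBH), %d species\n",
              x$pa_id, nrow(x$quadrats), nrow(x$records),
              length(unique(x$records$species_id))))
  invisible(x)
}

#' Simulate niche-model species counts per climate cell
#'
#' Draws Poisson counts per cell and species directly from the pool's niche
#' model: lambda = mean_abundance x softmax-free exp(niche . z(covariates)),
#' rescaled so the expected cell total is mean_abundance x species count x
#' the species' PA availability. A fast route to cell x species matrices for
#' testing the regression and dark-diversity stages without rendering
#' imagery.
#'
#' @param pool species_pool
#' @param grids climate_grids
#' @param mean_abundance expected count per species per cell at gradient centre
#' @param seed integer seed
#' @return list(counts = cells x species matrix, cells = covariate table)
#' @export
simulate_cell_counts <- function(pool, grids, mean_abundance = 8, seed = 1) {
  set.seed(seed)
  tab <- climate_cell_table(grids)
  Z <- scale(as.matrix(tab[, colnames(pool$niche)]))
  Z[is.nan(Z)] <- 0
  eta <- Z %*% t(pool$niche) # cells x species
  avail <- pool$membership[, match(tab$pa, colnames(pool$membership)), drop = FALSE]
  lambda <- mean_abundance * exp(eta - mean(eta)) * t(avail)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda),
                   dimnames = list(paste0("cell", seq_len(nrow(tab))),
                                   pool$species$species_id))
  list(counts = counts, cells = tab)
}

#' Simulate plot-level presence/absence data
#'
#' Draws `n_plots` plots per climate cell; each plot samples
#' `individuals_per_plot` stems from the cell's niche-model species
#' probabilities (multinomial), giving the plots x species presence matrix
#' the dark-diversity stage consumes. Plots inherit their cell's PA and a
#' drier/wetter region split at the median PA rainfall.
#'
#' @param pool species_pool
#' @param grids climate_grids
#' @param n_plots plots per cell
#' @param individuals_per_plot stems sampled per plot
#' @param seed integer seed
#' @return list(presence = plots x species 0/1 matrix, meta = per-plot
#'   data.frame(pa, region))
#' @export
simulate_plot_presence <- function(pool, grids, n_plots = 2L,
                                   individuals_per_plot = 40L, seed = 1) {
  set.seed(seed)
  tab <- climate_cell_table(grids)
  Z <- scale(as.matrix(tab[, colnames(pool$niche)]))
  Z[is.nan(Z)] <- 0
  eta <- Z %*% t(pool$niche)
  avail <- t(pool$membership[, match(tab$pa, colnames(pool$membership)), drop = FALSE])
  W <- exp(eta - apply(eta, 1, max)) * avail
  W <- W / rowSums(W)
  wet <- grids$pa_means$CC1 >= stats::median(grids$pa_means$CC1)
  region_of <- stats::setNames(ifelse(wet, "wetter", "drier"), grids$pa_means$pa)

  n_sp <- nrow(pool$species)
  pres <- matrix(0L, nrow(tab) * n_plots, n_sp,
                 dimnames = list(NULL, pool$species$species_id))
  meta <- data.frame(pa = character(nrow(pres)), region = character(nrow(pres)),
                     stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(nrow(tab))) {
    for (p in seq_len(n_plots)) {
      k <- k + 1L
      draw <- stats::rmultinom(1, individuals_per_plot, W[i, ])
      pres[k, ] <- as.integer(draw > 0)
      meta$pa[k] <- tab$pa[i]
      meta$region[k] <- region_of[[tab$pa[i]]]
    }
  }
  rownames(pres) <- paste0("plot", seq_len(nrow(pres)))
  list(presence = pres, meta = meta)
}
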