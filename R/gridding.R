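#' Overlay a 0.005 degree grid on a classification map
#'
#' Half-open cells tile the map extent starting at the map origin; edge cells
#' are clipped to the map. Cell centres are georeferenced from the map's geo
#' metadata.
#'
#' @param map classification_map with geo metadata
#' @param cell_size cell size in degrees (0.005 = 0.5 km in this world)
#' @return data.frame: cell_id, pixel window (row0/row1/col0/col1, 1-based
#'   inclusive), centre lon/lat
#' @export
overlay_grid <- function(map, cell_size = 0.005) {
  if (is.null(map$geo)) stop("map must be georeferenced")
  ppc <- round(cell_size / map$geo$px_deg)
  nr <- nrow(map$labels); nc <- ncol(map$labels)
  n_cr <- ceiling(nr / ppc); n_cc <- ceiling(nc / ppc)
  cells <- expand.grid(crow = seq_len(n_cr), ccol = seq_len(n_cc))
  out <- data.frame(
    cell_id = sprintf("c%03d_%03d", cells$crow, cells$ccol),
    row0 = (cells$crow - 1L) * ppc + 1L,
    row1 = pmin(cells$crow * ppc, nr),
    col0 = (cells$ccol - 1L) * ppc + 1L,
    col1 = pmin(cells$ccol * ppc, nc))
  out$lon <- map$geo$origin_lon + (cells$ccol - 0.5) * cell_size
  out$lat <- map$geo$origin_lat - (cells$crow - 0.5) * cell_size
  out
}

#' Extract 0.5 ha plots from a grid cell
#'
#' Places up to `n_plots` non-overlapping 18 x 18 pixel windows (0.518 ha at
#' 4 m, the smallest integer window of at least 0.5 ha) at seeded random
#' positions inside the cell and keeps those whose forest-pixel fraction is
#' at least `min_forest_fraction`. Returns an empty list (a logged outcome,
#' not an error) when no qualifying placement is found.
#'
#' @param map classification_map
#' @param cell one row of the [overlay_grid()] table
#' @param n_plots plots per cell
#' @param plot_px plot window edge in pixels
#' @param min_forest_fraction minimum labelled-pixel share
#' @param max_tries placement attempts per plot
#' @param seed integer seed
#' @return list of plots; each has window coords, forest_fraction and
#'   per-class pixel counts (named by legend)
#' @export
extract_plots <- function(map, cell, n_plots = 3L, plot_px = 18L,
                          min_forest_fraction = 0.70, max_tries = 60L, seed = 1) {
  set.seed(seed)
  rmax <- cell$row1 - plot_px + 1L
  cmax <- cell$col1 - plot_px + 1L
  if (rmax < cell$row0 || cmax < cell$col0) return(list())
  plots <- list(); taken <- matrix(numeric(0), 0, 2)
  for (try_i in seq_len(max_tries)) {
    if (length(plots) >= n_plots) break
    r0 <- sample(cell$row0:rmax, 1L)
    c0 <- sample(cell$col0:cmax, 1L)
    if (nrow(taken) > 0 &&
        any(abs(taken[, 1] - r0) < plot_px & abs(taken[, 2] - c0) < plot_px))
      next
    win <- map$labels[r0:(r0 + plot_px - 1L), c0:(c0 + plot_px - 1L)]
    ff <- mean(win > 0)
    if (ff < min_forest_fraction) next
    counts <- tabulate(win[win > 0], nbins = length(map$legend))
    names(counts) <- map$legend
    plots[[length(plots) + 1L]] <- list(row0 = r0, col0 = c0, plot_px = plot_px,
                                        forest_fraction = ff, pixel_counts = counts)
    taken <- rbind(taken, c(r0, c0))
  }
  plots
}

#' Extrapolate pixel counts to individual abundance
#'
#' abundance_s = round(pixel_count_s x pixel_area / crown_area_s) with crown
#' area pi (spread/2)^2; any species with at least one labelled pixel gets
#' abundance >= 1 (minimum-presence rule).
#'
#' @param pixel_counts named per-species pixel counts
#' @param canopy_spread named mean canopy spread (m) per species
#' @param pixel_area pixel area in m^2 (16 at 4 m resolution)
#' @return named integer abundance vector
#' @export
pixels_to_abundance <- function(pixel_counts, canopy_spread, pixel_area = 16) {
  present <- names(pixel_counts)[pixel_counts > 0]
  missing <- setdiff(present, names(canopy_spread))
  if (length(missing))
    stop("no canopy spread for species: ", paste(missing, collapse = ", "))
  spread <- canopy_spread[names(pixel_counts)]
  ab <- round(pixel_counts * pixel_area / (pi * (spread / 2)^2))
  ab[pixel_counts > 0 & ab < 1] <- 1L
  ab[pixel_counts == 0] <- 0L
  storage.mode(ab) <- "integer"
  names(ab) <- names(pixel_counts)
  ab
}

#' Sum plot abundances into a cell abundance vector
#' @param abundances list of named abundance vectors (one per plot)
#' @export
aggregate_cell_abundance <- function(abundances) {
  if (!length(abundances)) stop("need at least one accepted plot")
  Reduce(`+`, abundances)
}

#' Attach climate covariates to grid cells by nearest neighbour
#'
#' Each cell centre receives the value of the nearest covariate cell; soil is
#' a binary indicator. Errors listing the offending cells if any centre falls
#' outside the covariate extent (beyond half a cell of tolerance).
#'
#' @param cells data.frame with cell_id, lon, lat
#' @param grids climate_grids
#' @return `cells` with CC1..CC6, elevation, soil and pa columns appended
#' @export
attach_covariates <- function(cells, grids) {
  nr <- nrow(grids$pa); nc <- ncol(grids$pa)
  ci <- round((cells$lon - grids$origin[1]) / grids$cell_size + 0.5)
  ri <- round((grids$origin[2] - cells$lat) / grids$cell_size + 0.5)
  bad <- ri < 0 | ri > nr + 1 | ci < 0 | ci > nc + 1
  if (any(bad))
    stop("cell centres outside covariate extent: ",
         paste(cells$cell_id[bad], collapse = ", "))
  ri <- pmin(pmax(ri, 1L), nr); ci <- pmin(pmax(ci, 1L), nc)
  idx <- cbind(ri, ci)
  for (nm in names(grids$covariates)) cells[[nm]] <- grids$covariates[[nm]][idx]
  cells$elevation <- grids$elevation[idx]
  cells$soil <- grids$soil[idx]
  cells$pa <- grids$pa_ids[grids$pa[idx]]
  cells
}

#' Build the cell x species abundance matrix from a classification map
#'
#' The "large-scale plot data" stage: overlays the grid, extracts up to three
#' qualifying 0.5 ha plots per cell, extrapolates pixel counts to abundances
#' via canopy spread, aggregates plots per cell, and attaches climate
#' covariates. Cells with no qualifying plot are excluded and logged in the
#' `excluded` element.
#'
#' @param map classification_map
#' @param grids climate_grids
#' @param canopy_spread named mean canopy spread (m) per legend class
#' @param cell_size grid cell size in degrees
#' @param n_plots,plot_px,min_forest_fraction see [extract_plots()]
#' @param seed integer seed (plot placement per cell derives from it)
#' @return object of class `abundance_matrix`: counts (cells x species),
#'   cells table with covariates, plot registry, excluded-cell log
#' @export
build_abundance_matrix <- function(map, grids, canopy_spread, cell_size = 0.005,
                                   n_plots = 3L, plot_px = 18L,
                                   min_forest_fraction = 0.70, seed = 1) {
  grid <- overlay_grid(map, cell_size)
  counts <- list(); kept <- integer(0); excluded <- character(0)
  plot_registry <- list(); plot_counts <- list()
  for (i in seq_len(nrow(grid))) {
    plots <- extract_plots(map, grid[i, ], n_plots, plot_px,
                           min_forest_fraction, seed = seed + i)
    if (!length(plots)) { excluded <- c(excluded, grid$cell_id[i]); next }
    ab <- lapply(plots, function(p) pixels_to_abundance(p$pixel_counts, canopy_spread))
    counts[[length(counts) + 1L]] <- aggregate_cell_abundance(ab)
    kept <- c(kept, i)
    plot_registry[[grid$cell_id[i]]] <- data.frame(
      cell_id = grid$cell_id[i],
      plot = seq_along(plots),
      row0 = vapply(plots, `[[`, 0, "row0"),
      col0 = vapply(plots, `[[`, 0, "col0"),
      forest_fraction = vapply(plots, `[[`, 0, "forest_fraction"))
    pc <- do.call(rbind, ab)
    rownames(pc) <- paste0(grid$cell_id[i], "_p", seq_along(plots))
    plot_counts[[length(plot_counts) + 1L]] <- pc
  }
  if (!length(kept)) stop("no grid cell yielded a qualifying plot")
  Y <- do.call(rbind, counts)
  rownames(Y) <- grid$cell_id[kept]
  cells <- attach_covariates(grid[kept, , drop = FALSE], grids)
  structure(list(counts = Y, cells = cells,
                 plots = do.call(rbind, plot_registry),
                 plot_counts = do.call(rbind, plot_counts),
                 excluded = excluded),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d cells x %d species (%d cells excluded)\n",
              nrow(x$counts), ncol(x$counts), length(x$excluded)))
  invisible(x)
}

#' Relative-abundance view of an abundance matrix
#' @param x abundance_matrix or counts matrix
#' @return row-normalized matrix (rows sum to 1)
#' @export
relative_abundance <- function(x) {
  Y <- if (inherits(x, "abundance_matrix")) x$counts else as.matrix(x)
  rs <- rowSums(Y)
  if (any(rs == 0)) stop("retained cells must have positive row totals")
  Y / rs
}
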