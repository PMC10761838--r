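#' Default demo pipeline configuration
#'
#' A small four-PA world that exercises every stage in a few minutes:
#' 12 species, 250 x 250 pixel scenes (2 x 2 grid cells per PA at 4 m), the
#' default sensor noise and brightness gradient, and a K = 3 component
#' regression. Every random operation draws its seed from `seed`.
#'
#' @param seed master seed
#' @return nested configuration list (round-trips losslessly through JSON)
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = seed,
    stages = list(synth = TRUE, classify = TRUE, grid = TRUE, model = TRUE,
                  community = TRUE, traits = TRUE, darkdiv = TRUE),
    synth = list(n_species = 12L, n_pas = 4L, pa_specific_fraction = 0.25,
                 cells_per_pa = c(2L, 2L), scene_px = c(250L, 250L),
                 noise_sd = 0.005, brightness_range = c(0.8, 1.2),
                 cover = 0.9, noise_sd_frac = 0.1, n_quadrats = 60L),
    classify = list(ndvi_thresholds = c(0.4, 0.4, 0.6, 0.6),
                    abundant_coverage = 0.8, n_train_crowns = 900L,
                    snr_threshold = 2, ntree_grid = c(120L),
                    train_fraction = 0.75, map_paths = NULL),
    grid = list(cell_size = 0.005, n_plots = 3L, plot_px = 18L,
                min_forest_fraction = 0.70),
    model = list(K = 3L, s = 0.5, l = 1, n_blocks = 8L, max_iter = 100L),
    community = list(n_axes = 5L, k_types = 4L, n_boot = 50L),
    darkdiv = list(q = 0.05, min_richness = 5L, list_share = 0.15)
  )
}

.write_csv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

.write_matrix_csv <- function(m, path) {
  df <- data.frame(row = rownames(m) %||% seq_len(nrow(m)), as.data.frame(m),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write a classification (or truth) map as CSV + JSON sidecar
#' @param map classification_map
#' @param path CSV path; the legend/geo sidecar gets extension .json
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(legend = map$legend, geo = map$geo), side,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classification map written by [write_map_csv()]
#' @param path CSV path
#' @export
read_map_csv <- function(path) {
  labels <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  structure(list(labels = labels, legend = side$legend, geo = as.list(side$geo)),
            class = "classification_map")
}

#' Run the full analysis pipeline
#'
#' Executes synth -> classify -> grid -> model -> community -> traits ->
#' darkdiv in dependency order, writing plain-text artifacts (CSV/JSON) and
#' a run manifest with per-stage timings, warnings and file checksums to
#' `out_dir`. Stages can be toggled in the config; disabling `classify`
#' requires `config$classify$map_paths` pointing at previously written maps.
#'
#' @param config configuration list (see [demo_config()]) or path to a JSON
#'   file holding one
#' @param out_dir output directory (created if needed)
#' @return the run manifest, invisibly; artifacts on disk
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("run")) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list(), warnings = list())
  t_all <- proc.time()[3]
  log_stage <- function(name, t0, files) {
    manifest$stages[[name]] <<- list(
      elapsed_s = round(proc.time()[3] - t0, 2),
      files = as.list(tools::md5sum(files[file.exists(files)])))
    message(sprintf("[%s] done in %.1fs (seed %d)", name,
                    proc.time()[3] - t0, config$seed))
  }
  catch_warnings <- function(name, expr) {
    withCallingHandlers(expr, warning = function(w) {
      manifest$warnings[[name]] <<- c(manifest$warnings[[name]],
                                      conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  seed <- config$seed
  sc <- config$synth

  ## ---- synth ----
  t0 <- proc.time()[3]
  pool <- generate_species_pool(sc$n_species, sc$n_pas, sc$pa_specific_fraction,
                                seed = seed)
  grids <- generate_climate_grids(n_pas = sc$n_pas, cells_per_pa = sc$cells_per_pa,
                                  noise_sd_frac = sc$noise_sd_frac, seed = seed + 1)
  pool_csv <- file.path(out_dir, "species_pool.csv")
  .write_csv(cbind(pool$species, as.data.frame(pool$membership)), pool_csv)
  clim_csv <- file.path(out_dir, "climate_cells.csv")
  .write_csv(climate_cell_table(grids), clim_csv)
  log_stage("synth", t0, c(pool_csv, clim_csv))

  ## ---- per-PA imagery: classify + grid + traits inputs ----
  cc <- config$classify
  gc_ <- config$grid
  abund <- list(); surveys <- list(); pixel_traits <- list(); reports <- list()
  map_files <- character(0)
  for (p in seq_len(sc$n_pas)) {
    pa_id <- grids$pa_ids[p]
    t0 <- proc.time()[3]
    scene <- generate_scene(pool, grids, pa_id, size = sc$scene_px,
                            noise_sd = sc$noise_sd,
                            brightness_range = sc$brightness_range,
                            cover = sc$cover, seed = seed + 10 + p)
    surveys[[pa_id]] <- generate_field_survey(scene, sc$n_quadrats,
                                              seed = seed + 20 + p)

    if (isTRUE(config$stages$classify)) {
      cls <- catch_warnings(paste0("classify_", pa_id),
        classify_scene(scene, ndvi_threshold = cc$ndvi_thresholds[p],
                       abundant_coverage = cc$abundant_coverage,
                       n_train_crowns = cc$n_train_crowns,
                       snr_threshold = cc$snr_threshold,
                       ntree_grid = cc$ntree_grid,
                       train_fraction = cc$train_fraction,
                       seed = seed + 30 + p))
      map <- cls$map
      reports[[pa_id]] <- cls$report
      map_file <- file.path(out_dir, sprintf("map_%s.csv", pa_id))
      write_map_csv(map, map_file)
      acc_file <- file.path(out_dir, sprintf("accuracy_%s.csv", pa_id))
      .write_csv(data.frame(metric = c("overall_accuracy", "kappa", "oob_error"),
                            value = c(cls$report$overall_accuracy,
                                      cls$report$kappa,
                                      100 * cls$chain$rf$oob_error)), acc_file)
      map_files <- c(map_files, map_file, acc_file)
    } else {
      map <- read_map_csv(config$classify$map_paths[[pa_id]])
    }

    # crown-pixel index values for the trait table
    idx <- compute_indices(scene$cube)
    tr <- catch_warnings(paste0("traits_px_", pa_id),
      extract_training_spectra(scene$cube, scene$crowns,
                               mask = scene$truth > 0,
                               bands = band_set(1L, "one")))
    px <- data.frame(species_id = tr$labels, pa = pa_id,
                     CCI = idx$CCI[tr$coords], NIRvP = idx$NIRvP[tr$coords],
                     NDWI = idx$NDWI[tr$coords])
    pixel_traits[[pa_id]] <- px[stats::complete.cases(px), ]

    if (isTRUE(config$stages$grid)) {
      spread <- stats::setNames(pool$species$mean_canopy_spread,
                                pool$species$species_id)
      spread <- c(spread, others = mean(spread))
      abund[[pa_id]] <- catch_warnings(paste0("grid_", pa_id),
        build_abundance_matrix(map, grids, spread, cell_size = gc_$cell_size,
                               n_plots = gc_$n_plots, plot_px = gc_$plot_px,
                               min_forest_fraction = gc_$min_forest_fraction,
                               seed = seed + 40 + p))
    }
    rm(scene); gc(verbose = FALSE)
    log_stage(paste0("scene_", pa_id), t0, map_files)
  }

  ## ---- combined abundance matrix ----
  t0 <- proc.time()[3]
  species_union <- sort(unique(unlist(lapply(abund, function(a) colnames(a$counts)))))
  Y <- do.call(rbind, lapply(names(abund), function(pa_id) {
    m <- matrix(0L, nrow(abund[[pa_id]]$counts), length(species_union),
                dimnames = list(paste0(pa_id, "_", rownames(abund[[pa_id]]$counts)),
                                species_union))
    m[, colnames(abund[[pa_id]]$counts)] <- abund[[pa_id]]$counts
    m
  }))
  cells <- do.call(rbind, lapply(abund, function(a) a$cells))
  keep <- rowSums(Y) > 0
  Y <- Y[keep, , drop = FALSE]; cells <- cells[keep, , drop = FALSE]
  plot_counts <- do.call(rbind, lapply(names(abund), function(pa_id) {
    pc <- abund[[pa_id]]$plot_counts
    m <- matrix(0L, nrow(pc), length(species_union),
                dimnames = list(paste0(pa_id, "_", rownames(pc)), species_union))
    m[, colnames(pc)] <- pc
    m
  }))
  pa_of_plot <- sub("_.*", "", rownames(plot_counts))
  ab_csv <- file.path(out_dir, "abundance_matrix.csv")
  .write_csv(cbind(cells, as.data.frame(Y)), ab_csv)
  excl_csv <- file.path(out_dir, "excluded_cells.csv")
  .write_csv(data.frame(pa = rep(names(abund), vapply(abund, function(a)
    length(a$excluded), 0L)),
    cell_id = unlist(lapply(abund, function(a) a$excluded))), excl_csv)
  log_stage("grid", t0, c(ab_csv, excl_csv))

  ## ---- supervised-component model ----
  mc <- config$model
  if (isTRUE(config$stages$model)) {
  t0 <- proc.time()[3]
  X <- as.matrix(cells[, paste0("CC", 1:6)])
  extra <- as.matrix(cells[, c("elevation", "soil")])
  model <- catch_warnings("model",
    fit_scglr(X, Y, extra, K = mc$K, s = mc$s, l = mc$l,
              max_iter = mc$max_iter, seed = seed))
  n_blocks <- min(mc$n_blocks, nrow(Y) - 1L)
  blocks <- make_spatial_blocks(cells[, c("lon", "lat")], n_blocks)
  cv <- catch_warnings("model_cv",
    cross_validate(X, Y, extra, blocks, K = mc$K, s = mc$s, l = mc$l,
                   max_iter = mc$max_iter))
  model_json <- file.path(out_dir, "scglr_model.json")
  jsonlite::write_json(list(
    version = "1", mean = model$mean, sd = model$sd,
    loadings = model$loadings, coefficients = model$coefficients,
    species = colnames(Y), K = mc$K, s = mc$s, l = mc$l, seed = seed),
    model_json, digits = NA)
  cv_csv <- file.path(out_dir, "cv_results.csv")
  .write_csv(data.frame(species = names(cv$rho), rho = cv$rho), cv_csv)
  inertia_csv <- file.path(out_dir, "component_inertia.csv")
  .write_csv(component_inertia(model), inertia_csv)
  log_stage("model", t0, c(model_json, cv_csv, inertia_csv))
  }

  ## ---- community structure ----
  co <- config$community
  if (isTRUE(config$stages$community) && isTRUE(config$stages$model)) {
  t0 <- proc.time()[3]
  pred <- predict_abundance(model, X, extra)
  ca <- catch_warnings("community", correspondence_analysis(Y))
  n_axes <- min(co$n_axes, ncol(ca$row_scores))
  proj <- project_rows(ca, pred[, ca$species, drop = FALSE])
  typing <- assemblage_types(proj[, seq_len(n_axes), drop = FALSE],
                             k = min(co$k_types, nrow(proj)),
                             n_boot = co$n_boot, seed = seed)
  sim <- type_similarity(typing$types, Y, groups = cells$pa)
  ca_csv <- file.path(out_dir, "ca_scores.csv")
  .write_matrix_csv(cbind(observed = ca$row_scores[, 1:n_axes, drop = FALSE],
                          predicted = proj[, 1:n_axes, drop = FALSE]), ca_csv)
  typing_csv <- file.path(out_dir, "assemblage_types.csv")
  .write_csv(data.frame(cell_id = rownames(Y), pa = cells$pa,
                        type = typing$types, uncertainty = typing$uncertainty),
             typing_csv)
  sim_csv <- file.path(out_dir, "type_similarity.csv")
  .write_matrix_csv(sim, sim_csv)
  tree_txt <- file.path(out_dir, "typing_tree.txt")
  writeLines(typing_tree_text(typing), tree_txt)
  log_stage("community", t0, c(ca_csv, typing_csv, sim_csv, tree_txt))
  }

  ## ---- functional traits ----
  if (isTRUE(config$stages$traits)) {
  t0 <- proc.time()[3]
  records <- do.call(rbind, lapply(names(surveys), function(pa_id)
    cbind(surveys[[pa_id]]$records, pa = pa_id)))
  pixels <- do.call(rbind, pixel_traits)
  info <- data.frame(species_id = pool$species$species_id,
                     wood_density = pool$species$wood_density,
                     phenology = pool$species$phenology)
  traits <- catch_warnings("traits",
    build_trait_table(records[, c("species_id", "pa", "dbh_m")], pixels, info))
  # the pooled "others" class: mean traits of the pooled species
  if ("others" %in% colnames(Y) && !"others" %in% traits$species_id) {
    oth <- data.frame(species_id = "others",
                      t(colMeans(traits[, -1], na.rm = TRUE)))
    traits <- rbind(traits, oth)
  }
  traits <- traits[stats::complete.cases(traits), ]
  traits_csv <- file.path(out_dir, "trait_table.csv")
  .write_csv(traits, traits_csv)

  usable_sp <- intersect(colnames(Y), traits$species_id)
  Yt <- Y[, usable_sp, drop = FALSE]
  tm <- as.matrix(traits[match(usable_sp, traits$species_id),
                         c("wood_density", "phenology", "max_dbh",
                           "CCI", "NIRvP", "NDWI")])
  rownames(tm) <- usable_sp
  cwms <- vapply(colnames(tm), function(tr)
    vapply(seq_len(nrow(Yt)), function(i)
      cwm(Yt[i, ], stats::setNames(tm[, tr], usable_sp)), 0), numeric(nrow(Yt)))
  cwm_csv <- file.path(out_dir, "cwm.csv")
  .write_csv(data.frame(cell_id = rownames(Yt), pa = cells$pa, cwms), cwm_csv)

  fd_bio <- compute_fd(Yt, tm[, c("wood_density", "phenology", "max_dbh")])
  fd_chem <- compute_fd(Yt, tm[, c("CCI", "NIRvP", "NDWI")])
  fd_csv <- file.path(out_dir, "functional_diversity.csv")
  .write_csv(data.frame(cell_id = rownames(Yt), pa = cells$pa,
                        fric_bio = fd_bio$fric, fdiv_bio = fd_bio$fdiv,
                        fric_chem = fd_chem$fric, fdiv_chem = fd_chem$fdiv),
             fd_csv)
  fd_sum_csv <- file.path(out_dir, "fd_summary.csv")
  .write_csv(catch_warnings("traits_summary",
    summarize_fd(fd_chem, cells$pa)), fd_sum_csv)
  log_stage("traits", t0, c(traits_csv, cwm_csv, fd_csv, fd_sum_csv))
  }

  ## ---- dark diversity ----
  dc <- config$darkdiv
  if (isTRUE(config$stages$darkdiv)) {
  t0 <- proc.time()[3]
  pres <- (plot_counts > 0) * 1L
  b <- beals_matrix(pres)
  thr <- catch_warnings("darkdiv", species_thresholds(b, pres, dc$q))
  dd <- dark_diversity(pres, b, thr, dc$min_richness)
  region <- ifelse(grids$pa_means$soil[match(pa_of_plot, grids$pa_ids)] == 1,
                   "wetter", "drier")
  rep_dd <- dd_summaries(dd, regions = region, list_share = dc$list_share)
  dd_csv <- file.path(out_dir, "dark_diversity.csv")
  .write_matrix_csv((dd$membership) * 1L, dd_csv)
  ddr_csv <- file.path(out_dir, "dd_report.csv")
  .write_csv(data.frame(species = names(rep_dd$species_share),
                        share = rep_dd$species_share,
                        listed = names(rep_dd$species_share) %in% rep_dd$listed),
             ddr_csv)
  log_stage("darkdiv", t0, c(dd_csv, ddr_csv))
  }

  ## ---- manifest ----
  manifest$elapsed_s <- round(proc.time()[3] - t_all, 2)
  manifest$version <- as.character(utils::packageVersion("canopydiv"))
  all_files <- list.files(out_dir, full.names = TRUE)
  all_files <- all_files[!grepl("manifest\\.json$", all_files)]
  manifest$checksums <- as.list(tools::md5sum(all_files))
  names(manifest$checksums) <- basename(all_files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Validate pipeline output schemas
#'
#' Checks each expected artifact for existence, required columns and value
#' ranges (non-negative abundances, rho in \[-1, 1\], uncertainties in
#' \[0, 1\], binary dark-diversity membership). Missing files are listed and
#' non-fatal.
#'
#' @param out_dir pipeline output directory
#' @return data.frame(file, status, detail); attribute `ok` is TRUE when
#'   every present file passes and nothing is missing
#' @export
validate_outputs <- function(out_dir) {
  checks <- list(
    "species_pool.csv" = function(df) {
      if (!all(c("species_id", "wood_density") %in% names(df))) return("missing columns")
      if (any(df$wood_density <= 0)) return("non-positive wood density")
      "ok"
    },
    "abundance_matrix.csv" = function(df) {
      sp <- setdiff(names(df), c("cell_id", "row0", "row1", "col0", "col1",
                                 "lon", "lat", paste0("CC", 1:6),
                                 "elevation", "soil", "pa"))
      m <- as.matrix(df[, sp])
      if (any(m < 0) || any(m != round(m))) return("negative or non-integer abundance")
      if (any(rowSums(m) == 0)) return("zero-total cell retained")
      "ok"
    },
    "cv_results.csv" = function(df) {
      if (!all(c("species", "rho") %in% names(df))) return("missing columns")
      r <- df$rho[!is.na(df$rho)]
      if (any(r < -1 | r > 1)) return("rho outside [-1, 1]")
      "ok"
    },
    "component_inertia.csv" = function(df) {
      if (any(df$share < 0 | df$share > 100 + 1e-9)) return("share outside [0, 100]")
      if (is.unsorted(df$cumulative)) return("cumulative share decreasing")
      "ok"
    },
    "assemblage_types.csv" = function(df) {
      if (any(df$uncertainty < 0 | df$uncertainty > 1)) return("uncertainty outside [0, 1]")
      "ok"
    },
    "trait_table.csv" = function(df) {
      if (any(df$max_dbh <= 0, na.rm = TRUE)) return("non-positive max DBH")
      "ok"
    },
    "dark_diversity.csv" = function(df) {
      m <- as.matrix(df[, -1])
      if (!all(m %in% c(0, 1))) return("membership not binary")
      "ok"
    },
    "manifest.json" = function(df) "ok"
  )
  out <- data.frame(file = names(checks), status = "missing", detail = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(checks)) {
    path <- file.path(out_dir, out$file[i])
    if (!file.exists(path)) next
    df <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
          else utils::read.csv(path, check.names = FALSE)
    res <- tryCatch(checks[[i]](df), error = function(e) conditionMessage(e))
    out$status[i] <- if (identical(res, "ok")) "pass" else "fail"
    out$detail[i] <- if (identical(res, "ok")) "" else res
  }
  attr(out, "ok") <- all(out$status == "pass")
  out
}
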