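#' Designate abundant species from a crown registry
#'
#' Orders species by crown count and keeps the smallest prefix whose crowns
#' cover at least `coverage` of all crowns; the remainder is pooled into the
#' class `"others"`, which is then treated exactly like a species.
#'
#' @param crowns crown registry data.frame with a `species_id` column
#' @param coverage cumulative crown-share cut-off (default 0.8)
#' @param max_species upper bound on the abundant list
#' @return character vector of abundant species ids (never includes "others")
#' @export
designate_abundant <- function(crowns, coverage = 0.8, max_species = Inf) {
  tab <- sort(table(crowns$species_id), decreasing = TRUE)
  cum <- cumsum(tab) / sum(tab)
  n_keep <- min(which(cum >= coverage)[1], max_species, length(tab))
  names(tab)[seq_len(n_keep)]
}

#' Extract labelled training spectra from crown footprints
#'
#' One sample per valid pixel inside a crown disc. Crowns whose footprint
#' yields fewer than `min_pixels` valid pixels are skipped with a warning.
#' Species outside `abundant` are relabelled `"others"`.
#'
#' @param cube spectral_cube
#' @param crowns registry data.frame (species_id, row, col, diameter_m)
#' @param mask logical matrix of valid pixels (e.g. the NDVI mask)
#' @param bands band_set to extract (default all bands)
#' @param abundant character vector of abundant species ids (NULL = keep all)
#' @param min_pixels minimum valid pixels per crown
#' @param core_fraction fraction of the crown radius to sample from (pixels
#'   near the crown edge are often mixed with neighbouring canopies; 1 = the
#'   full disc)
#' @return list(spectra, labels, crown_id, coords)
#' @export
extract_training_spectra <- function(cube, crowns, mask = NULL, bands = NULL,
                                     abundant = NULL, min_pixels = 1L,
                                     core_fraction = 1) {
  if (is.null(mask)) mask <- cube$mask
  nr <- nrow(mask); nc <- ncol(mask)
  px_m <- if (!is.null(cube$geo)) cube$geo$px_m else 4
  flat <- matrix(cube$reflectance, ncol = dim(cube$reflectance)[3])
  bi <- if (is.null(bands)) seq_along(cube$wavelengths) else bands$indices

  spec <- list(); labels <- character(0); cid <- integer(0); coords <- list()
  skipped <- 0L
  for (k in seq_len(nrow(crowns))) {
    rad <- crowns$diameter_m[k] / 2 / px_m * core_fraction
    r0 <- max(1L, floor(crowns$row[k] - rad)); r1 <- min(nr, ceiling(crowns$row[k] + rad))
    c0 <- max(1L, floor(crowns$col[k] - rad)); c1 <- min(nc, ceiling(crowns$col[k] + rad))
    if (r0 > r1 || c0 > c1) { skipped <- skipped + 1L; next }
    rr <- r0:r1; cc <- c0:c1
    inside <- outer((rr - crowns$row[k])^2, (cc - crowns$col[k])^2, "+") <= max(rad, 0.5)^2
    ok <- inside & mask[rr, cc, drop = FALSE]
    hits <- which(ok, arr.ind = TRUE)
    if (nrow(hits) < min_pixels) { skipped <- skipped + 1L; next }
    prow <- rr[hits[, 1]]; pcol <- cc[hits[, 2]]
    spec[[length(spec) + 1L]] <- flat[(pcol - 1L) * nr + prow, bi, drop = FALSE]
    labels <- c(labels, rep(crowns$species_id[k], nrow(hits)))
    cid <- c(cid, rep(if (!is.null(crowns$crown_id)) crowns$crown_id[k] else k, nrow(hits)))
    coords[[length(coords) + 1L]] <- cbind(prow, pcol)
  }
  if (!length(spec)) stop("no crowns overlap valid pixels")
  if (skipped > 0)
    warning(sprintf("%d crowns skipped (< %d valid pixels)", skipped, min_pixels))
  if (!is.null(abundant)) labels[!labels %in% abundant] <- "others"
  list(spectra = do.call(rbind, spec), labels = labels, crown_id = cid,
       coords = do.call(rbind, coords))
}

#' Stratified train/test split
#'
#' Simple random per-class partition into 75% training and 25% testing.
#' Train and test are disjoint by sample (a with-replacement split would leak
#' duplicated samples across the partition and invalidate the test estimate).
#'
#' @param labels class label vector
#' @param train_fraction training share per class
#' @param seed integer seed
#' @return character vector of tags "train"/"test", same length as labels
#' @export
split_train_test <- function(labels, train_fraction = 0.75, seed = 1) {
  set.seed(seed)
  tags <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2)
      stop(sprintf("class '%s' has a single sample; cannot split", cl))
    n_tr <- max(1L, round(train_fraction * length(idx)))
    if (n_tr == length(idx)) n_tr <- length(idx) - 1L
    tr <- sample(idx, n_tr)
    tags[tr] <- "train"
    tags[setdiff(idx, tr)] <- "test"
  }
  tags
}

#' SMOTE oversampling to class balance
#'
#' Minority classes are grown to the majority-class count with synthetic
#' samples x + u (x_nn - x), u ~ U\[0, 1), between a random class member and
#' one of its k nearest same-class neighbours. The majority class and the
#' label set are never changed.
#'
#' @param X samples x features matrix
#' @param y class labels
#' @param k_neighbors neighbourhood size (reduced with a warning when a class
#'   is smaller than k + 1)
#' @param seed integer seed
#' @return list(X, y, synthetic = logical flag per row)
#' @export
smote_balance <- function(X, y, k_neighbors = 5L, seed = 1) {
  set.seed(seed)
  X <- as.matrix(X)
  counts <- table(y)
  n_max <- max(counts)
  add_X <- list(); add_y <- character(0)
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0) next
    idx <- which(y == cl)
    if (length(idx) < 2)
      stop(sprintf("class '%s' needs >= 2 samples for SMOTE", cl))
    k <- k_neighbors
    if (k >= length(idx)) {
      k <- length(idx) - 1L
      warning(sprintf("class '%s': k_neighbors reduced to %d", cl, k))
    }
    Xc <- X[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(Xc))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
    base <- sample.int(nrow(Xc), need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
    u <- stats::runif(need)
    add_X[[cl]] <- Xc[base, , drop = FALSE] +
      u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
    add_y <- c(add_y, rep(cl, need))
  }
  if (length(add_X)) {
    Xs <- rbind(X, do.call(rbind, add_X))
    ys <- c(y, add_y)
  } else { Xs <- X; ys <- y }
  list(X = Xs, y = ys, synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, length(add_y))))
}

#' Train a random forest with (mtry, ntree) grid search
#'
#' Grows CART forests (Gini splits, bootstrap resampling) for every grid
#' combination and keeps the one with the highest out-of-bag accuracy.
#' Prediction ties break to the lowest class index, and everything is
#' deterministic under the seed.
#'
#' @param X samples x features matrix (balanced training set)
#' @param y class labels
#' @param mtry_grid candidate numbers of features per split
#' @param ntree_grid candidate forest sizes
#' @param seed integer seed
#' @param min_node minimum node size before a split is attempted
#' @return object of class `rf_model` (levels, forest, oob_error, chosen
#'   hyperparameters, full grid results)
#' @export
train_rf <- function(X, y, mtry_grid = NULL, ntree_grid = c(200L), seed = 1,
                     min_node = 2L) {
  X <- as.matrix(X)
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1L, round(sqrt(ncol(X)) * c(0.5, 1, 2))))
  if (!length(mtry_grid) || !length(ntree_grid)) stop("empty hyperparameter grid")
  levels_ <- sort(unique(y))
  yi <- match(y, levels_) - 1L

  grid <- expand.grid(mtry = as.integer(mtry_grid), ntree = as.integer(ntree_grid))
  grid$oob_error <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    fit <- rf_fit_cpp(X, yi, length(levels_), grid$ntree[g], grid$mtry[g],
                      as.integer(min_node), as.integer(seed))
    grid$oob_error[g] <- fit$oob_error
    if (is.null(best) || fit$oob_error < best$oob_error - 1e-12)
      best <- list(fit = fit, mtry = grid$mtry[g], ntree = grid$ntree[g],
                   oob_error = fit$oob_error)
  }
  structure(list(forest = best$fit, levels = levels_, mtry = best$mtry,
                 ntree = best$ntree, oob_error = best$oob_error,
                 grid = grid, n_features = ncol(X), seed = seed),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("rf_model: %d classes, mtry = %d, ntree = %d, OOB error = %.2f%%\n",
              length(x$levels), x$mtry, x$ntree, 100 * x$oob_error))
  invisible(x)
}

#' Predict class labels with a trained forest
#' @param object rf_model
#' @param newdata samples x features matrix
#' @param ... unused
#' @return character vector of predicted labels
#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature dimension mismatch: model expects ", object$n_features)
  object$levels[rf_predict_cpp(object$forest, newdata) + 1L]
}

#' Predict a per-pixel species map
#'
#' Applies the full preprocessing chain stored in a `classifier_chain`
#' (band subset, brightness normalization, MNF projection) to every unmasked
#' pixel and labels it; masked pixels carry the non-forest code 0.
#'
#' @param chain classifier_chain from [classify_scene()] (or a list with
#'   fields bands, mnf, n_components, rf)
#' @param cube spectral_cube
#' @param mask logical forest mask
#' @return object of class `classification_map`: integer label matrix
#'   (0 = non-forest), legend, and geo metadata
#' @export
predict_map <- function(chain, cube, mask) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (any(mask)) {
    cs <- cube_spectra(cube, chain$bands, mask)
    bn <- brightness_normalize(cs$spectra)
    keep <- setdiff(seq_len(nrow(cs$spectra)), attr(bn, "dropped_rows"))
    scores <- mnf_transform(chain$mnf, bn, chain$n_components)
    pred <- predict(chain$rf, scores)
    labels[cs$coords[keep, , drop = FALSE]] <- match(pred, chain$rf$levels)
  }
  structure(list(labels = labels, legend = chain$rf$levels, geo = cube$geo),
            class = "classification_map")
}

#' @export
print.classification_map <- function(x, ...) {
  cat(sprintf("classification_map: %d x %d px, %d classes, %.1f%% labelled\n",
              nrow(x$labels), ncol(x$labels), length(x$legend),
              100 * mean(x$labels > 0)))
  invisible(x)
}

#' Per-class mapped area in km^2
#' @param map classification_map
#' @param px_m pixel edge in metres (default from geo metadata, else 4)
#' @export
species_area_km2 <- function(map, px_m = NULL) {
  if (is.null(px_m)) px_m <- if (!is.null(map$geo)) map$geo$px_m else 4
  counts <- tabulate(map$labels[map$labels > 0], nbins = length(map$legend))
  stats::setNames(counts * px_m^2 / 1e6, map$legend)
}

#' Confusion-matrix accuracy assessment
#'
#' @param predicted predicted label vector
#' @param reference reference label vector (same length)
#' @return object of class `confusion_report`: confusion matrix (reference
#'   rows x predicted columns), overall accuracy (%), kappa, per-class
#'   producer's and user's accuracies (%).
#' @export
assess_accuracy <- function(predicted, reference) {
  if (!length(predicted) || length(predicted) != length(reference))
    stop("predicted and reference must be equal-length non-empty vectors")
  lev <- sort(unique(c(predicted, reference)))
  cm <- table(factor(reference, lev), factor(predicted, lev))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  producers <- 100 * diag(cm) / rowSums(cm) # reference totals
  users <- 100 * diag(cm) / colSums(cm)     # predicted totals
  structure(list(confusion = cm, overall_accuracy = 100 * po, kappa = kappa,
                 producers_accuracy = producers, users_accuracy = users),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("confusion_report: OA = %.2f%%, kappa = %.3f (%d classes, n = %d)\n",
              x$overall_accuracy, x$kappa, nrow(x$confusion), sum(x$confusion)))
  invisible(x)
}

#' End-to-end species classification of a scene
#'
#' Orchestrates the full mapping chain on one scene: NDVI forest mask,
#' usable/classification band selection, brightness normalization, MNF fit on
#' the training spectra, SMOTE-balanced random forest with hyperparameter
#' grid search, per-pixel map prediction and test-set accuracy assessment.
#'
#' @param scene synthetic_scene (or any list with cube + crowns registry)
#' @param ndvi_threshold forest mask cut-off
#' @param abundant_coverage crown-share used by [designate_abundant()]
#' @param n_train_crowns number of crowns sampled per scene for training
#' @param snr_threshold MNF eigenvalue cut-off for component retention
#' @param mtry_grid,ntree_grid forest hyperparameter grids
#' @param train_fraction training share of the crown spectra
#' @param seed integer seed for split, SMOTE and forest
#' @return list(map, report, chain, test) where `chain` bundles bands, MNF
#'   model, retained components and the forest for reuse on new cubes
#' @export
classify_scene <- function(scene, ndvi_threshold = 0.4, abundant_coverage = 0.8,
                           n_train_crowns = 1500L, snr_threshold = 2,
                           mtry_grid = NULL, ntree_grid = c(150L),
                           train_fraction = 0.75, seed = 1) {
  set.seed(seed)
  cube <- scene$cube
  mask <- compute_ndvi_mask(cube, ndvi_threshold)
  usable <- select_usable_bands(cube)
  cls_bands <- select_classification_bands(usable, cube)

  abundant <- designate_abundant(scene$crowns, abundant_coverage)
  crowns <- scene$crowns
  # field teams sample spectrally pure, canopy-visible crowns: keep crowns
  # that still own their centre pixel after taller-tree-wins rasterization
  if (!is.null(scene$truth)) {
    ctr <- cbind(pmin(pmax(round(crowns$row), 1L), nrow(scene$truth)),
                 pmin(pmax(round(crowns$col), 1L), ncol(scene$truth)))
    visible <- scene$truth[ctr] == crowns$species
    crowns <- crowns[visible, , drop = FALSE]
  }
  if (nrow(crowns) > n_train_crowns)
    crowns <- crowns[sample.int(nrow(crowns), n_train_crowns), , drop = FALSE]

  tr <- extract_training_spectra(cube, crowns, mask, cls_bands, NULL,
                                 core_fraction = 0.8)
  # crown delineation against ground truth: keep the pure pixels of each
  # training crown (overlapping taller neighbours are excluded), emulating
  # expert-drawn crown polygons; the classifier itself never sees the truth
  if (!is.null(scene$truth)) {
    pure <- scene$pool$species$species_id[scene$truth[tr$coords]] == tr$labels
    pure[is.na(pure)] <- FALSE
    tr$spectra <- tr$spectra[pure, , drop = FALSE]
    tr$labels <- tr$labels[pure]
    tr$crown_id <- tr$crown_id[pure]
    tr$coords <- tr$coords[pure, , drop = FALSE]
  }
  tr$labels[!tr$labels %in% abundant] <- "others"
  bn <- brightness_normalize(tr$spectra)
  keep <- setdiff(seq_len(nrow(tr$spectra)), attr(bn, "dropped_rows"))
  labels <- tr$labels[keep]
  coords <- tr$coords[keep, , drop = FALSE]

  mnf <- fit_mnf(bn, coords, groups = tr$crown_id[keep])
  ncomp <- mnf_n_components(mnf, snr_threshold, min_components = 3L)
  scores <- mnf_transform(mnf, bn, ncomp)

  tags <- split_train_test(labels, train_fraction, seed)
  bal <- smote_balance(scores[tags == "train", , drop = FALSE],
                       labels[tags == "train"], seed = seed)
  rf <- train_rf(bal$X, bal$y, mtry_grid, ntree_grid, seed)

  chain <- structure(list(bands = cls_bands, mnf = mnf, n_components = ncomp,
                          rf = rf, ndvi_threshold = ndvi_threshold,
                          abundant = abundant),
                     class = "classifier_chain")
  map <- predict_map(chain, cube, mask)

  test_pred <- predict(rf, scores[tags == "test", , drop = FALSE])
  report <- assess_accuracy(test_pred, labels[tags == "test"])

  list(map = map, report = report, chain = chain,
       test = list(predicted = test_pred, reference = labels[tags == "test"]))
}
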