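#' Spectral cube container
#'
#' A minimal in-memory hyperspectral raster: a row x col x band reflectance
#' array in \[0, 1\], a strictly increasing wavelength vector (nm) and a
#' per-pixel validity mask. Geographic registration (origin of the upper-left
#' pixel centre in degrees, pixel size in degrees) is optional and only
#' needed by the gridding stage.
#'
#' @param reflectance numeric array, dim = c(nrow, ncol, nband).
#' @param wavelengths numeric vector of band centres in nm, strictly increasing.
#' @param mask logical matrix (nrow x ncol); TRUE = valid pixel. Default all TRUE.
#' @param geo optional list(origin_lon, origin_lat, px_deg) for georeferencing.
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(reflectance, wavelengths, mask = NULL, geo = NULL) {
  stopifnot(length(dim(reflectance)) == 3)
  if (dim(reflectance)[3] != length(wavelengths))
    stop("band count must equal wavelength count")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (is.null(mask)) mask <- matrix(TRUE, dim(reflectance)[1], dim(reflectance)[2])
  structure(list(reflectance = reflectance, wavelengths = wavelengths,
                 mask = mask, geo = geo),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("spectral_cube: %d x %d pixels, %d bands (%.0f-%.0f nm), %d valid px\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), sum(x$mask)))
  invisible(x)
}

#' Index of the band nearest to a nominal wavelength
#' @param cube spectral_cube
#' @param nm nominal wavelength (nm)
#' @return integer band index
#' @export
nearest_band <- function(cube, nm) which.min(abs(cube$wavelengths - nm))

band_set <- function(indices, label) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices, label = label), class = "band_set")
}

#' Select usable bands
#'
#' Drops noisy short-wave bands (centre < 411 nm) and the two atmospheric
#' water-absorption windows 1348-1428 nm and 1778-1949 nm. Counts are
#' emergent from the wavelength grid, never hard-coded.
#'
#' @param cube spectral_cube
#' @return band_set with label "usable"
#' @export
select_usable_bands <- function(cube) {
  wl <- cube$wavelengths
  keep <- wl >= 411 & !(wl >= 1348 & wl <= 1428) & !(wl >= 1778 & wl <= 1949)
  if (!any(keep)) stop("no usable bands remain after window filtering")
  band_set(which(keep), "usable")
}

#' Select classification bands
#'
#' Retains usable bands whose centres fall in one of four discriminative
#' regions: 550-650, 750-1250, 1500-1750 and 2000-2250 nm (closed intervals).
#'
#' @param bands band_set from [select_usable_bands()]
#' @param cube spectral_cube the band set indexes into
#' @return band_set with label "classification"
#' @export
select_classification_bands <- function(bands, cube) {
  wl <- cube$wavelengths[bands$indices]
  windows <- rbind(c(550, 650), c(750, 1250), c(1500, 1750), c(2000, 2250))
  keep <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(windows)))
    keep <- keep | (wl >= windows[i, 1] & wl <= windows[i, 2])
  band_set(bands$indices[keep], "classification")
}

#' Brightness normalization (BNORM)
#'
#' Scales each pixel spectrum to unit Euclidean norm, removing multiplicative
#' brightness gradients (canopy illumination geometry) while preserving
#' spectral shape. Idempotent and scale-invariant by construction.
#'
#' @param spectra numeric matrix, pixels x bands.
#' @return matrix of unit-norm rows; all-zero rows are dropped with a warning
#'   and their original positions recorded in attribute `dropped_rows`.
#' @export
brightness_normalize <- function(spectra) {
  spectra <- as.matrix(spectra)
  nrm <- sqrt(rowSums(spectra^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    warning(sprintf("%d all-zero spectra excluded from brightness normalization",
                    length(bad)))
    spectra <- spectra[-bad, , drop = FALSE]
    nrm <- nrm[-bad]
  }
  out <- spectra / nrm
  attr(out, "dropped_rows") <- bad
  out
}

#' Fit a Minimum Noise Fraction transform
#'
#' Noise covariance is estimated from differences of horizontally adjacent
#' pixels, d = (x\[r,c\] - x\[r,c+1\]) / sqrt(2), assuming the signal is
#' locally smooth. The data covariance is whitened by the noise covariance
#' and eigendecomposed; components are ordered by decreasing eigenvalue
#' (signal-to-noise + 1 under the model; pure noise gives eigenvalues near 1).
#'
#' @param spectra pixels x bands matrix (typically brightness-normalized).
#' @param coords integer matrix (pixels x 2) of (row, col) image positions of
#'   each sample, used to find horizontal neighbours for the noise estimate.
#' @param groups optional per-sample grouping (e.g. crown id): only neighbour
#'   pairs within a group enter the noise estimate, so that canopy boundaries
#'   do not inflate it. The shift-difference estimator assumes locally smooth
#'   signal, which holds within a homogeneous canopy patch but not across
#'   crowns of different species at 4 m pixels.
#' @param ridge relative ridge added to a (near-)singular noise covariance;
#'   applied as ridge * mean(diag) * I and logged via a message.
#' @param noise_diff "single" (right neighbour) or "dual" (average of left and
#'   right difference estimates).
#' @return object of class `mnf_model`: centre, forward/backward matrices,
#'   eigenvalues.
#' @export
fit_mnf <- function(spectra, coords, groups = NULL, ridge = 1e-8,
                    noise_diff = c("single", "dual")) {
  noise_diff <- match.arg(noise_diff)
  spectra <- as.matrix(spectra)
  p <- ncol(spectra)
  if (nrow(spectra) < p + 1)
    stop("need at least band-count + 1 samples to fit MNF")
  stopifnot(nrow(coords) == nrow(spectra), ncol(coords) == 2)

  key <- paste(coords[, 1], coords[, 2])
  pair_diffs <- function(dc) {
    idx <- match(paste(coords[, 1], coords[, 2] + dc), key)
    ok <- !is.na(idx)
    if (!is.null(groups)) ok <- ok & !is.na(groups) & groups == groups[idx]
    (spectra[ok, , drop = FALSE] - spectra[idx[ok], , drop = FALSE]) / sqrt(2)
  }
  d <- pair_diffs(1L)
  if (nrow(d) < p + 1)
    stop("too few horizontally adjacent sample pairs for the noise estimate")
  Sn <- stats::cov(d)
  if (noise_diff == "dual") {
    dl <- pair_diffs(-1L)
    Sn <- (Sn + stats::cov(dl)) / 2
  }

  en <- eigen(Sn, symmetric = TRUE)
  tolv <- max(en$values) * 1e-10
  if (any(en$values <= tolv)) {
    message(sprintf("MNF: noise covariance near-singular (min eig %.3g); ridge %.3g applied",
                    min(en$values), ridge * mean(diag(Sn))))
    Sn <- Sn + diag(ridge * mean(diag(Sn)) + tolv, p)
    en <- eigen(Sn, symmetric = TRUE)
  }
  W <- en$vectors %*% diag(1 / sqrt(en$values), p) # noise whitener

  centre <- colMeans(spectra)
  Xc <- sweep(spectra, 2, centre)
  Sw <- crossprod(Xc %*% W) / (nrow(Xc) - 1)      # whitened data covariance
  es <- eigen(Sw, symmetric = TRUE)

  forward <- W %*% es$vectors                      # scores = Xc %*% forward
  backward <- t(es$vectors) %*% diag(sqrt(en$values), p) %*% t(en$vectors)

  structure(list(centre = centre, forward = forward, backward = backward,
                 eigenvalues = es$values, noise_cov = Sn),
            class = "mnf_model")
}

#' @export
print.mnf_model <- function(x, ...) {
  cat(sprintf("mnf_model: %d bands; top eigenvalues %s\n", length(x$centre),
              paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Number of MNF components above an SNR eigenvalue threshold
#' @param model mnf_model
#' @param snr_threshold eigenvalue cut-off (noise-only components sit near 1).
#' @param min_components lower bound on the returned count.
#' @export
mnf_n_components <- function(model, snr_threshold = 2, min_components = 1L) {
  max(min_components, sum(model$eigenvalues > snr_threshold))
}

#' Project spectra into MNF space
#' @param model mnf_model
#' @param spectra pixels x bands matrix
#' @param n_components number of leading components to keep (default all)
#' @export
mnf_transform <- function(model, spectra, n_components = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(model$centre)) stop("band dimension mismatch")
  scores <- sweep(spectra, 2, model$centre) %*% model$forward
  if (!is.null(n_components)) scores <- scores[, seq_len(n_components), drop = FALSE]
  scores
}

#' Reconstruct spectra from MNF scores
#' @param model mnf_model
#' @param scores pixels x components matrix (components beyond those supplied
#'   are treated as zero)
#' @export
mnf_inverse <- function(model, scores) {
  scores <- as.matrix(scores)
  p <- length(model$centre)
  if (ncol(scores) < p) {
    pad <- matrix(0, nrow(scores), p - ncol(scores))
    scores <- cbind(scores, pad)
  }
  sweep(scores %*% model$backward, 2, model$centre, `+`)
}

#' NDVI forest mask
#'
#' NDVI = (R_NIR - R_red) / (R_NIR + R_red) using the bands nearest 860 and
#' 650 nm. Pixels below the threshold (non-forest) or with a zero denominator
#' are masked out, as are pixels already invalid in the cube.
#'
#' @param cube spectral_cube
#' @param threshold NDVI cut-off (0.4 for the drier reserves, 0.6 for the wetter).
#' @return logical matrix; TRUE = forest pixel retained.
#' @export
compute_ndvi_mask <- function(cube, threshold) {
  nir <- cube$reflectance[, , nearest_band(cube, 860)]
  red <- cube$reflectance[, , nearest_band(cube, 650)]
  den <- nir + red
  ndvi <- ifelse(den == 0, -Inf, (nir - red) / den)
  cube$mask & ndvi >= threshold
}

#' Canopy reflectance indices
#'
#' Computes NDVI, CCI = (R531 - R645)/(R531 + R645), NIRv = NDVI x R_NIR,
#' NIRvP = NIRv x PAR and NDWI = (R860 - R1240)/(R860 + R1240) with
#' nearest-band matching. The matched wavelengths are recorded per index.
#'
#' @param cube spectral_cube
#' @param par photosynthetically active radiation scalar or matrix (default 1;
#'   results are then interpreted relatively).
#' @return named list of index rasters (matrices, NA outside the cube mask),
#'   with attribute `wavelengths_used`.
#' @export
compute_indices <- function(cube, par = 1) {
  nr <- dim(cube$reflectance)[1]; nc <- dim(cube$reflectance)[2]
  gb <- function(nm) matrix(cube$reflectance[, , nearest_band(cube, nm)], nr, nc)
  wl <- function(nm) cube$wavelengths[nearest_band(cube, nm)]
  nd <- function(a, b) ifelse(a + b == 0, NA_real_, (a - b) / (a + b))

  nir <- gb(860); red <- gb(650)
  ndvi <- nd(nir, red)
  cci <- nd(gb(531), gb(645))
  nirv <- ndvi * nir
  nirvp <- nirv * par
  ndwi <- nd(gb(860), gb(1240))

  out <- list(NDVI = ndvi, CCI = cci, NIRv = nirv, NIRvP = nirvp, NDWI = ndwi)
  out <- lapply(out, function(m) { m[!cube$mask] <- NA_real_; m })
  attr(out, "wavelengths_used") <- c(
    NIR = wl(860), red = wl(650), w531 = wl(531), w645 = wl(645), w1240 = wl(1240))
  out
}

#' Extract valid-pixel spectra as a matrix
#'
#' @param cube spectral_cube
#' @param bands band_set (default: all bands)
#' @param mask logical matrix overriding the cube mask
#' @return list(spectra = pixels x bands matrix, coords = (row, col) matrix)
#' @export
cube_spectra <- function(cube, bands = NULL, mask = NULL) {
  if (is.null(mask)) mask <- cube$mask
  idx <- which(mask, arr.ind = TRUE)
  bi <- if (is.null(bands)) seq_along(cube$wavelengths) else bands$indices
  flat <- matrix(cube$reflectance, ncol = dim(cube$reflectance)[3])
  pix <- (idx[, 2] - 1L) * nrow(mask) + idx[, 1]
  list(spectra = flat[pix, bi, drop = FALSE], coords = idx)
}
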