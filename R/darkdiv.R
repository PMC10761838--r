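#' Beals smoothing matrix
#'
#' b_ij is the expected probability of species j in plot i given the plot's
#' other species and pairwise co-occurrence frequencies:
#' b_ij = (1 / S_i^(-j)) sum_k (M_jk / N_k) over the species k != j present
#' in plot i, with M_jk the number of plots containing both j and k, N_k the
#' number of plots containing k, and S_i^(-j) the richness of plot i
#' excluding j (b_ij = 0 when that richness is 0). The target species is
#' excluded from both the sum and the richness, the prevailing
#' Beals-smoothing convention.
#'
#' @param X plots x species binary (0/1) matrix
#' @return plots x species matrix of probabilities in \[0, 1\]
#' @export
beals_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 plots and >= 2 species")
  if (!all(X %in% c(0, 1))) stop("X must be a 0/1 presence matrix")
  M <- crossprod(X)              # M[j, k] = plots containing both j and k
  N <- diag(M)                   # occurrences per species
  W <- M / ifelse(N == 0, 1, N)[col(M)] # W[j, k] = M_jk / N_k
  W[, N == 0] <- 0
  B <- X %*% t(W)                # sum_k X_ik M_jk / N_k (includes k = j)
  B <- B - X                     # remove the k = j term (M_jj / N_j = 1)
  Sm <- rowSums(X) - X           # S_i^(-j)
  out <- ifelse(Sm > 0, B / Sm, 0)
  dimnames(out) <- dimnames(X)
  out
}

#' Species-specific dark-diversity thresholds
#'
#' threshold_j = empirical q-quantile (linear interpolation between order
#' statistics) of the Beals values of the plots where species j occurs.
#' Species with zero occurrences are skipped with a warning (threshold NA).
#'
#' @param b Beals matrix from [beals_matrix()]
#' @param X the presence matrix it was computed from
#' @param q quantile level (default 0.05)
#' @return named numeric vector of thresholds
#' @export
species_thresholds <- function(b, X, q = 0.05) {
  X <- as.matrix(X)
  thr <- vapply(seq_len(ncol(X)), function(j) {
    occ <- X[, j] == 1
    if (!any(occ)) return(NA_real_)
    stats::quantile(b[occ, j], q, names = FALSE, type = 7)
  }, 0)
  names(thr) <- colnames(X)
  if (anyNA(thr))
    warning("species with zero occurrences skipped: ",
            paste(colnames(X)[is.na(thr)], collapse = ", "))
  thr
}

#' Dark-diversity membership
#'
#' A plot is eligible when its richness exceeds `min_richness` (the field
#' rule: only plots with more than five abundant species enter the
#' analysis). Species j belongs to the dark diversity of an eligible plot i
#' when it is absent there (X_ij = 0) but its Beals probability reaches its
#' species-specific threshold.
#'
#' @param X plots x species presence matrix
#' @param b Beals matrix
#' @param thresholds per-species thresholds from [species_thresholds()]
#' @param min_richness richness must be strictly greater than this
#' @return list(membership = logical plots x species matrix,
#'   eligible = logical plot vector)
#' @export
dark_diversity <- function(X, b, thresholds, min_richness = 5L) {
  X <- as.matrix(X)
  eligible <- rowSums(X) > min_richness
  thr <- matrix(thresholds, nrow(X), ncol(X), byrow = TRUE)
  membership <- eligible & (X == 0) & !is.na(thr) & (b >= thr)
  dimnames(membership) <- dimnames(X)
  list(membership = membership, eligible = eligible)
}

#' Dark-diversity summaries
#'
#' Mean dark-diversity species count per eligible plot, per-species share of
#' plots carrying it in dark diversity, the species exceeding the listing
#' cut-off (> 15% of eligible plots), and optional per-region plot counts.
#'
#' @param dd result of [dark_diversity()]
#' @param regions optional per-plot region labels (e.g. drier/wetter)
#' @param list_share listing cut-off on the per-species plot share
#' @return object of class `dd_report`
#' @export
dd_summaries <- function(dd, regions = NULL, list_share = 0.15) {
  m <- dd$membership
  n_eligible <- sum(dd$eligible)
  per_plot <- rowSums(m)
  mean_per_plot <- if (n_eligible > 0) sum(m) / n_eligible else 0
  species_share <- if (n_eligible > 0) colSums(m) / n_eligible else
    stats::setNames(numeric(ncol(m)), colnames(m))
  listed <- names(species_share)[species_share > list_share]
  region_counts <- NULL
  if (!is.null(regions)) {
    has_dd <- per_plot > 0
    region_counts <- stats::aggregate(
      data.frame(plots_eligible = as.integer(dd$eligible),
                 plots_with_dd = as.integer(has_dd)),
      by = list(region = regions), FUN = sum)
  }
  structure(list(mean_per_plot = mean_per_plot, per_plot = per_plot,
                 species_share = species_share, listed = listed,
                 region_counts = region_counts, n_eligible = n_eligible),
            class = "dd_report")
}

#' @export
print.dd_report <- function(x, ...) {
  cat(sprintf("dd_report: %d eligible plots, mean %.2f DD species/plot, %d species > listing cut-off\n",
              x$n_eligible, x$mean_per_plot, length(x$listed)))
  invisible(x)
}
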