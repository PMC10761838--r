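#' Central 95% trim of a value vector
#'
#' Keeps values inside the 2.5-97.5 empirical percentiles (linear
#' interpolation). This is how "retain the 95% interval of values" is read
#' here: a trim of the pixel-value distribution, which preserves multiple
#' values for the subsequent averaging step (a CI of the mean would not).
#'
#' @param x numeric vector
#' @param level central mass to keep
#' @export
trim_central <- function(x, level = 0.95) {
  if (!length(x)) return(x)
  a <- (1 - level) / 2
  q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  x[x >= q[1] & x <= q[2]]
}

#' Assemble the species trait table
#'
#' Per species and PA: index traits (CCI, NIRvP, NDWI) are crown-pixel
#' values trimmed to their central 95% and averaged; maximum DBH is the mean
#' of the two largest field DBH records. A species occurring in more than
#' one PA gets the mean of its per-PA means. Wood density and phenology are
#' constant across PAs.
#'
#' @param records field records: data.frame(species_id, pa, dbh_m)
#' @param pixels crown-pixel index values: data.frame(species_id, pa, CCI,
#'   NIRvP, NDWI)
#' @param species_info data.frame(species_id, wood_density, phenology)
#'   with phenology coded 0 = deciduous, 1 = evergreen
#' @return object of class `trait_table`: one row per species with
#'   wood_density, phenology, max_dbh, CCI, NIRvP, NDWI
#' @export
build_trait_table <- function(records, pixels, species_info) {
  sp <- sort(unique(c(records$species_id, pixels$species_id)))
  missing_info <- setdiff(sp, species_info$species_id)
  if (length(missing_info))
    stop("no wood density/phenology source for species: ",
         paste(missing_info, collapse = ", "))

  per_pa_mean <- function(df, value_col, fun) {
    # fun aggregates the values of one species in one PA
    out <- stats::aggregate(df[[value_col]],
                            by = list(species_id = df$species_id, pa = df$pa),
                            FUN = fun)
    stats::aggregate(out$x, by = list(species_id = out$species_id), FUN = mean)
  }

  max_dbh_rule <- function(v) mean(utils::head(sort(v, decreasing = TRUE), 2))
  trim_mean <- function(v) mean(trim_central(v))

  dbh <- per_pa_mean(records, "dbh_m", max_dbh_rule)
  idx <- lapply(c("CCI", "NIRvP", "NDWI"), function(tr)
    per_pa_mean(pixels, tr, trim_mean))
  names(idx) <- c("CCI", "NIRvP", "NDWI")

  out <- data.frame(species_id = sp, stringsAsFactors = FALSE)
  info <- species_info[match(sp, species_info$species_id), ]
  out$wood_density <- info$wood_density
  out$phenology <- info$phenology
  out$max_dbh <- dbh$x[match(sp, dbh$species_id)]
  for (tr in names(idx)) out[[tr]] <- idx[[tr]]$x[match(sp, idx[[tr]]$species_id)]

  incomplete <- sp[!stats::complete.cases(out)]
  if (length(incomplete))
    warning("species with missing trait sources (kept as NA): ",
            paste(incomplete, collapse = ", "))
  structure(out, class = c("trait_table", "data.frame"))
}

#' Community-weighted mean of a trait
#'
#' Sum of p_i t_i with p_i the relative abundances; a convex combination, so
#' always inside the present species' trait range and invariant to abundance
#' rescaling.
#'
#' @param abundance named species abundance vector (one community)
#' @param traits named trait values covering the present species
#' @return weighted mean, or NA with a warning for a zero-total community
#' @export
cwm <- function(abundance, traits) {
  tot <- sum(abundance)
  if (tot == 0) { warning("zero-total community; CWM undefined"); return(NA_real_) }
  present <- names(abundance)[abundance > 0]
  miss <- present[!present %in% names(traits) | is.na(traits[present])]
  if (length(miss)) stop("trait missing for present species: ",
                         paste(miss, collapse = ", "))
  sum(abundance[present] / tot * traits[present])
}

#' Functional richness: convex hull volume in 3-D trait space
#'
#' Exact hull volume of the supplied trait points (incremental hull).
#' Fewer than four affinely independent points give volume 0 with a
#' degeneracy flag; duplicate points collapse silently.
#'
#' @param traits species x 3 numeric matrix
#' @return list(volume, vertices = row indices of hull vertices, degenerate)
#' @export
fric <- function(traits) {
  traits <- as.matrix(traits)
  if (ncol(traits) != 3) stop("fric expects exactly 3 traits")
  hull3d_cpp(traits)
}

#' Functional divergence
#'
#' With G the centroid of the convex-hull vertices and d_i the Euclidean
#' distance of species i to G: dbar = mean(d_i) (unweighted),
#' Dd = sum p_i (d_i - dbar), D|d| = sum p_i |d_i - dbar|, and
#' FDiv = (Dd + dbar) / (D|d| + dbar). Equals 1 when all species are
#' equidistant from G, and grows as abundance concentrates on species far
#' from the centre of gravity.
#'
#' @param traits species x 3 matrix
#' @param abundance abundance vector aligned with the rows of `traits`
#' @return list(fdiv, degenerate)
#' @export
fdiv <- function(traits, abundance) {
  traits <- as.matrix(traits)
  stopifnot(length(abundance) == nrow(traits))
  hull <- fric(traits)
  if (hull$degenerate) return(list(fdiv = NA_real_, degenerate = TRUE))
  G <- colMeans(traits[hull$vertices, , drop = FALSE])
  d <- sqrt(rowSums(sweep(traits, 2, G)^2))
  p <- abundance / sum(abundance)
  dbar <- mean(d)
  dd <- sum(p * (d - dbar))
  dad <- sum(p * abs(d - dbar))
  list(fdiv = (dd + dbar) / (dad + dbar), degenerate = FALSE)
}

#' Per-community functional diversity metrics
#'
#' Standardizes the trait columns to zero mean and unit variance over the
#' species pool (so traits with different units contribute comparably),
#' then computes FRic and FDiv per community over its present species.
#'
#' @param counts communities x species abundance matrix
#' @param traits species x 3 trait matrix (rownames = species ids matching
#'   the columns of `counts`)
#' @param standardize standardize traits over the pool first (default TRUE)
#' @return data.frame(community, fric, fdiv, degenerate, n_species)
#' @export
compute_fd <- function(counts, traits, standardize = TRUE) {
  counts <- as.matrix(counts)
  traits <- as.matrix(traits)
  traits <- traits[colnames(counts), , drop = FALSE]
  if (anyNA(traits)) stop("traits missing for some species in the count matrix")
  if (standardize) traits <- scale(traits)
  out <- data.frame(community = rownames(counts) %||% seq_len(nrow(counts)),
                    fric = NA_real_, fdiv = NA_real_,
                    degenerate = TRUE, n_species = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(counts))) {
    pres <- which(counts[i, ] > 0)
    out$n_species[i] <- length(pres)
    if (length(pres) < 4) next
    tp <- traits[pres, , drop = FALSE]
    h <- fric(tp)
    out$fric[i] <- h$volume
    fd <- fdiv(tp, counts[i, pres])
    out$fdiv[i] <- fd$fdiv
    out$degenerate[i] <- h$degenerate
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group means of functional diversity metrics
#'
#' Arithmetic mean of FRic and FDiv over the defined (non-degenerate) cells
#' of each group; degenerate cells are excluded from the means and counted.
#'
#' @param fd data.frame from [compute_fd()]
#' @param grouping vector of group labels (PA or assemblage type), one per row
#' @return data.frame(group, mean_fric, mean_fdiv, n, n_degenerate)
#' @export
summarize_fd <- function(fd, grouping) {
  stopifnot(length(grouping) == nrow(fd))
  out <- lapply(split(seq_len(nrow(fd)), grouping), function(idx) {
    sub <- fd[idx, ]
    ok <- !sub$degenerate & !is.na(sub$fric)
    if (!any(ok)) warning("group with no defined functional diversity values")
    data.frame(mean_fric = if (any(ok)) mean(sub$fric[ok]) else NA_real_,
               mean_fdiv = if (any(ok)) mean(sub$fdiv[ok], na.rm = TRUE) else NA_real_,
               n = nrow(sub), n_degenerate = sum(!ok))
  })
  res <- do.call(rbind, out)
  res$group <- names(out)
  res[, c("group", "mean_fric", "mean_fdiv", "n", "n_degenerate")]
}
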