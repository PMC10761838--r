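#' Correspondence analysis of a cells x species table
#'
#' SVD of the standardized residual matrix
#' S = D_r^{-1/2} (P - r c') D_c^{-1/2} with P = N / n. Row and column
#' scores are returned in principal coordinates, column scores additionally
#' in standard coordinates (used to project supplementary rows). Total
#' inertia equals the chi-square statistic of the table divided by its grand
#' total, and per-axis inertias are the squared singular values.
#'
#' @param N non-negative cells x species matrix; all-zero rows/columns are
#'   dropped with a warning
#' @return object of class `ca_result`
#' @export
correspondence_analysis <- function(N) {
  N <- as.matrix(N)
  if (any(N < 0)) stop("table must be non-negative")
  zr <- rowSums(N) == 0; zc <- colSums(N) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("dropping %d all-zero rows and %d all-zero columns",
                    sum(zr), sum(zc)))
    N <- N[!zr, !zc, drop = FALSE]
  }
  if (!nrow(N) || !ncol(N) || sum(N) == 0) stop("table has rank 0")
  n <- sum(N)
  P <- N / n
  r <- rowSums(P); cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  keep <- which(sv$d > max(sv$d[1], 1) * 1e-12)
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]

  row_std <- diag(1 / sqrt(r)) %*% U           # standard coordinates
  col_std <- diag(1 / sqrt(cm)) %*% V
  row_scores <- sweep(row_std, 2, d, "*")      # principal coordinates
  col_scores <- sweep(col_std, 2, d, "*")
  rownames(row_scores) <- rownames(N); rownames(col_scores) <- colnames(N)
  rownames(col_std) <- colnames(N)

  inertia <- d^2
  structure(list(row_scores = row_scores, col_scores = col_scores,
                 col_std = col_std, singular_values = d,
                 inertia = inertia, inertia_share = inertia / sum(inertia),
                 total_inertia = sum(inertia),
                 row_mass = r, col_mass = cm,
                 species = colnames(N)),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("ca_result: %d axes, total inertia %.4f; leading shares %s\n",
              length(x$singular_values), x$total_inertia,
              paste(sprintf("%.1f%%", 100 * utils::head(x$inertia_share, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Project new rows onto fitted CA axes as supplementary points
#'
#' New row profiles are multiplied by the fitted column standard
#' coordinates; a training row projected this way recovers its fitted
#' principal coordinates exactly, and proportional rows share a score
#' (profile invariance).
#'
#' @param ca ca_result
#' @param N_new cells x species matrix over the fitted species set
#' @return matrix of supplementary row scores (principal coordinates)
#' @export
project_rows <- function(ca, N_new) {
  N_new <- as.matrix(N_new)
  if (ncol(N_new) != nrow(ca$col_std) ||
      (!is.null(colnames(N_new)) && !is.null(ca$species) &&
         !identical(colnames(N_new), ca$species)))
    stop("species set must match the fitted CA")
  rs <- rowSums(N_new)
  if (any(rs == 0)) stop("cannot project all-zero rows")
  profiles <- N_new / rs
  out <- profiles %*% ca$col_std
  rownames(out) <- rownames(N_new)
  out
}

#' Assemblage typing by Ward clustering with bootstrap uncertainty
#'
#' Ward linkage (ward.D2) on Euclidean distances between row scores
#' (typically the first five CA axes), cut into k types. Per-cell uncertainty
#' is the fraction of bootstrap re-clusterings (cells resampled with
#' replacement, types matched to the original by maximum overlap) in which
#' the cell's type changes; the reference analysis reports mean per-type
#' uncertainties between 0 and 0.08%.
#'
#' @param scores cells x axes matrix
#' @param k number of assemblage types
#' @param n_boot bootstrap replicates
#' @param seed integer seed
#' @return object of class `assemblage_typing`: per-cell type labels and
#'   uncertainty, per-type mean uncertainty, the hclust tree
#' @export
assemblage_types <- function(scores, k = 4L, n_boot = 100L, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k > n) stop("k exceeds the number of cells")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  types <- stats::cutree(hc, k = k)

  changed <- numeric(n); seen <- numeric(n)
  if (n_boot > 0 && k > 1) {
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      uidx <- unique(idx)
      if (length(uidx) <= k) next
      hb <- stats::hclust(stats::dist(scores[uidx, , drop = FALSE]), method = "ward.D2")
      tb <- stats::cutree(hb, k = k)
      # match bootstrap types to original by greedy maximum overlap
      ov <- table(factor(types[uidx], seq_len(k)), factor(tb, seq_len(k)))
      mapping <- integer(k)
      ovw <- ov
      for (step in seq_len(k)) {
        best <- which(ovw == max(ovw), arr.ind = TRUE)[1, ]
        mapping[best[2]] <- best[1]
        ovw[best[1], ] <- -1; ovw[, best[2]] <- -1
      }
      relabelled <- mapping[tb]
      seen[uidx] <- seen[uidx] + 1
      changed[uidx] <- changed[uidx] + (relabelled != types[uidx])
    }
  }
  uncertainty <- ifelse(seen > 0, changed / seen, 0)
  type_uncertainty <- vapply(seq_len(k), function(t)
    mean(uncertainty[types == t]), 0)

  structure(list(types = types, uncertainty = uncertainty,
                 type_uncertainty = type_uncertainty, k = k, tree = hc,
                 n_boot = n_boot, seed = seed),
            class = "assemblage_typing")
}

#' @export
print.assemblage_typing <- function(x, ...) {
  cat(sprintf("assemblage_typing: %d types over %d cells; mean uncertainty %s\n",
              x$k, length(x$types),
              paste(sprintf("%.3f", x$type_uncertainty), collapse = ", ")))
  invisible(x)
}

#' Hierarchical tree as nested Newick-like text
#' @param typing assemblage_typing (or any object with an hclust `tree`)
#' @return single character string
#' @export
typing_tree_text <- function(typing) {
  hc <- typing$tree
  lab <- if (is.null(hc$labels)) as.character(seq_along(hc$order)) else hc$labels
  build <- function(i) {
    if (i < 0) return(lab[-i])
    sprintf("(%s,%s)", build(hc$merge[i, 1]), build(hc$merge[i, 2]))
  }
  paste0(build(nrow(hc$merge)), ";")
}

#' Sorensen similarity between assemblage types
#'
#' Each community (a group/type combination) is reduced to its species set:
#' species with abundance > 0 in at least `occupancy` of the community's
#' cells. Similarity = 2 shared / (S1 + S2), in percent.
#'
#' @param types per-cell type labels
#' @param counts cells x species abundance matrix (rows match `types`)
#' @param groups optional per-cell grouping (e.g. PA ids); communities are
#'   then group:type combinations
#' @param occupancy minimum occupied-cell share for a species to count
#' @return symmetric percentage matrix with NA for empty communities
#' @export
type_similarity <- function(types, counts, groups = NULL, occupancy = 0.05) {
  counts <- as.matrix(counts)
  key <- if (is.null(groups)) paste0("type", types) else paste0(groups, ":type", types)
  comms <- sort(unique(key))
  sets <- lapply(comms, function(cm) {
    sub <- counts[key == cm, , drop = FALSE]
    colnames(sub)[colMeans(sub > 0) >= occupancy]
  })
  names(sets) <- comms
  m <- matrix(NA_real_, length(comms), length(comms), dimnames = list(comms, comms))
  for (i in seq_along(comms)) for (j in seq_along(comms)) {
    s1 <- sets[[i]]; s2 <- sets[[j]]
    if (!length(s1) || !length(s2)) next
    m[i, j] <- 100 * 2 * length(intersect(s1, s2)) / (length(s1) + length(s2))
  }
  m
}
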