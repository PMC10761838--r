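# Lightweight Poisson IRLS used throughout the supervised-component fits.
# Returns coefficients, log-likelihood and fitted means; a tiny ridge keeps
# the weighted normal equations solvable on collinear designs.
poisson_irls <- function(Z, y, tol = 1e-10, max_iter = 60, ridge = 1e-10) {
  Z <- as.matrix(Z)
  beta <- numeric(ncol(Z))
  beta[1] <- log(mean(y) + 1e-8)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    A <- crossprod(Z, W * Z)
    diag(A) <- diag(A) + ridge * (mean(diag(A)) + 1)
    beta <- drop(solve(A, crossprod(Z, W * z)))
    eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
    ll <- sum(y * eta - exp(eta) - lgamma(y + 1))
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  mu <- exp(eta)
  ll_sat <- sum(ifelse(y > 0, y * log(y) - y, 0) - lgamma(y + 1))
  list(beta = beta, loglik = ll, mu = mu, deviance = 2 * (ll_sat - ll))
}

# structural relevance phi(u): variable-powered inertia of the component
# Xu in the standardized covariates; l = 1 reduces to u'S^2u / u'Su whose
# maximizer is the first principal component.
.phi_grad <- function(u, S, l) {
  Su <- drop(S %*% u)
  q <- drop(crossprod(u, Su))
  a <- Su^2 / q
  phi <- sum(a^l)
  grad <- numeric(length(u))
  for (j in seq_along(a)) {
    ga <- (2 * Su[j] * S[, j]) / q - a[j] * (2 * Su) / q
    grad <- grad + l * a[j]^(l - 1) * ga
  }
  list(phi = phi, grad = grad)
}

# goodness-of-fit psi(u): summed per-species Poisson log-likelihood gain of
# adding the component f = Xu to the previous components and extra
# covariates. The gradient uses the envelope theorem: at the per-species
# optimum, d psi / du = sum_s gamma_s X'(y_s - mu_s).
.psi_grad <- function(u, Xs, Y, base, null_ll) {
  f <- drop(Xs %*% u)
  Z <- cbind(base, f)
  fc <- ncol(Z)
  psi <- 0
  grad <- numeric(ncol(Xs))
  for (sidx in seq_len(ncol(Y))) {
    fit <- poisson_irls(Z, Y[, sidx])
    psi <- psi + max(fit$loglik - null_ll[sidx], 0)
    grad <- grad + fit$beta[fc] * drop(crossprod(Xs, Y[, sidx] - fit$mu))
  }
  list(psi = psi, grad = grad)
}

#' Fit a supervised-component GLM for multivariate species abundances
#'
#' Builds K unit-norm components u_h over the standardized covariates, each
#' maximizing crit(u) = s log phi(u) + (1 - s) log psi(u): phi is the
#' variable-powered inertia of Xu among the covariates (structural relevance,
#' power l) and psi the summed per-species Poisson log-likelihood gain of
#' adding Xu to the previous components and extra covariates (goodness of
#' fit). Optimization is a projected iterated normed gradient with step
#' halving, so the criterion is non-decreasing at every accepted step;
#' subsequent components are constrained orthogonal to previous ones in the
#' X'X metric. Per-species Poisson log-link regressions are refitted on the
#' final components plus extras.
#'
#' @param X cells x covariates matrix (standardized internally)
#' @param Y cells x species non-negative integer counts
#' @param extra optional cells x additional-covariates matrix entering the
#'   GLMs directly, outside component construction (elevation, soil)
#' @param K number of components (<= rank of X)
#' @param s fit-vs-structure trade-off in \[0, 1\] (1 = pure structure: the
#'   first component is then the first principal component when l = 1)
#' @param l structural relevance power (>= 1)
#' @param tol convergence tolerance on the loading change
#' @param max_iter maximum optimizer iterations per component
#' @param seed integer seed (recorded; the fit itself is deterministic)
#' @return object of class `scglr_model`
#' @export
fit_scglr <- function(X, Y, extra = NULL, K = 2L, s = 0.5, l = 1,
                      tol = 1e-6, max_iter = 200L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed")
  if (any(Y < 0) || any(Y != round(Y))) stop("Y must be non-negative integer counts")
  if (s < 0 || s > 1 || l < 1) stop("need 0 <= s <= 1 and l >= 1")
  n <- nrow(X); p <- ncol(X)
  if (!is.null(extra)) extra <- as.matrix(extra)

  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, stats::sd)
  sd_x[sd_x == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  rk <- qr(Xs)$rank
  if (K > rk) stop("K exceeds rank(X) = ", rk)
  S <- crossprod(Xs) / n
  G <- crossprod(Xs) # X'X metric for the orthogonality constraint

  crit_fun <- function(u, base, null_ll) {
    ph <- if (s > 0) .phi_grad(u, S, l) else list(phi = 1, grad = 0)
    ps <- if (s < 1) .psi_grad(u, Xs, Y, base, null_ll) else list(psi = 1, grad = 0)
    psi_e <- ps$psi + 1e-8
    list(crit = s * log(ph$phi) + (1 - s) * log(psi_e),
         grad = s * ph$grad / ph$phi + (1 - s) * ps$grad / psi_e)
  }

  U <- matrix(0, p, K)
  Fm <- matrix(0, n, K)
  conv <- logical(K); iters <- integer(K); crit_trace <- vector("list", K)
  sv <- svd(Xs)

  for (h in seq_len(K)) {
    if (h > 1) {
      D <- G %*% U[, seq_len(h - 1), drop = FALSE]
      Q <- qr.Q(qr(D))
      proj <- function(v) v - Q %*% crossprod(Q, v)
    } else proj <- identity

    base <- cbind(rep(1, n), if (h > 1) Fm[, seq_len(h - 1), drop = FALSE], extra)
    null_ll <- if (s < 1)
      vapply(seq_len(ncol(Y)), function(j) poisson_irls(base, Y[, j])$loglik, 0)
    else NULL

    u <- drop(proj(sv$v[, 1]))
    if (sqrt(sum(u^2)) < 1e-10) u <- drop(proj(sv$v[, min(h, ncol(sv$v))]))
    u <- u / sqrt(sum(u^2))
    cg <- crit_fun(u, base, null_ll)
    trace_h <- cg$crit
    alpha <- 1; stalled <- 0L

    for (it in seq_len(max_iter)) {
      g <- drop(proj(cg$grad))
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) { conv[h] <- TRUE; break }
      g <- g / gn
      accepted <- FALSE
      for (half in 1:25) {
        ut <- drop(proj(u + alpha * g))
        utn <- sqrt(sum(ut^2))
        if (utn < 1e-12) { alpha <- alpha / 2; next }
        ut <- ut / utn
        if (sum(ut * u) < 0) ut <- -ut
        ct <- crit_fun(ut, base, null_ll)
        if (ct$crit >= cg$crit - 1e-12) {
          step <- sqrt(sum((ut - u)^2))
          gain <- ct$crit - cg$crit
          u <- ut; cg <- ct; accepted <- TRUE
          trace_h <- c(trace_h, ct$crit)
          stalled <- if (gain < 1e-9 * (abs(ct$crit) + 1)) stalled + 1L else 0L
          if (step < tol || stalled >= 3L) conv[h] <- TRUE
          alpha <- min(alpha * 2, 4)
          break
        }
        alpha <- alpha / 2
      }
      iters[h] <- it
      if (!accepted) { conv[h] <- TRUE; break }
      if (conv[h]) break
    }
    if (!conv[h])
      warning(sprintf("component %d: optimizer did not converge in %d iterations; best iterate kept",
                      h, max_iter))
    U[, h] <- u
    Fm[, h] <- drop(Xs %*% u)
    crit_trace[[h]] <- trace_h
  }

  design <- cbind(`(Intercept)` = 1, Fm, extra)
  colnames(design)[1 + seq_len(K)] <- paste0("comp", seq_len(K))
  fits <- lapply(seq_len(ncol(Y)), function(j) poisson_irls(design, Y[, j]))
  B <- vapply(fits, `[[`, numeric(ncol(design)), "beta")
  rownames(B) <- colnames(design)
  colnames(B) <- colnames(Y)
  fitted <- exp(pmin(design %*% B, 30))
  deviance <- vapply(fits, `[[`, 0, "deviance")

  cross_fx <- list(fx = crossprod(Fm, Xs), ff = colSums(Fm^2),
                   total = sum(Xs^2))

  structure(list(mean = mu_x, sd = sd_x, loadings = U, components = Fm,
                 coefficients = B, fitted = fitted, deviance = deviance,
                 cross_fx = cross_fx,
                 K = K, s = s, l = l, rank = rk,
                 n_extra = if (is.null(extra)) 0L else ncol(extra),
                 covariate_names = colnames(X), species = colnames(Y),
                 converged = conv, iterations = iters,
                 crit_trace = crit_trace, seed = seed),
            class = "scglr_model")
}

#' @export
print.scglr_model <- function(x, ...) {
  cat(sprintf("scglr_model: K = %d components over %d covariates, %d species (s = %.2f, l = %g)\n",
              x$K, length(x$mean), ncol(x$coefficients), x$s, x$l))
  invisible(x)
}

#' Predict expected species counts from a fitted model
#' @param model scglr_model
#' @param X_new cells x covariates matrix (training schema and units)
#' @param extra_new matching additional covariates (if the model used any)
#' @return cells x species matrix of expected counts
#' @export
predict_abundance <- function(model, X_new, extra_new = NULL) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$mean)) stop("covariate schema mismatch")
  if (model$n_extra > 0) {
    if (is.null(extra_new) || ncol(as.matrix(extra_new)) != model$n_extra)
      stop("extra covariate schema mismatch")
    extra_new <- as.matrix(extra_new)
  }
  Xs <- sweep(sweep(X_new, 2, model$mean), 2, model$sd, "/")
  Fm <- Xs %*% model$loadings
  design <- cbind(1, Fm, extra_new)
  exp(pmin(design %*% model$coefficients, 30))
}

#' Per-component share of standardized-covariate inertia
#'
#' share_h = || P_{f_h} X ||^2 / || X ||^2 (percent), the inertia of the
#' standardized covariates captured by regressing them on component h.
#' Components are mutually orthogonal, so the cumulative share is the
#' inertia captured by their span and reaches 100% at K = rank(X).
#'
#' @param model scglr_model
#' @return data.frame(component, share, cumulative), shares in percent
#' @export
component_inertia <- function(model) {
  cp <- model$cross_fx
  share <- 100 * vapply(seq_len(model$K), function(h)
    sum(cp$fx[h, ]^2) / cp$ff[h] / cp$total, 0)
  data.frame(component = seq_len(model$K), share = share,
             cumulative = cumsum(share))
}

#' Ward spatial blocks for leave-one-block-out cross-validation
#'
#' Ward linkage (ward.D2) on Euclidean distances between cell coordinates,
#' cut into `n_blocks` spatially compact clusters. Deterministic.
#'
#' @param coords cells x 2 matrix (lon, lat)
#' @param n_blocks number of blocks (23 in the reference analysis)
#' @return integer block label per cell
#' @export
make_spatial_blocks <- function(coords, n_blocks = 23L) {
  coords <- as.matrix(coords)
  if (n_blocks > nrow(coords)) stop("n_blocks exceeds the number of cells")
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  stats::cutree(hc, k = n_blocks)
}

#' Leave-one-block-out cross-validation of the supervised-component GLM
#'
#' For each spatial block the model is refitted on the remaining cells and
#' the held-out cells predicted; held-out predictions are pooled across
#' folds (every cell used exactly once) before correlating observed and
#' predicted counts per species with Spearman's rank correlation.
#'
#' @param X,Y,extra as in [fit_scglr()]
#' @param blocks integer block labels from [make_spatial_blocks()]
#' @param K,s,l,tol,max_iter model configuration
#' @return object of class `scglr_cv`: per-species rho, median rho_cv,
#'   pooled predictions
#' @export
cross_validate <- function(X, Y, extra = NULL, blocks, K = 2L, s = 0.5, l = 1,
                           tol = 1e-6, max_iter = 100L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (length(unique(blocks)) < 2) stop("need at least 2 blocks")
  pred <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (b in unique(blocks)) {
    hold <- blocks == b
    fit <- fit_scglr(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                     extra = if (!is.null(extra)) extra[!hold, , drop = FALSE],
                     K = K, s = s, l = l, tol = tol, max_iter = max_iter)
    pred[hold, ] <- predict_abundance(fit, X[hold, , drop = FALSE],
                                      if (!is.null(extra)) extra[hold, , drop = FALSE])
  }
  rho <- vapply(seq_len(ncol(Y)), function(j) {
    if (all(Y[, j] == 0) || stats::sd(pred[, j]) == 0) return(NA_real_)
    suppressWarnings(stats::cor(Y[, j], pred[, j], method = "spearman"))
  }, 0)
  names(rho) <- colnames(Y)
  structure(list(rho = rho, median_rho = stats::median(rho, na.rm = TRUE),
                 predicted = pred, blocks = blocks, K = K, s = s, l = l),
            class = "scglr_cv")
}

#' @export
print.scglr_cv <- function(x, ...) {
  cat(sprintf("scglr_cv: %d blocks, median rho_cv = %.3f (%d species)\n",
              length(unique(x$blocks)), x$median_rho, length(x$rho)))
  invisible(x)
}

#' Choose the component count by cross-validated median rho
#' @param X,Y,extra,blocks as in [cross_validate()]
#' @param K_grid candidate component counts
#' @param ... passed to [cross_validate()]
#' @return list(K, scores) with the grid of median rho values
#' @export
select_k_scglr <- function(X, Y, extra = NULL, blocks, K_grid = 1:6, ...) {
  K_grid <- K_grid[K_grid <= qr(scale(as.matrix(X)))$rank]
  scores <- vapply(K_grid, function(k)
    cross_validate(X, Y, extra, blocks, K = k, ...)$median_rho, 0)
  list(K = K_grid[which.max(scores)],
       scores = stats::setNames(scores, paste0("K", K_grid)))
}
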