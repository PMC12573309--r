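#' Adjusted cumulative percentage of explained variance
#'
#' Fraction of a view's total variance captured by the span of the first
#' latent score vectors: `trace(M' P M) / trace(M' M)` where `P` is the
#' orthogonal projector onto the span of the scores and `M` the original
#' (undeflated, standardized) matrix. Because sparse loadings are not
#' orthogonal, the projector-based adjustment avoids double-counting shared
#' variance; the quantity is nondecreasing in the number of components and
#' depends only on the span of the scores.
#'
#' @param m numeric matrix (the original standardized view).
#' @param scores matrix whose columns are the unit-norm latent score vectors
#'   of components `1..k` (or `NULL` / zero columns for `k = 0`).
#' @return A fraction in `[0, 1]`.
#' @export
adj_cpev <- function(m, scores) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (is.null(scores) || NCOL(scores) == 0L || length(scores) == 0L) return(0)
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(m))
    stop("scores must have one row per row of the matrix")
  keep <- colSums(scores^2) > 0
  if (!any(keep)) return(0)
  qrS <- qr(scores[, keep, drop = FALSE])
  Q <- qr.Q(qrS)[, seq_len(qrS$rank), drop = FALSE]
  sum(crossprod(Q, m)^2) / sum(m^2)
}

as_sparsity_grid <- function(grid) {
  if (is.data.frame(grid)) grid <- as.matrix(grid)
  if (is.list(grid) && !is.matrix(grid))
    grid <- do.call(rbind, lapply(grid, function(g) as.integer(g[1:2])))
  if (is.numeric(grid) && is.null(dim(grid)) && length(grid) == 2L)
    grid <- matrix(grid, 1L)
  grid <- matrix(as.integer(grid), ncol = 2L,
                 dimnames = list(NULL, c("px", "qy")))
  if (nrow(grid) < 1L) stop("sparsity grid must be non-empty")
  grid
}

#' Select sparsity levels by individual-level cross-validation
#'
#' For each component in turn, evaluates every `(px, qy)` pair in the grid
#' by k-fold cross-validation where folds partition \emph{individuals} (all
#' visits of an individual stay together — required for valid clustered CV).
#' The out-of-fold criterion is the aligned canonical correlation: on the
#' held-out individuals, the correlation between their X scores
#' `X_test w_x` and the trajectory-predicted latent values of the other view
#' on the same rows (fixed-effect curve only, since held-out individuals are
#' unseen by the trajectory fit). The pair with the largest mean score wins;
#' ties go to the sparser pair (smaller `px + qy`, then smaller `px`). The
#' chosen pair is refitted on the full data and both views are deflated
#' before the next component is tuned.
#'
#' Fold assignment depends only on the seed and the sorted individual ids,
#' never on the feature values.
#'
#' @param data a [paired_longitudinal()].
#' @param grid matrix/data frame with columns `px`, `qy`, or a list of
#'   pairs.
#' @param n_folds number of folds (>= 2).
#' @param k number of components to tune sequentially.
#' @param spec_x,spec_y [trajectory_spec()]s.
#' @param seed integer seed (fold assignment and NIPALS initializations).
#' @param tol,max_iter,standardize,weight_update passed to the fitter.
#' @return An object of class `cv_tosccamm`: `grid`, `scores` (array
#'   pair x component), `se`, `chosen` (k x 2 matrix), `fit` (the full-data
#'   [tosccamm()] fit at the chosen sparsity), `n_folds`, `seed`, `folds`.
#' @export
cv_select <- function(data, grid, n_folds = 5L, k = 1L,
                      spec_x = trajectory_spec("random_intercept_linear"),
                      spec_y = spec_x, seed, tol = 1e-6, max_iter = 100L,
                      standardize = TRUE, weight_update = "cov") {
  stopifnot(inherits(data, "paired_longitudinal"))
  if (missing(seed)) stop("'seed' is required")
  seed <- as.integer(seed)
  grid <- as_sparsity_grid(grid)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  k <- as.integer(k)

  if (standardize) {
    X0 <- standardize_columns(data$x)$view$features
    Y0 <- standardize_columns(data$y)$view$features
  } else {
    X0 <- data$x$features; Y0 <- data$y$features
  }
  idx <- data$x$ids; tx <- data$x$times
  idy <- data$y$ids; ty <- data$y$times

  uids <- sort(unique(c(idx, idy)))
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep_len(seq_len(n_folds), length(uids))),
                             uids)

  npair <- nrow(grid)
  scores <- se <- matrix(NA_real_, npair, k,
                         dimnames = list(paste0("(", grid[, 1L], ",", grid[, 2L], ")"),
                                         paste0("comp", seq_len(k))))
  chosen <- matrix(NA_integer_, k, 2L, dimnames = list(NULL, c("px", "qy")))
  components <- vector("list", k)

  Xd <- X0; Yd <- Y0
  for (kk in seq_len(k)) {
    init_kk <- local({ set.seed(seed + 7919L * kk); stats::rnorm(ncol(X0)) })
    for (g in seq_len(npair)) {
      px <- grid[g, 1L]; qy <- grid[g, 2L]
      fold_scores <- rep(NA_real_, n_folds)
      for (f in seq_len(n_folds)) {
        test_ids <- uids[fold_of == f]
        if (length(test_ids) < 2L) {
          warning("fold ", f, " has fewer than 2 test individuals; skipped")
          next
        }
        tr_x <- !(idx %in% test_ids); te_x <- idx %in% test_ids
        tr_y <- !(idy %in% test_ids)
        if (sum(te_x) < 3L || sum(tr_x) < 3L || sum(tr_y) < 3L) {
          warning("fold ", f, " leaves too few rows; skipped")
          next
        }
        comp <- tryCatch(
          nipals_component_mat(Xd[tr_x, , drop = FALSE], Yd[tr_y, , drop = FALSE],
                               idx[tr_x], tx[tr_x], idy[tr_y], ty[tr_y],
                               px, qy, spec_x, spec_y, init = init_kk,
                               tol = tol, max_iter = max_iter,
                               weight_update = weight_update),
          error = function(e) NULL)
        if (is.null(comp) || comp$degenerate) next
        eta_te <- drop(Xd[te_x, , drop = FALSE] %*% comp$wx)
        gam_te <- predict_trajectory(comp$gamma_fit, idx[te_x], tx[te_x])
        if (stats::sd(eta_te) == 0 || stats::sd(gam_te) == 0) next
        fold_scores[f] <- stats::cor(eta_te, gam_te)
      }
      ok <- !is.na(fold_scores)
      if (!any(ok))
        stop("all folds failed for sparsity pair (", px, ",", qy, ")")
      scores[g, kk] <- mean(fold_scores[ok])
      se[g, kk] <- stats::sd(fold_scores[ok]) / sqrt(sum(ok))
    }
    # argmax with ties to the sparser pair
    ord <- order(-scores[, kk], grid[, 1L] + grid[, 2L], grid[, 1L])
    best <- ord[1L]
    chosen[kk, ] <- grid[best, ]
    comp_full <- nipals_component_mat(Xd, Yd, idx, tx, idy, ty,
                                      grid[best, 1L], grid[best, 2L],
                                      spec_x, spec_y, init = init_kk,
                                      tol = tol, max_iter = max_iter,
                                      weight_update = weight_update)
    components[[kk]] <- comp_full
    if (!comp_full$degenerate) {
      Xd <- deflate(Xd, comp_full$eta)
      Yd <- deflate(Yd, comp_full$gamma)
    }
  }

  fit <- assemble_tosccamm(components, X0, Y0, idx, tx, idy, ty,
                           spec_x, spec_y, seed, tol, max_iter,
                           standardize, weight_update,
                           call = match.call())
  structure(list(grid = grid, scores = scores, se = se, chosen = chosen,
                 fit = fit, n_folds = n_folds, seed = seed,
                 folds = fold_of),
            class = "cv_tosccamm")
}

# build a tosccamm object from already-extracted components
assemble_tosccamm <- function(components, X0, Y0, idx, tx, idy, ty,
                              spec_x, spec_y, seed, tol, max_iter,
                              standardize, weight_update, call) {
  k <- length(components)
  etas <- vapply(components, function(cc) cc$eta, numeric(nrow(X0)))
  gammas <- vapply(components, function(cc) cc$gamma, numeric(nrow(Y0)))
  etas <- matrix(etas, ncol = k); gammas <- matrix(gammas, ncol = k)
  structure(list(components = components, k = k,
                 sparsity = cbind(px = vapply(components, `[[`, integer(1L), "px"),
                                  qy = vapply(components, `[[`, integer(1L), "qy")),
                 rho = vapply(components, `[[`, numeric(1L), "rho"),
                 cpev_x = vapply(seq_len(k), function(j)
                   adj_cpev(X0, etas[, seq_len(j), drop = FALSE]), numeric(1L)),
                 cpev_y = vapply(seq_len(k), function(j)
                   adj_cpev(Y0, gammas[, seq_len(j), drop = FALSE]), numeric(1L)),
                 preprocessing = NULL,
                 rows = list(idx = idx, tx = tx, idy = idy, ty = ty),
                 feature_names = list(x = colnames(X0), y = colnames(Y0)),
                 spec_x = spec_x, spec_y = spec_y,
                 seed = seed, tol = tol, max_iter = max_iter,
                 standardize = standardize, weight_update = weight_update,
                 call = call),
            class = "tosccamm")
}

#' @export
print.cv_tosccamm <- function(x, ...) {
  cat("Cross-validated sparsity selection (", x$n_folds, "-fold, by individual)\n",
      sep = "")
  for (kk in seq_len(ncol(x$scores))) {
    cat(sprintf("Component %d: chosen (px, qy) = (%d, %d)\n",
                kk, x$chosen[kk, 1L], x$chosen[kk, 2L]))
  }
  cat("\nMean out-of-fold correlation:\n")
  print(round(x$scores, 4))
  invisible(x)
}

#' Visit-level residual association of a component
#'
#' The permutation statistic matched to individual-block permutation. Both
#' views share whatever population-level time pattern the data carry (the
#' fitted trend and any common misfit of the trajectory family), and
#' permuting whole individuals cannot destroy it; a valid clustered test
#' must therefore measure only the association that block permutation
#' actually exchanges. This statistic takes each view's latent scores minus
#' their fitted individual trajectories (fixed curve + random intercept),
#' centers the residuals within exact time points (removing every common
#' time pattern), and correlates them across the visits observed in both
#' views. If fewer than 10 shared `(id, time)` visits exist (or the
#' residuals are degenerate, as under the passthrough family) it falls back
#' to pairing per-individual mean residuals, and finally to the component's
#' canonical correlation itself.
#'
#' @param comp a `canonical_component`.
#' @param idx,tx,idy,ty row metadata of the two views.
#' @return A list with `stat` (the statistic) and `type`
#'   (`"visit_residual"`, `"individual_residual"` or `"rho"`).
#' @keywords internal
component_perm_stat <- function(comp, idx, tx, idy, ty) {
  if (comp$degenerate) return(list(stat = 0, type = "rho"))
  rx <- comp$eta - predict_trajectory(comp$eta_fit, idx, tx)
  ry <- comp$gamma - predict_trajectory(comp$gamma_fit, idy, ty)
  rx <- rx - stats::ave(rx, tx)
  ry <- ry - stats::ave(ry, ty)
  kx <- paste(idx, sprintf("%.15g", tx))
  ky <- paste(idy, sprintf("%.15g", ty))
  m <- match(kx, ky)
  ok <- !is.na(m)
  if (sum(ok) >= 10L) {
    a <- rx[ok]; b <- ry[m[ok]]
    if (stats::sd(a) > 0 && stats::sd(b) > 0)
      return(list(stat = stats::cor(a, b), type = "visit_residual"))
  }
  ux <- tapply(rx, idx, mean)
  uy <- tapply(ry, idy, mean)
  shared <- intersect(names(ux), names(uy))
  if (length(shared) >= 5L) {
    a <- ux[shared]; b <- uy[shared]
    if (stats::sd(a) > 0 && stats::sd(b) > 0)
      return(list(stat = stats::cor(a, b), type = "individual_residual"))
  }
  list(stat = comp$rho, type = "rho")
}

#' Permutation test for the number of components
#'
#' Tests, component by component, the null hypothesis of no association
#' between the two views beyond their common time trends. The null
#' distribution is built by permuting the assignment of whole individuals'
#' Y blocks against X — each individual's time series stays intact,
#' preserving the within-individual correlation that row-level permutation
#' would destroy — and refitting the component on each permuted dataset (at
#' the same sparsity levels as the observed fit).
#' `p_k = (1 + #\{T*_b >= T_k\}) / (B + 1)`.
#'
#' The default test statistic is the visit-level residual association
#' ([component_perm_stat()]): shared population time trends survive
#' individual-block permutation, so the raw canonical correlation has no
#' power against them and the statistic must be trend-adjusted.
#' `statistic = "rho"` uses the raw canonical correlation instead, which is
#' only appropriate when the latent series carry no common time trend.
#'
#' @param data a [paired_longitudinal()].
#' @param k number of components to test.
#' @param px,qy sparsity levels per component (recycled to length `k`).
#' @param spec_x,spec_y [trajectory_spec()]s.
#' @param B number of permutations (>= 19).
#' @param seed integer seed.
#' @param fit optionally, an existing [tosccamm()] fit of the same data and
#'   sparsity to reuse as the observed fit.
#' @param statistic `"residual"` (default) or `"rho"`.
#' @param tol,max_iter,standardize,weight_update passed to the fitter.
#' @return An object of class `tosccamm_perm`: `observed_rho` (canonical
#'   correlations), `observed_stat` (test statistics), `null_stats` (B x k),
#'   `p_values`, `statistic`, `B`, `seed`.
#' @export
permutation_test <- function(data, k = 1L, px, qy,
                             spec_x = trajectory_spec("random_intercept_linear"),
                             spec_y = spec_x, B = 99L, seed,
                             fit = NULL, statistic = c("residual", "rho"),
                             tol = 1e-6, max_iter = 100L,
                             standardize = TRUE, weight_update = "cov") {
  statistic <- match.arg(statistic)
  stopifnot(inherits(data, "paired_longitudinal"))
  if (missing(seed)) stop("'seed' is required")
  seed <- as.integer(seed)
  B <- as.integer(B)
  if (B < 19L) stop("B must be >= 19")
  n_x <- length(unique(data$x$ids)); n_y <- length(unique(data$y$ids))
  if (n_x < 5L || n_y < 5L)
    stop("too few individuals for a meaningful permutation test (need >= 5 per view)")

  k <- as.integer(k)
  if (is.null(fit)) {
    fit <- tosccamm(data, k = k, px = px, qy = qy,
                    spec_x = spec_x, spec_y = spec_y, seed = seed,
                    tol = tol, max_iter = max_iter,
                    standardize = standardize, weight_update = weight_update)
  } else {
    stopifnot(inherits(fit, "tosccamm"), fit$k >= k)
  }
  px <- fit$sparsity[seq_len(k), "px"]
  qy <- fit$sparsity[seq_len(k), "qy"]

  if (standardize) {
    X0 <- standardize_columns(data$x)$view$features
    Y0 <- standardize_columns(data$y)$view$features
  } else {
    X0 <- data$x$features; Y0 <- data$y$features
  }
  idx <- data$x$ids; tx <- data$x$times
  idy <- data$y$ids; ty <- data$y$times
  uidy <- sort(unique(idy))

  # deflated matrices entering each component, from the observed fit
  Xd <- X0; Yd <- Y0
  Xd_list <- Yd_list <- vector("list", k)
  for (kk in seq_len(k)) {
    Xd_list[[kk]] <- Xd; Yd_list[[kk]] <- Yd
    cc <- fit$components[[kk]]
    if (!cc$degenerate) {
      Xd <- deflate(Xd, cc$eta)
      Yd <- deflate(Yd, cc$gamma)
    }
  }

  stat_of <- function(comp, idy_use) {
    if (statistic == "rho") comp$rho
    else component_perm_stat(comp, idx, tx, idy_use, ty)$stat
  }
  observed_stat <- vapply(seq_len(k), function(kk)
    stat_of(fit$components[[kk]], idy), numeric(1L))

  set.seed(seed)
  null_stats <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    perm <- stats::setNames(sample(uidy), uidy)
    idy_b <- unname(perm[idy])
    for (kk in seq_len(k)) {
      comp <- tryCatch(
        nipals_component_mat(Xd_list[[kk]], Yd_list[[kk]], idx, tx,
                             idy_b, ty, px[kk], qy[kk], spec_x, spec_y,
                             init = fit$components[[kk]]$init,
                             tol = tol, max_iter = max_iter,
                             weight_update = weight_update),
        error = function(e) NULL)
      null_stats[b, kk] <- if (is.null(comp)) 0 else stat_of(comp, idy_b)
    }
  }

  p_values <- vapply(seq_len(k), function(kk)
    (1 + sum(null_stats[, kk] >= observed_stat[kk])) / (B + 1), numeric(1L))
  structure(list(observed_rho = fit$rho[seq_len(k)],
                 observed_stat = observed_stat,
                 null_stats = null_stats,
                 p_values = p_values, statistic = statistic,
                 B = B, seed = seed, fit = fit),
            class = "tosccamm_perm")
}

#' @export
print.tosccamm_perm <- function(x, ...) {
  cat("Permutation test for the number of components (B = ", x$B,
      ", statistic = ", x$statistic, ")\n", sep = "")
  tab <- data.frame(component = seq_along(x$p_values),
                    rho = round(x$observed_rho, 4),
                    stat = round(x$observed_stat, 4),
                    p_value = round(x$p_values, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
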