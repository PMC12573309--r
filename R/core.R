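#' Top-k soft-thresholding of a weight vector
#'
#' The sparsity operator of thresholded ordered sparse CCA: instead of a
#' penalty value, the tuning parameter is the number `k` of nonzero
#' coefficients to keep. The threshold is the `(k+1)`-th largest absolute
#' entry \eqn{\lambda} (0 when `k = length(w)`); every entry is soft-shrunk,
#' \eqn{sign(w_j)\,max(|w_j| - \lambda, 0)}, and the result is rescaled to
#' unit Euclidean norm. For generic inputs (k-th and (k+1)-th largest
#' absolute values distinct, k-th nonzero) the result has exactly `k`
#' nonzeros; boundary ties shrink to zero, which keeps the operator
#' deterministic.
#'
#' @param w numeric weight vector.
#' @param k target cardinality, between 1 and `length(w)`.
#' @return Unit-norm thresholded vector. An all-zero input returns an
#'   all-zero vector (no normalization) with attribute `degenerate = TRUE`.
#' @examples
#' soft_threshold_topk(c(3, -2, 1, 0.5), 2)  # (2, -1, 0, 0) / sqrt(5)
#' @export
soft_threshold_topk <- function(w, k) {
  w <- as.numeric(w)
  p <- length(w)
  if (length(k) != 1L || is.na(k) || k < 1 || k > p)
    stop("k must be a single integer in [1, length(w)]")
  k <- as.integer(k)
  if (all(w == 0)) {
    out <- w
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  aw <- abs(w)
  # the (k+1)-th largest is the (p-k)-th smallest
  lambda <- if (k == p) 0 else sort(aw, partial = p - k)[p - k]
  out <- sign(w) * pmax(aw - lambda, 0)
  nrm <- sqrt(sum(out^2))
  if (nrm == 0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out / nrm
}

#' Deflate a data matrix by a latent score vector
#'
#' Removes the rank-1 contribution of a unit-norm latent score from a matrix:
#' `M - s (s' M)`. All columns of the result are orthogonal to `s`, which is
#' how sequentially extracted components are kept orthogonal.
#'
#' @param m numeric matrix (rows = visits).
#' @param s unit-norm score vector with `length(s) == nrow(m)`.
#' @return The deflated matrix.
#' @export
deflate <- function(m, s) {
  if (!is.matrix(m)) m <- as.matrix(m)
  s <- as.numeric(s)
  if (length(s) != nrow(m))
    stop("score length must equal the number of matrix rows")
  m - tcrossprod(s, crossprod(m, s))
}

unitize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) v else v / nrm
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

negate_trajectory_fit <- function(fit) {
  # the trajectory model is linear in the response, so negating the response
  # negates fixed effects, BLUPs and fitted values exactly
  fit$fixed_effects <- -fit$fixed_effects
  fit$random_intercepts <- -fit$random_intercepts
  fit$fitted <- -fit$fitted
  fit$train$values <- -fit$train$values
  fit
}

#' One canonical component by trajectory-augmented NIPALS
#'
#' Extracts a single pair of sparse canonical weights from standardized
#' two-view longitudinal data. Each iteration alternates: compute the X-side
#' latent scores \eqn{\eta = X w_x}; fit the X trajectory model on
#' \eqn{(id, t_x, \eta)} and predict \eqn{\tilde\eta} on Y's rows; update
#' \eqn{\tilde w_y = Y^\top \tilde\eta}, threshold to `qy` nonzeros and
#' normalize; compute \eqn{\gamma = Y w_y} (unit norm); fit the Y trajectory
#' and predict \eqn{\tilde\gamma} on X's rows; update
#' \eqn{\tilde w_x = X^\top \tilde\gamma}, threshold to `px`; recompute
#' \eqn{\eta} (unit norm); track \eqn{\rho = cor(\tilde\gamma, \eta)} and
#' stop when its change drops below `tol`. The trajectory predictions fill in
#' the blanks between the two views' sparse, irregular grids.
#'
#' The canonical correlation is reported between the aligned quantities the
#' algorithm actually regresses on: `rho` pairs the predicted
#' \eqn{\tilde\gamma} with \eqn{\eta} on X's rows; `rho_y` is the analogous
#' Y-side value. The sign convention makes `rho` nonnegative by flipping
#' \eqn{w_y} (and its trajectory fit) if needed.
#'
#' @param data a [paired_longitudinal()] whose features are already
#'   standardized (see [standardize_columns()]); [tosccamm()] handles this
#'   for you.
#' @param px,qy number of nonzero weights to keep in X resp. Y.
#' @param spec_x,spec_y [trajectory_spec()] for each view's latent scores.
#' @param init initial X weight vector (length p), or a single integer used
#'   to seed a standard-normal draw.
#' @param tol convergence tolerance on the change in canonical correlation.
#' @param max_iter maximum number of iterations.
#' @param weight_update `"cov"` (the covariance update \eqn{Y^\top\tilde\eta},
#'   default) or `"ls"` (full least-squares
#'   \eqn{(Y^\top Y)^{-1} Y^\top \tilde\eta}; equivalent up to column scaling
#'   for standardized data, and far more expensive for wide views).
#' @return An object of class `canonical_component`: `wx`, `wy` (named),
#'   unit-norm scores `eta` (X rows) and `gamma` (Y rows), trajectory fits
#'   `eta_fit`, `gamma_fit`, correlations `rho`, `rho_y`, the per-iteration
#'   `rho_trace`, `n_iter`, `converged` and `degenerate` flags.
#' @export
nipals_component <- function(data, px, qy, spec_x, spec_y,
                             init = 1L, tol = 1e-6, max_iter = 100L,
                             weight_update = c("cov", "ls")) {
  stopifnot(inherits(data, "paired_longitudinal"))
  weight_update <- match.arg(weight_update)
  X <- data$x$features; Y <- data$y$features
  comp <- nipals_component_mat(X, Y, data$x$ids, data$x$times,
                               data$y$ids, data$y$times,
                               px, qy, spec_x, spec_y, init, tol, max_iter,
                               weight_update)
  comp
}

nipals_component_mat <- function(X, Y, idx, tx, idy, ty, px, qy,
                                 spec_x, spec_y, init = 1L,
                                 tol = 1e-6, max_iter = 100L,
                                 weight_update = "cov") {
  p <- ncol(X); q <- ncol(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L)
    stop("both views must have at least one row")
  px <- as.integer(px); qy <- as.integer(qy)
  if (px < 1 || px > p) stop("px must be in [1, ncol(X)]")
  if (qy < 1 || qy > q) stop("qy must be in [1, ncol(Y)]")
  if (length(init) == 1L) {
    set.seed(as.integer(init))
    init <- stats::rnorm(p)
  }
  if (length(init) != p) stop("init must have length ncol(X)")
  wx <- unitize(as.numeric(init))
  init_vec <- wx
  if (weight_update == "ls") {
    qrY <- qr(Y)
    qrX <- qr(X)
  }

  degenerate <- function(reason) {
    structure(list(wx = stats::setNames(rep(0, p), colnames(X)),
                   wy = stats::setNames(rep(0, q), colnames(Y)),
                   eta = rep(0, nrow(X)), gamma = rep(0, nrow(Y)),
                   eta_fit = NULL, gamma_fit = NULL,
                   rho = 0, rho_y = 0, rho_trace = numeric(0),
                   n_iter = 0L, converged = FALSE, degenerate = TRUE,
                   px = px, qy = qy, init = init_vec, reason = reason),
              class = "canonical_component")
  }

  rho_prev <- 0
  rho_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  eta <- gamma <- NULL
  eta_fit <- gamma_fit <- NULL
  wy <- NULL
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% wx)
    eta_fit <- fit_trajectory(spec_x, idx, tx, eta)
    eta_pred <- predict_trajectory(eta_fit, idy, ty)
    wty <- if (weight_update == "ls") qr.coef(qrY, eta_pred)
           else drop(crossprod(Y, eta_pred))
    wty[is.na(wty)] <- 0
    wy <- soft_threshold_topk(wty, qy)
    if (isTRUE(attr(wy, "degenerate"))) return(degenerate("all-zero wy"))
    gamma <- unitize(drop(Y %*% wy))
    gamma_fit <- fit_trajectory(spec_y, idy, ty, gamma)
    gamma_pred <- predict_trajectory(gamma_fit, idx, tx)
    wtx <- if (weight_update == "ls") qr.coef(qrX, gamma_pred)
           else drop(crossprod(X, gamma_pred))
    wtx[is.na(wtx)] <- 0
    wx <- soft_threshold_topk(wtx, px)
    if (isTRUE(attr(wx, "degenerate"))) return(degenerate("all-zero wx"))
    eta <- unitize(drop(X %*% wx))
    rho <- safe_cor(gamma_pred, eta)
    rho_trace <- c(rho_trace, rho)
    if (abs(rho - rho_prev) <= tol) { converged <- TRUE; break }
    rho_prev <- rho
    if (iter >= max_iter) break
  }

  # sign convention: report a nonnegative canonical correlation
  rho <- rho_trace[length(rho_trace)]
  if (rho < 0) {
    wy <- -wy
    gamma <- -gamma
    gamma_fit <- negate_trajectory_fit(gamma_fit)
    rho <- -rho
  }
  # refit the X trajectory on the final eta so the stored fit describes the
  # stored scores, then report the Y-side aligned correlation as well
  eta_fit <- fit_trajectory(spec_x, idx, tx, eta)
  rho_y <- safe_cor(predict_trajectory(eta_fit, idy, ty), gamma)
  gamma_pred <- predict_trajectory(gamma_fit, idx, tx)
  rho <- safe_cor(gamma_pred, eta)

  structure(list(wx = stats::setNames(as.numeric(wx), colnames(X)),
                 wy = stats::setNames(as.numeric(wy), colnames(Y)),
                 eta = eta, gamma = gamma,
                 eta_fit = eta_fit, gamma_fit = gamma_fit,
                 rho = rho, rho_y = rho_y, rho_trace = rho_trace,
                 n_iter = iter, converged = converged, degenerate = FALSE,
                 px = px, qy = qy, init = init_vec),
            class = "canonical_component")
}

#' @export
print.canonical_component <- function(x, ...) {
  cat(sprintf("Canonical component: rho = %.4f (%d/%d nonzero weights, %d iterations%s)\n",
              x$rho, sum(x$wx != 0), sum(x$wy != 0), x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Sparse CCA for repeated measurements with latent trajectories
#'
#' Fits `k` ordered pairs of sparse canonical weights to two longitudinal
#' views by the trajectory-augmented NIPALS algorithm
#' ([nipals_component()]), deflating both views by each component's
#' unit-norm latent scores before extracting the next, so latent variables
#' of distinct components are orthogonal. Canonical weights are held fixed
#' across measurements; all time dynamics live on the latent variables
#' through the per-view trajectory models.
#'
#' @param x a [paired_longitudinal()] object, a [longitudinal_view()], or a
#'   long-format data frame with `id` and `time` columns.
#' @param y the second view (ignored when `x` is already paired).
#' @param k number of components to extract.
#' @param px,qy nonzero-weight counts per component (scalars are recycled to
#'   length `k`).
#' @param spec_x,spec_y [trajectory_spec()] for the X resp. Y latent scores.
#' @param seed integer seed controlling the random initialization of each
#'   component's weight vector; required so that runs are exactly
#'   reproducible.
#' @param tol,max_iter convergence control for each component.
#' @param standardize center and scale feature columns first (recommended;
#'   the model assumes comparable feature scales).
#' @param weight_update see [nipals_component()].
#' @return An object of class `tosccamm` with elements `components` (list of
#'   `canonical_component`), `sparsity` (k x 2 matrix), `rho` (vector),
#'   `cpev_x`, `cpev_y` (adjusted cumulative explained-variance curves),
#'   `preprocessing` (centers/scales), row metadata and the call. Methods:
#'   [print()], [summary()], [coef()], [predict()], [plot()].
#' @examples
#' sim <- generate_dataset(sim_config(n = 20, p = 30, q = 15, seed = 1))
#' fit <- tosccamm(sim$data, k = 1, px = 10, qy = 5, seed = 1,
#'                 spec_x = trajectory_spec("random_intercept_polynomial", degree = 3),
#'                 spec_y = trajectory_spec("random_intercept_polynomial", degree = 3))
#' fit
#' @export
tosccamm <- function(x, y = NULL, k = 1L, px, qy,
                     spec_x = trajectory_spec("random_intercept_linear"),
                     spec_y = spec_x,
                     seed, tol = 1e-6, max_iter = 100L,
                     standardize = TRUE,
                     weight_update = c("cov", "ls")) {
  cl <- match.call()
  weight_update <- match.arg(weight_update)
  if (missing(seed)) stop("'seed' is required: initialization is random and must be reproducible")
  seed <- as.integer(seed)
  data <- if (inherits(x, "paired_longitudinal")) x else {
    xv <- if (inherits(x, "longitudinal_view")) x else as_longitudinal_view(x)
    yv <- if (inherits(y, "longitudinal_view")) y else as_longitudinal_view(y)
    paired_longitudinal(xv, yv)
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  px <- rep_len(as.integer(px), k)
  qy <- rep_len(as.integer(qy), k)

  if (standardize) {
    sx <- standardize_columns(data$x)
    sy <- standardize_columns(data$y)
    prep <- list(x_centers = sx$centers, x_scales = sx$scales,
                 y_centers = sy$centers, y_scales = sy$scales)
    X0 <- sx$view$features; Y0 <- sy$view$features
  } else {
    prep <- NULL
    X0 <- data$x$features; Y0 <- data$y$features
  }
  idx <- data$x$ids; tx <- data$x$times
  idy <- data$y$ids; ty <- data$y$times

  Xd <- X0; Yd <- Y0
  components <- vector("list", k)
  set.seed(seed)
  inits <- replicate(k, stats::rnorm(ncol(X0)), simplify = FALSE)
  for (kk in seq_len(k)) {
    comp <- nipals_component_mat(Xd, Yd, idx, tx, idy, ty,
                                 px[kk], qy[kk], spec_x, spec_y,
                                 init = inits[[kk]], tol = tol,
                                 max_iter = max_iter,
                                 weight_update = weight_update)
    components[[kk]] <- comp
    if (!comp$degenerate) {
      Xd <- deflate(Xd, comp$eta)
      Yd <- deflate(Yd, comp$gamma)
    }
  }

  etas <- vapply(components, function(cc) cc$eta, numeric(nrow(X0)))
  gammas <- vapply(components, function(cc) cc$gamma, numeric(nrow(Y0)))
  cpev_x <- vapply(seq_len(k), function(j)
    adj_cpev(X0, etas[, seq_len(j), drop = FALSE]), numeric(1L))
  cpev_y <- vapply(seq_len(k), function(j)
    adj_cpev(Y0, gammas[, seq_len(j), drop = FALSE]), numeric(1L))

  structure(list(components = components,
                 k = k,
                 sparsity = cbind(px = px, qy = qy),
                 rho = vapply(components, `[[`, numeric(1L), "rho"),
                 cpev_x = cpev_x, cpev_y = cpev_y,
                 preprocessing = prep,
                 rows = list(idx = idx, tx = tx, idy = idy, ty = ty),
                 feature_names = list(x = colnames(X0), y = colnames(Y0)),
                 spec_x = spec_x, spec_y = spec_y,
                 seed = seed, tol = tol, max_iter = max_iter,
                 standardize = standardize,
                 weight_update = weight_update,
                 call = cl),
            class = "tosccamm")
}

#' @export
print.tosccamm <- function(x, ...) {
  cat("Sparse longitudinal CCA (TOSCCA-MM)\n")
  cat("Call: "); print(x$call)
  tab <- data.frame(component = seq_len(x$k),
                    px = x$sparsity[, "px"], qy = x$sparsity[, "qy"],
                    rho = round(x$rho, 4),
                    iterations = vapply(x$components, `[[`, integer(1L), "n_iter"),
                    converged = vapply(x$components, `[[`, logical(1L), "converged"))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tosccamm <- function(object, ...) {
  comps <- lapply(object$components, function(cc) {
    list(rho = cc$rho, rho_y = cc$rho_y,
         nnz_x = sum(cc$wx != 0), nnz_y = sum(cc$wy != 0),
         n_iter = cc$n_iter, converged = cc$converged,
         eta_fixed = if (!is.null(cc$eta_fit)) cc$eta_fit$fixed_effects,
         eta_varcomp = if (!is.null(cc$eta_fit)) cc$eta_fit$variance_components,
         gamma_fixed = if (!is.null(cc$gamma_fit)) cc$gamma_fit$fixed_effects,
         gamma_varcomp = if (!is.null(cc$gamma_fit)) cc$gamma_fit$variance_components)
  })
  structure(list(fit = object, components = comps,
                 cpev_x = object$cpev_x, cpev_y = object$cpev_y),
            class = "summary.tosccamm")
}

#' @export
print.summary.tosccamm <- function(x, ...) {
  print(x$fit)
  cat("\nAdjusted CPEV  X:", paste(sprintf("%.3f", x$cpev_x), collapse = " "),
      "\n               Y:", paste(sprintf("%.3f", x$cpev_y), collapse = " "), "\n")
  for (kk in seq_along(x$components)) {
    cc <- x$components[[kk]]
    cat(sprintf("\nComponent %d trajectories (eta | gamma):\n", kk))
    if (!is.null(cc$eta_fixed)) {
      cat("  eta fixed effects:  ",
          paste(sprintf("%s=%.4g", names(cc$eta_fixed), cc$eta_fixed),
                collapse = ", "), "\n")
      cat("  gamma fixed effects:",
          paste(sprintf("%s=%.4g", names(cc$gamma_fixed), cc$gamma_fixed),
                collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Extract canonical weight matrices
#'
#' @param object a fitted [tosccamm()] object.
#' @param view `"x"` or `"y"`.
#' @param ... unused.
#' @return Numeric matrix (features x components) of canonical weights.
#' @export
coef.tosccamm <- function(object, view = c("x", "y"), ...) {
  view <- match.arg(view)
  w <- vapply(object$components,
              function(cc) if (view == "x") cc$wx else cc$wy,
              numeric(length(object$feature_names[[view]])))
  w <- matrix(w, ncol = object$k,
              dimnames = list(object$feature_names[[view]],
                              paste0("comp", seq_len(object$k))))
  w
}

#' Predict latent trajectory values
#'
#' Predicts a component's latent trajectory at new `(id, time)` pairs using
#' the fitted trajectory model of the requested view: fixed-effect curve
#' plus the individual's random intercept (or the curve alone for
#' individuals not seen at fit time).
#'
#' @param object a fitted [tosccamm()] object.
#' @param ids,times vectors of equal length; default is the fitted grid.
#' @param component which component.
#' @param view `"x"` (eta trajectory) or `"y"` (gamma trajectory).
#' @param ... unused.
#' @return Numeric vector of predicted latent values.
#' @export
predict.tosccamm <- function(object, ids = NULL, times = NULL,
                             component = 1L, view = c("x", "y"), ...) {
  view <- match.arg(view)
  cc <- object$components[[component]]
  fit <- if (view == "x") cc$eta_fit else cc$gamma_fit
  if (is.null(fit)) stop("component ", component, " is degenerate; no trajectory fit")
  if (is.null(ids)) {
    ids <- if (view == "x") object$rows$idx else object$rows$idy
    times <- if (view == "x") object$rows$tx else object$rows$ty
  }
  predict_trajectory(fit, ids, times)
}

#' Plot latent scores and their fitted trajectory
#'
#' Plots one component's latent scores against time (points), the fitted
#' individual trajectories (thin lines) and the population fixed-effect
#' curve (thick line).
#'
#' @param x a fitted [tosccamm()] object.
#' @param component which component.
#' @param view `"x"` or `"y"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tosccamm <- function(x, component = 1L, view = c("x", "y"), ...) {
  view <- match.arg(view)
  cc <- x$components[[component]]
  scores <- if (view == "x") cc$eta else cc$gamma
  ids <- if (view == "x") x$rows$idx else x$rows$idy
  tt <- if (view == "x") x$rows$tx else x$rows$ty
  fit <- if (view == "x") cc$eta_fit else cc$gamma_fit
  graphics::plot(tt, scores, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "time", ylab = sprintf("latent score (%s, comp %d)", view, component),
                 ...)
  if (!is.null(fit) && fit$spec$family != "passthrough") {
    grid <- seq(min(tt), max(tt), length.out = 100L)
    for (id in unique(ids)) {
      graphics::lines(grid, predict_trajectory(fit, rep(id, 100L), grid),
                      col = grDevices::adjustcolor("steelblue", 0.25))
    }
    pop <- drop(design_matrix(fit$spec, grid) %*% fit$fixed_effects)
    graphics::lines(grid, pop, lwd = 3, col = "firebrick")
  }
  invisible(x)
}

#' Write a fitted model to disk
#'
#' Writes three artifacts into `dir`: `weights.csv` (feature, component,
#' weight; zero weights omitted), `scores.csv` (id, time, component, view,
#' score, predicted trajectory value) and `summary.json` (canonical
#' correlations, iterations, convergence, seed, sparsity, trajectory fixed
#' effects and variance components).
#'
#' @param object a fitted [tosccamm()] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tosccamm <- function(object, dir) {
  stopifnot(inherits(object, "tosccamm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtab <- do.call(rbind, lapply(seq_len(object$k), function(kk) {
    cc <- object$components[[kk]]
    rows <- list()
    nzx <- which(cc$wx != 0)
    nzy <- which(cc$wy != 0)
    rbind(
      if (length(nzx)) data.frame(view = "x", feature = names(cc$wx)[nzx],
                                  component = kk, weight = unname(cc$wx[nzx])),
      if (length(nzy)) data.frame(view = "y", feature = names(cc$wy)[nzy],
                                  component = kk, weight = unname(cc$wy[nzy])))
  }))
  atomic_write_csv(wtab, file.path(dir, "weights.csv"))

  stab <- do.call(rbind, lapply(seq_len(object$k), function(kk) {
    cc <- object$components[[kk]]
    if (cc$degenerate) return(NULL)
    rbind(data.frame(id = object$rows$idx, time = object$rows$tx,
                     component = kk, view = "eta", score = cc$eta,
                     predicted = predict_trajectory(cc$eta_fit, object$rows$idx,
                                                    object$rows$tx)),
          data.frame(id = object$rows$idy, time = object$rows$ty,
                     component = kk, view = "gamma", score = cc$gamma,
                     predicted = predict_trajectory(cc$gamma_fit, object$rows$idy,
                                                    object$rows$ty)))
  }))
  atomic_write_csv(stab, file.path(dir, "scores.csv"))

  summ <- list(
    k = object$k, seed = object$seed,
    sparsity = lapply(seq_len(object$k), function(kk)
      list(px = unname(object$sparsity[kk, "px"]),
           qy = unname(object$sparsity[kk, "qy"]))),
    rho = object$rho,
    rho_y = vapply(object$components, `[[`, numeric(1L), "rho_y"),
    iterations = vapply(object$components, `[[`, integer(1L), "n_iter"),
    converged = vapply(object$components, `[[`, logical(1L), "converged"),
    adj_cpev_x = object$cpev_x, adj_cpev_y = object$cpev_y,
    trajectories = lapply(object$components, function(cc) {
      if (cc$degenerate) return(list(degenerate = TRUE))
      list(eta = list(fixed_effects = as.list(cc$eta_fit$fixed_effects),
                      variance_components = as.list(cc$eta_fit$variance_components),
                      fallback = cc$eta_fit$fallback),
           gamma = list(fixed_effects = as.list(cc$gamma_fit$fixed_effects),
                        variance_components = as.list(cc$gamma_fit$variance_components),
                        fallback = cc$gamma_fit$fallback))
    }))
  atomic_write_json(summ, file.path(dir, "summary.json"))
  invisible(dir)
}
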