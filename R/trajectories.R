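#' Specify a latent trajectory model
#'
#' Trajectory models describe the latent scores of one view as a smooth
#' function of time plus an individual random intercept:
#' \eqn{f(t) = \alpha_i + x(t)^\top \beta}. They are fitted on the
#' low-dimensional latent variable, not on the features, which keeps the
#' longitudinal modelling cheap, and are then used to predict latent values
#' on the other view's time grid.
#'
#' Families:
#' \describe{
#'   \item{`random_intercept_linear`}{basis `(1, t)`.}
#'   \item{`random_intercept_polynomial`}{raw polynomial basis
#'     `(1, t, ..., t^degree)`.}
#'   \item{`change_point`}{cubic polynomial plus an extra slope active after
#'     the change point `s`: basis `(1, t, t^2, t^3, t * 1{t > s})`, or
#'     `(t - s) * 1{t > s}` for the last column when `shifted = TRUE`. The
#'     change point is supplied, not estimated; `s = 0` suits event-centered
#'     time scales.}
#'   \item{`passthrough`}{a degenerate model that memorizes the training
#'     scores and returns them unchanged when predicting on the same
#'     `(id, time)` grid. It reduces the longitudinal algorithm to the plain
#'     cross-sectional one and exists for testing and comparison.}
#' }
#'
#' @param family one of `"random_intercept_linear"`,
#'   `"random_intercept_polynomial"`, `"change_point"`, `"passthrough"`.
#' @param degree polynomial degree (>= 1) for the polynomial family.
#' @param change_point the change point `s` (same units as time).
#' @param shifted if `TRUE` the post-change term uses `(t - s)` instead of
#'   `t` (the two parameterizations span the same model space when the basis
#'   already contains `t`).
#' @param method `"REML"` (default) or `"ML"` estimation for the mixed model.
#' @return An object of class `trajectory_spec`.
#' @examples
#' trajectory_spec("random_intercept_polynomial", degree = 3)
#' @export
trajectory_spec <- function(family = c("random_intercept_linear",
                                       "random_intercept_polynomial",
                                       "change_point", "passthrough"),
                            degree = 1L, change_point = 0,
                            shifted = FALSE, method = c("REML", "ML")) {
  family <- match.arg(family)
  method <- match.arg(method)
  degree <- as.integer(degree)
  if (family == "random_intercept_polynomial" && degree < 1L)
    stop("polynomial degree must be >= 1")
  if (family == "random_intercept_linear") degree <- 1L
  if (family == "change_point") degree <- 3L
  structure(list(family = family, degree = degree,
                 change_point = as.numeric(change_point),
                 shifted = isTRUE(shifted), method = method),
            class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat("Trajectory spec:", x$family)
  if (x$family == "random_intercept_polynomial") cat(" (degree", x$degree, ")")
  if (x$family == "change_point")
    cat(" (s =", x$change_point, if (x$shifted) ", shifted" else "", ")")
  cat("\n")
  invisible(x)
}

#' Fixed-effects regression basis at given times
#'
#' @param spec a [trajectory_spec()].
#' @param t numeric vector of times.
#' @return For a single time, the basis vector; see [design_matrix()] for the
#'   matrix version used internally.
#' @examples
#' design_row(trajectory_spec("change_point", change_point = 0), -1)
#' @export
design_row <- function(spec, t) {
  drop(design_matrix(spec, t))
}

#' Fixed-effects design matrix at given times
#'
#' @inheritParams design_row
#' @return Numeric matrix, one row per time.
#' @export
design_matrix <- function(spec, t) {
  stopifnot(inherits(spec, "trajectory_spec"))
  t <- as.numeric(t)
  switch(spec$family,
    random_intercept_linear = cbind(`(Intercept)` = 1, t = t),
    random_intercept_polynomial = {
      m <- outer(t, 0:spec$degree, `^`)
      colnames(m) <- c("(Intercept)", paste0("t", seq_len(spec$degree)))
      m
    },
    change_point = {
      s <- spec$change_point
      post <- if (spec$shifted) (t - s) * (t > s) else t * (t > s)
      cbind(`(Intercept)` = 1, t = t, t2 = t^2, t3 = t^3, post = post)
    },
    passthrough = stop("the passthrough family has no regression basis"))
}

min_distinct_times <- function(spec) {
  # degree-d polynomial trend: require at least d + 2 distinct times so the
  # residual variance is identifiable on top of the trend
  spec$degree + 2L
}

#' Fit a trajectory model to latent scores
#'
#' Fits the spec's linear mixed model (random intercept per individual, fixed
#' time basis) to latent scores by REML (or ML) via \pkg{lme4}. If the mixed
#' model fails to converge or sits on the singular boundary
#' (\eqn{\sigma_b^2 \to 0}), the fit falls back to fixed-effects-only least
#' squares with random-intercept variance 0 and is flagged, so an outer
#' estimation loop never aborts mid-iteration.
#'
#' @param spec a [trajectory_spec()].
#' @param ids individual identifiers, one per observation.
#' @param times observation times.
#' @param values latent scores to model.
#' @return An object of class `trajectory_fit` with elements
#'   `fixed_effects`, `random_intercepts` (named by id; BLUPs),
#'   `variance_components` (`var_intercept`, `var_residual`), `fallback`
#'   flag, `spec`, and `fitted` values at the training points.
#' @examples
#' ids <- rep(c("a", "b", "c"), each = 4); t <- rep(1:4, 3)
#' val <- c(-1, 0, 1)[match(ids, c("a", "b", "c"))] + 2 * t
#' fit <- fit_trajectory(trajectory_spec("random_intercept_linear"), ids, t, val)
#' fit$fixed_effects
#' @export
fit_trajectory <- function(spec, ids, times, values) {
  stopifnot(inherits(spec, "trajectory_spec"))
  ids <- as.character(ids)
  times <- as.numeric(times)
  values <- as.numeric(values)
  n <- length(values)
  if (length(ids) != n || length(times) != n)
    stop("ids, times and values must have equal length")

  if (spec$family == "passthrough") {
    fit <- structure(list(spec = spec,
                          fixed_effects = numeric(0),
                          random_intercepts = stats::setNames(
                            rep(0, length(unique(ids))), unique(ids)),
                          variance_components = c(var_intercept = 0,
                                                  var_residual = 0),
                          fallback = FALSE,
                          train = list(ids = ids, times = times,
                                       values = values),
                          fitted = values),
                     class = "trajectory_fit")
    return(fit)
  }

  uid <- unique(ids)
  if (length(uid) < 2L)
    stop("need at least 2 distinct individuals to fit a mixed model")
  if (length(unique(times)) < min_distinct_times(spec))
    stop("rank deficiency: a degree-", spec$degree,
         " trajectory needs at least ", min_distinct_times(spec),
         " distinct time points")

  X <- design_matrix(spec, times)
  fid <- factor(ids, levels = uid)
  df <- data.frame(.y = values, .id = fid)

  # exact-interpolation case (noiseless scores): basis + individual offsets
  # reproduce the data; the mixed-model optimizer cannot handle a zero
  # residual variance, so recover the decomposition directly
  Z <- stats::model.matrix(~ 0 + fid)
  n_par <- (ncol(X) - 1L) + length(uid)
  full <- if (n > n_par) stats::lm.fit(cbind(X[, -1L, drop = FALSE], Z), values)
          else NULL
  if (!is.null(full) &&
      sum(full$residuals^2) < 1e-12 * max(1, sum(values^2))) {
    cf <- full$coefficients
    cf[is.na(cf)] <- 0
    nb <- ncol(X) - 1L
    beta_t <- cf[seq_len(nb)]
    offsets <- cf[nb + seq_along(uid)]
    beta <- c(mean(offsets), beta_t)
    names(beta) <- colnames(X)
    re <- stats::setNames(as.numeric(offsets - mean(offsets)), uid)
    out <- list(spec = spec, fixed_effects = beta, random_intercepts = re,
                variance_components = c(var_intercept = stats::var(offsets),
                                        var_residual = 0),
                fallback = FALSE)
    out$train <- list(ids = ids, times = times, values = values)
    fit <- structure(out, class = "trajectory_fit")
    fit$fitted <- predict_trajectory(fit, ids, times)
    return(fit)
  }

  res <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(.y ~ 0 + X + (1 | .id), data = df,
                 REML = spec$method == "REML",
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    if (lme4::isSingular(fit, tol = 1e-6)) NULL else fit
  }, error = function(e) NULL)

  if (is.null(res)) {
    # fixed-effects-only least squares fallback
    ls <- stats::lm.fit(X, values)
    beta <- ls$coefficients
    beta[is.na(beta)] <- 0
    fitted_vals <- drop(X %*% beta)
    re <- stats::setNames(rep(0, length(uid)), uid)
    dfres <- max(1L, n - sum(!is.na(ls$coefficients)))
    vc <- c(var_intercept = 0,
            var_residual = sum((values - fitted_vals)^2) / dfres)
    out <- list(spec = spec,
                fixed_effects = stats::setNames(as.numeric(beta), colnames(X)),
                random_intercepts = re,
                variance_components = vc, fallback = TRUE)
  } else {
    beta <- lme4::fixef(res)
    names(beta) <- colnames(X)
    reframe <- lme4::ranef(res)$.id
    re <- stats::setNames(reframe[["(Intercept)"]], rownames(reframe))
    re <- re[uid]
    names(re) <- uid
    vcmat <- lme4::VarCorr(res)
    vc <- c(var_intercept = as.numeric(vcmat$.id[1L, 1L]),
            var_residual = attr(vcmat, "sc")^2)
    out <- list(spec = spec,
                fixed_effects = as.numeric(beta), random_intercepts = re,
                variance_components = vc, fallback = FALSE)
    names(out$fixed_effects) <- colnames(X)
  }
  out$train <- list(ids = ids, times = times, values = values)
  fit <- structure(out, class = "trajectory_fit")
  fit$fitted <- predict_trajectory(fit, ids, times)
  fit
}

#' Predict latent scores from a fitted trajectory model
#'
#' For an individual seen at fit time the prediction is the fixed-effect
#' curve plus that individual's predicted (BLUP) random intercept; for an
#' unseen individual the random effect is at its prior mean, so the
#' prediction is the fixed-effect curve only. Extrapolation beyond the fitted
#' time range is permitted (predicting on the other view's grid requires it).
#'
#' @param fit a `trajectory_fit`.
#' @param ids,times the `(id, time)` pairs to predict at.
#' @return Numeric vector of predictions in input order.
#' @export
predict_trajectory <- function(fit, ids, times) {
  stopifnot(inherits(fit, "trajectory_fit"))
  ids <- as.character(ids)
  times <- as.numeric(times)
  if (length(ids) != length(times))
    stop("ids and times must have equal length")
  if (fit$spec$family == "passthrough") {
    key <- paste(fit$train$ids, sprintf("%.15g", fit$train$times), sep = "\r")
    qkey <- paste(ids, sprintf("%.15g", times), sep = "\r")
    m <- match(qkey, key)
    if (anyNA(m))
      stop("passthrough trajectory can only predict on its training (id, time) grid")
    return(fit$train$values[m])
  }
  X <- design_matrix(fit$spec, times)
  re <- fit$random_intercepts[ids]
  re[is.na(re)] <- 0
  drop(X %*% fit$fixed_effects) + as.numeric(re)
}

#' @export
predict.trajectory_fit <- function(object, ids, times, ...) {
  predict_trajectory(object, ids, times)
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Trajectory fit (", x$spec$family, ")\n", sep = "")
  if (length(x$fixed_effects)) {
    cat("Fixed effects:\n")
    print(x$fixed_effects)
    cat(sprintf("Variance components: intercept %.4g, residual %.4g\n",
                x$variance_components[["var_intercept"]],
                x$variance_components[["var_residual"]]))
  }
  if (x$fallback) cat("NOTE: fixed-effects-only fallback was used\n")
  invisible(x)
}
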