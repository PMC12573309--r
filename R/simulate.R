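#' Configuration for the synthetic longitudinal two-view generator
#'
#' Describes a probabilistic-CCA generative process with a shared dynamic
#' latent variable: for each component a single latent series per individual
#' drives both views, each view observes it through a sparse weight vector,
#' and the observation noise is correlated over time (AR(1) with unit
#' marginal variance). Visit-level missingness then removes a fixed fraction
#' of rows from each view independently, so the two views end up with
#' different individuals-per-visit coverage.
#'
#' Defaults reproduce the reference simulation design: 100 individuals, 10
#' visits at times 1..10, 10,000 X features, 200 Y features, two latent
#' components with 10 (X) and 5 (Y) truly nonzero weights each, 20% of X
#' visits and 30% of Y visits removed. The latent population curves are
#' `theta0 * t + sin(theta1 * t) * t` (component 1) and
#' `theta2 * t + (1 + t / max(t))^3` (component 2); each individual adds a
#' normal random offset (`sigma_b`) and per-visit noise (`sigma_eps`). The
#' curve parameters and noise levels default to values that make the
#' trajectories visibly nonlinear yet recoverable at these dimensions.
#'
#' @param n individuals.
#' @param p,q feature counts for X and Y.
#' @param n_times visits per individual (times are `1..n_times`).
#' @param n_components number of latent components (1 or 2).
#' @param support_x,support_y truly nonzero weights per component.
#' @param theta0,theta1,theta2 latent-curve parameters.
#' @param sigma_b SD of the individual random offset on the latent series.
#' @param sigma_eps SD of the per-visit latent noise.
#' @param rho_t AR(1) correlation of the observation noise over time.
#' @param noise_sd marginal SD of the observation noise (1 reproduces the
#'   unit-diagonal noise covariance; 0 gives the noiseless limit).
#' @param miss_x,miss_y fractions of visits removed from each view
#'   (in `[0, 1)`).
#' @param seed integer seed; fixing it makes the dataset bit-identical.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 100L, p = 10000L, q = 200L, n_times = 10L,
                       n_components = 2L, support_x = 10L, support_y = 5L,
                       theta0 = 0.5, theta1 = 1.0, theta2 = -0.3,
                       sigma_b = 0.5, sigma_eps = 0.5, rho_t = 0.3,
                       noise_sd = 1, miss_x = 0.2, miss_y = 0.3, seed = 1L) {
  cfg <- list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
              n_times = as.integer(n_times),
              n_components = as.integer(n_components),
              support_x = as.integer(support_x),
              support_y = as.integer(support_y),
              theta0 = theta0, theta1 = theta1, theta2 = theta2,
              sigma_b = sigma_b, sigma_eps = sigma_eps, rho_t = rho_t,
              noise_sd = noise_sd,
              miss_x = miss_x, miss_y = miss_y, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n < 2L) stop("n must be >= 2")
    if (n_times < 1L) stop("n_times must be >= 1")
    if (!n_components %in% 1:2)
      stop("n_components must be 1 or 2 (latent curves are defined for two components)")
    if (miss_x < 0 || miss_x >= 1 || miss_y < 0 || miss_y >= 1)
      stop("missingness fractions must be in [0, 1)")
    if (n_components * support_x > p)
      stop("disjoint X supports need n_components * support_x <= p")
    if (n_components * support_y > q)
      stop("disjoint Y supports need n_components * support_y <= q")
    if (sigma_b < 0 || sigma_eps < 0 || noise_sd < 0)
      stop("SDs must be nonnegative")
    if (abs(rho_t) >= 1) stop("rho_t must be in (-1, 1)")
  })
  invisible(cfg)
}

#' Population latent curve of a component
#'
#' The deterministic population-level latent trajectory; individuals add a
#' random offset and visit-level noise on top (see [generate_dataset()]).
#'
#' @param k component (1 or 2).
#' @param t numeric vector of times.
#' @param config a [sim_config()] (supplies the curve parameters and the
#'   design grid's maximum time).
#' @return Numeric vector of population latent values.
#' @examples
#' latent_curve(1, 0, sim_config())  # 0
#' @export
latent_curve <- function(k, t, config = sim_config()) {
  stopifnot(k %in% 1:2)
  t <- as.numeric(t)
  max_t <- config$n_times
  if (k == 1L) config$theta0 * t + sin(config$theta1 * t) * t
  else config$theta2 * t + (1 + t / max_t)^3
}

# sparse true weights: equal magnitude 1/sqrt(support), alternating signs,
# supports disjoint across components at fixed indices
true_weights <- function(n_feat, support, n_components, prefix) {
  W <- matrix(0, n_feat, n_components)
  for (k in seq_len(n_components)) {
    idx <- ((k - 1L) * support + 1L):(k * support)
    W[idx, k] <- rep_len(c(1, -1), support) / sqrt(support)
  }
  dimnames(W) <- list(paste0(prefix, seq_len(n_feat)),
                      paste0("comp", seq_len(n_components)))
  W
}

# AR(1) noise over time with unit marginal variance, independent across
# features; returns an (n * n_times) x n_feat matrix in (id, time) row order
ar1_noise <- function(n, n_times, n_feat, rho) {
  E <- matrix(0, n * n_times, n_feat)
  rows_t <- function(t) seq.int(t, by = n_times, length.out = n)
  prev <- matrix(stats::rnorm(n * n_feat), n, n_feat)
  E[rows_t(1L), ] <- prev
  if (n_times > 1L) {
    sc <- sqrt(1 - rho^2)
    for (t in 2:n_times) {
      prev <- rho * prev + sc * matrix(stats::rnorm(n * n_feat), n, n_feat)
      E[rows_t(t), ] <- prev
    }
  }
  E
}

#' Generate a synthetic longitudinal two-view dataset
#'
#' Draws the shared latent series (the same realization drives both views),
#' builds the sparse true weights, adds time-correlated observation noise
#' and removes exactly `round(miss * n * n_times)` visits per view uniformly
#' at random — an individual can lose none, several or all visits. Fixing
#' the seed makes the output bit-identical.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_tosccamm`: `data` (a
#'   [paired_longitudinal()] after missingness), `truth` (true `Wx`, `Wy`,
#'   the latent array `z` (`n x n_times x K`), population curves, retained-row
#'   masks, the full grid and ids) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n; Tm <- config$n_times; K <- config$n_components
  grid <- seq_len(Tm)
  ids <- sprintf("id%03d", seq_len(n))

  pop <- vapply(seq_len(K), function(k) latent_curve(k, grid, config),
                numeric(Tm))
  z <- array(0, dim = c(n, Tm, K),
             dimnames = list(ids, paste0("t", grid), paste0("comp", seq_len(K))))
  for (k in seq_len(K)) {
    b <- stats::rnorm(n, sd = config$sigma_b)
    eps <- matrix(stats::rnorm(n * Tm, sd = config$sigma_eps), n, Tm)
    z[, , k] <- matrix(pop[, k], n, Tm, byrow = TRUE) + b + eps
  }

  Wx <- true_weights(config$p, config$support_x, K, "x")
  Wy <- true_weights(config$q, config$support_y, K, "y")

  # long-format latent matrix in (id, time) row order
  Zl <- matrix(0, n * Tm, K)
  for (k in seq_len(K)) Zl[, k] <- as.vector(t(z[, , k]))
  row_ids <- rep(ids, each = Tm)
  row_times <- rep(grid, n)

  Xfull <- Zl %*% t(Wx) + config$noise_sd * ar1_noise(n, Tm, config$p, config$rho_t)
  Yfull <- Zl %*% t(Wy) + config$noise_sd * ar1_noise(n, Tm, config$q, config$rho_t)
  colnames(Xfull) <- rownames(Wx)
  colnames(Yfull) <- rownames(Wy)

  n_rows <- n * Tm
  rm_x <- sort(sample.int(n_rows, round(config$miss_x * n_rows)))
  rm_y <- sort(sample.int(n_rows, round(config$miss_y * n_rows)))
  keep_x <- setdiff(seq_len(n_rows), rm_x)
  keep_y <- setdiff(seq_len(n_rows), rm_y)

  xv <- longitudinal_view(row_ids[keep_x], row_times[keep_x],
                          Xfull[keep_x, , drop = FALSE])
  yv <- longitudinal_view(row_ids[keep_y], row_times[keep_y],
                          Yfull[keep_y, , drop = FALSE])
  data <- suppressWarnings(paired_longitudinal(xv, yv))

  structure(list(data = data,
                 truth = list(Wx = Wx, Wy = Wy, z = z,
                              population_curves = pop,
                              grid = grid, ids = ids,
                              keep_x = keep_x, keep_y = keep_y,
                              removed_x = rm_x, removed_y = rm_y),
                 config = config),
            class = "sim_tosccamm")
}

#' @export
print.sim_tosccamm <- function(x, ...) {
  cfg <- x$config
  cat("Simulated longitudinal two-view dataset\n")
  cat(sprintf("  %d individuals, %d visits at t = 1..%d, %d latent components\n",
              cfg$n, cfg$n_times, cfg$n_times, cfg$n_components))
  cat(sprintf("  X: %d features (%d rows retained), Y: %d features (%d rows retained)\n",
              cfg$p, length(x$truth$keep_x), cfg$q, length(x$truth$keep_y)))
  invisible(x)
}

#' Score support and trajectory recovery against the simulation truth
#'
#' Matches each true component to the estimated component with which its
#' latent series correlates most strongly (greedy, without replacement,
#' signs aligned), then reports, per true component: true/false positive
#' counts for the X and Y weight supports, and the correlation between the
#' estimated mean latent trajectory and the true population curve on the
#' full grid. The estimated mean latent trajectory is the per-grid-time mean
#' of the estimated latent scores (the average of the estimated individual
#' latent values), which tracks the curve's shape without the smoothing bias
#' of the fitted trajectory family.
#'
#' @param truth the `truth` element of a [generate_dataset()] result (or the
#'   `sim_tosccamm` object itself).
#' @param result a fitted [tosccamm()] object on the simulated data.
#' @return A data frame with one row per true component: `true_comp`,
#'   `est_comp`, `tp_x`, `fp_x`, `tp_y`, `fp_y`, `latent_cor`,
#'   `trajectory_cor`.
#' @export
evaluate_recovery <- function(truth, result) {
  if (inherits(truth, "sim_tosccamm")) truth <- truth$truth
  stopifnot(inherits(result, "tosccamm"))
  K_true <- dim(truth$z)[3L]
  grid <- truth$grid

  # true latent values on the retained X rows, per component
  key_rows <- paste(result$rows$idx, result$rows$tx)
  key_full <- paste(rep(truth$ids, each = length(grid)),
                    rep(grid, length(truth$ids)))
  m <- match(key_rows, key_full)
  z_rows <- vapply(seq_len(K_true), function(k)
    as.vector(t(truth$z[, , k]))[m], numeric(length(m)))

  avail <- seq_len(result$k)
  out <- vector("list", K_true)
  for (k in seq_len(K_true)) {
    if (!length(avail)) {
      out[[k]] <- data.frame(true_comp = k, est_comp = NA_integer_,
                             tp_x = 0L, fp_x = 0L, tp_y = 0L, fp_y = 0L,
                             latent_cor = NA_real_, trajectory_cor = NA_real_)
      next
    }
    cors <- vapply(avail, function(j)
      safe_cor(z_rows[, k], result$components[[j]]$eta), numeric(1L))
    best <- which.max(abs(cors))
    pick <- avail[best]
    best_cor <- abs(cors[best])
    sgn <- sign(cors[best])
    if (sgn == 0) sgn <- 1
    avail <- setdiff(avail, pick)
    cc <- result$components[[pick]]

    est_supp_x <- which(cc$wx != 0)
    est_supp_y <- which(cc$wy != 0)
    true_supp_x <- which(truth$Wx[, k] != 0)
    true_supp_y <- which(truth$Wy[, k] != 0)

    # estimated mean latent path: per-grid-time mean of the eta scores
    est_path <- vapply(grid, function(tt) {
      sel <- result$rows$tx == tt
      if (!any(sel)) NA_real_ else mean(cc$eta[sel])
    }, numeric(1L))
    ok <- !is.na(est_path)
    traj_cor <- if (sum(ok) >= 3L)
      safe_cor(sgn * est_path[ok], truth$population_curves[ok, k]) else NA_real_

    out[[k]] <- data.frame(true_comp = k, est_comp = pick,
                           tp_x = length(intersect(est_supp_x, true_supp_x)),
                           fp_x = length(setdiff(est_supp_x, true_supp_x)),
                           tp_y = length(intersect(est_supp_y, true_supp_y)),
                           fp_y = length(setdiff(est_supp_y, true_supp_y)),
                           latent_cor = best_cor,
                           trajectory_cor = traj_cor)
  }
  do.call(rbind, out)
}

#' Write a simulated dataset to disk
#'
#' Writes `x.csv` and `y.csv` (long format), `truth_weights.csv`,
#' `truth_latent.csv`, the resolved configuration as `config.yaml` and a
#' `manifest.json` with the seed and row counts.
#'
#' @param sim a [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_tosccamm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_long_csv(sim$data$x, file.path(dir, "x.csv"))
  write_long_csv(sim$data$y, file.path(dir, "y.csv"))

  tw <- rbind(
    data.frame(view = "x",
               feature = rep(rownames(sim$truth$Wx), ncol(sim$truth$Wx)),
               component = rep(seq_len(ncol(sim$truth$Wx)),
                               each = nrow(sim$truth$Wx)),
               weight = as.vector(sim$truth$Wx)),
    data.frame(view = "y",
               feature = rep(rownames(sim$truth$Wy), ncol(sim$truth$Wy)),
               component = rep(seq_len(ncol(sim$truth$Wy)),
                               each = nrow(sim$truth$Wy)),
               weight = as.vector(sim$truth$Wy)))
  tw <- tw[tw$weight != 0, ]
  atomic_write_csv(tw, file.path(dir, "truth_weights.csv"))

  z <- sim$truth$z
  tl <- do.call(rbind, lapply(seq_len(dim(z)[3L]), function(k)
    data.frame(id = rep(sim$truth$ids, each = length(sim$truth$grid)),
               time = rep(sim$truth$grid, length(sim$truth$ids)),
               component = k,
               z = as.vector(t(z[, , k])))))
  atomic_write_csv(tl, file.path(dir, "truth_latent.csv"))

  atomic_write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  atomic_write_json(list(seed = sim$config$seed,
                         n_rows_x = length(sim$truth$keep_x),
                         n_rows_y = length(sim$truth$keep_y),
                         n_removed_x = length(sim$truth$removed_x),
                         n_removed_y = length(sim$truth$removed_y)),
                    file.path(dir, "manifest.json"))
  invisible(dir)
}
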