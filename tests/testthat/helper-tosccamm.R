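# shared fixtures and independent oracles

# small, fast simulation for unit tests
small_sim <- function(seed = 7, n = 30, p = 40, q = 20, n_times = 8,
                      support_x = 5, support_y = 3, ...) {
  generate_dataset(sim_config(n = n, p = p, q = q, n_times = n_times,
                              support_x = support_x, support_y = support_y,
                              seed = seed, ...))
}

cubic_spec <- function() trajectory_spec("random_intercept_polynomial", degree = 3)

# independently coded plain cross-sectional sparse NIPALS loop (the
# reduction oracle): no trajectory modelling, same thresholding semantics
# re-derived from the order-statistic definition, same stopping rule and
# final sign convention
plain_toscca <- function(X, Y, px, qy, init, tol = 1e-6, max_iter = 100) {
  topk <- function(v, k) {
    v <- unname(v)
    lam <- if (k == length(v)) 0 else sort(abs(v), decreasing = TRUE)[k + 1]
    out <- sign(v) * pmax(abs(v) - lam, 0)
    out / sqrt(sum(out^2))
  }
  wx <- init / sqrt(sum(init^2))
  rho_prev <- 0
  rho <- NA_real_
  for (l in seq_len(max_iter)) {
    eta <- drop(X %*% wx)
    wy <- topk(drop(t(Y) %*% eta), qy)
    gamma <- drop(Y %*% wy); gamma <- gamma / sqrt(sum(gamma^2))
    wx <- topk(drop(t(X) %*% gamma), px)
    eta <- drop(X %*% wx); eta <- eta / sqrt(sum(eta^2))
    rho <- cor(gamma, eta)
    if (abs(rho - rho_prev) <= tol) break
    rho_prev <- rho
  }
  if (rho < 0) { wy <- -wy; gamma <- -gamma; rho <- -rho }
  list(wx = wx, wy = wy, eta = eta, gamma = gamma, rho = rho)
}

# paired data with one visit per individual at a common time, so the
# passthrough trajectory makes the longitudinal algorithm coincide with the
# plain cross-sectional one (and stays well-defined when individual labels
# are permuted)
single_visit_pair <- function(n = 12, p = 5, q = 4, seed = 2) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  times <- rep(1, n)
  common <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p) + common
  Y <- matrix(rnorm(n * q), n, q) + common
  paired_longitudinal(longitudinal_view(ids, times, X),
                      longitudinal_view(ids, times, Y))
}

# ---- memoized heavy objects shared across acceptance tests ----------------
.acc <- new.env(parent = emptyenv())
ACC_SEED <- 42L

acc_sim <- function() {
  if (is.null(.acc$sim)) .acc$sim <- generate_dataset(sim_config(seed = ACC_SEED))
  .acc$sim
}

acc_fit <- function() {
  if (is.null(.acc$fit))
    .acc$fit <- tosccamm(acc_sim()$data, k = 3, px = 10, qy = 5,
                         spec_x = cubic_spec(), spec_y = cubic_spec(),
                         seed = ACC_SEED)
  .acc$fit
}

acc_perm <- function() {
  if (is.null(.acc$perm))
    .acc$perm <- permutation_test(acc_sim()$data, k = 3, px = 10, qy = 5,
                                  spec_x = cubic_spec(), spec_y = cubic_spec(),
                                  B = 99, seed = ACC_SEED, fit = acc_fit())
  .acc$perm
}

acc_cv <- function() {
  if (is.null(.acc$cv))
    .acc$cv <- cv_select(acc_sim()$data,
                         grid = rbind(c(5, 3), c(10, 5), c(20, 10)),
                         n_folds = 5, k = 1,
                         spec_x = cubic_spec(), spec_y = cubic_spec(),
                         seed = ACC_SEED)
  .acc$cv
}
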