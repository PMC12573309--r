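test_that("latent curves match hand-evaluated values", {
  cfg <- sim_config(n = 10, p = 20, q = 10)
  expect_equal(latent_curve(1, 0, cfg), 0)          # theta0*0 + sin(0)*0
  tmax <- cfg$n_times
  expect_equal(latent_curve(2, tmax, cfg), cfg$theta2 * tmax + 8)  # (1+1)^3 = 8
  expect_equal(latent_curve(1, 2, cfg), cfg$theta0 * 2 + sin(cfg$theta1 * 2) * 2)
})

test_that("generation is deterministic, dimensioned, and counts removals exactly", {
  cfg <- sim_config(n = 12, p = 25, q = 15, n_times = 6,
                    support_x = 6, support_y = 4, miss_x = 0.25,
                    miss_y = 0.1, seed = 33)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$data$x$features, s2$data$x$features)
  expect_identical(s1$truth$z, s2$truth$z)

  expect_equal(ncol(s1$data$x$features), 25L)
  expect_equal(ncol(s1$data$y$features), 15L)
  expect_equal(length(s1$truth$ids), 12L)
  # exact rounding rule for removals: 12*6 = 72 rows; 25% -> 18, 10% -> 7
  expect_equal(length(s1$data$x$ids), 72L - round(0.25 * 72))
  expect_equal(length(s1$data$y$ids), 72L - round(0.10 * 72))
  expect_equal(length(s1$truth$removed_x), 18L)
  expect_equal(length(s1$truth$removed_y), 7L)

  expect_error(sim_config(miss_x = 1.5), "missingness")
  expect_error(sim_config(n_components = 3), "n_components")
  expect_error(sim_config(p = 15, support_x = 10, n_components = 2), "disjoint")
})

test_that("noiseless limit reproduces the latent signal exactly", {
  cfg <- sim_config(n = 8, p = 12, q = 8, n_times = 5,
                    support_x = 4, support_y = 2, sigma_b = 0,
                    sigma_eps = 0, noise_sd = 0, rho_t = 0,
                    miss_x = 0, miss_y = 0, seed = 3)
  sim <- generate_dataset(cfg)
  Zl <- sapply(1:2, function(k) as.vector(t(sim$truth$z[, , k])))
  expect_equal(unname(sim$data$x$features), unname(Zl %*% t(sim$truth$Wx)))
  expect_equal(unname(sim$data$y$features), unname(Zl %*% t(sim$truth$Wy)))
  # with sigma_b = sigma_eps = 0 all individuals share the population curve
  for (k in 1:2)
    expect_equal(sim$truth$z[, , k],
                 matrix(sim$truth$population_curves[, k], 8, 5, byrow = TRUE),
                 ignore_attr = TRUE)
})

test_that("observation noise has unit marginal variance and the AR(1) lag-1 correlation", {
  # no latent signal: flat curves, no individual effects -> pure noise view
  cfg <- sim_config(n = 80, p = 400, q = 10, n_times = 10, theta0 = 0,
                    theta1 = 0, theta2 = 0, sigma_b = 0, sigma_eps = 0,
                    support_x = 1, support_y = 1, n_components = 1,
                    miss_x = 0, miss_y = 0, rho_t = 0.3, seed = 77)
  sim <- generate_dataset(cfg)
  E <- sim$data$x$features[, -1L]  # drop the single signal-carrying feature
  tt <- sim$data$x$times
  v <- apply(E, 2L, var)
  expect_lt(abs(mean(v) - 1), 3 * sd(v) / sqrt(length(v)))
  lag1 <- apply(E, 2L, function(col) cor(col[tt < 10], col[tt > 1]))
  expect_lt(abs(mean(lag1) - 0.3), 3 * sd(lag1) / sqrt(length(lag1)))
})

test_that("evaluate_recovery scores oracle and disjoint supports correctly", {
  cfg <- sim_config(n = 20, p = 30, q = 15, n_times = 8, sigma_b = 0,
                    sigma_eps = 0, miss_x = 0.1, miss_y = 0.1, seed = 9)
  sim <- generate_dataset(cfg)
  # inject the exact truth as a fitted result
  idx <- sim$data$x$ids; tx <- sim$data$x$times
  idy <- sim$data$y$ids; ty <- sim$data$y$times
  mk_comp <- function(k) {
    zfull_x <- as.vector(t(sim$truth$z[, , k]))[sim$truth$keep_x]
    zfull_y <- as.vector(t(sim$truth$z[, , k]))[sim$truth$keep_y]
    structure(list(wx = sim$truth$Wx[, k], wy = sim$truth$Wy[, k],
                   eta = zfull_x / sqrt(sum(zfull_x^2)),
                   gamma = zfull_y / sqrt(sum(zfull_y^2)),
                   eta_fit = NULL, gamma_fit = NULL, rho = 1, rho_y = 1,
                   n_iter = 1L, converged = TRUE, degenerate = FALSE,
                   px = cfg$support_x, qy = cfg$support_y),
              class = "canonical_component")
  }
  oracle_fit <- structure(list(components = list(mk_comp(1), mk_comp(2)), k = 2L,
                               rows = list(idx = idx, tx = tx, idy = idy, ty = ty),
                               rho = c(1, 1)),
                          class = "tosccamm")
  metrics <- evaluate_recovery(sim, oracle_fit)
  expect_equal(metrics$tp_x, c(10L, 10L))
  expect_equal(metrics$fp_x, c(0L, 0L))
  expect_equal(metrics$tp_y, c(5L, 5L))
  expect_equal(metrics$trajectory_cor, c(1, 1), tolerance = 1e-8)
  expect_equal(metrics$latent_cor, c(1, 1), tolerance = 1e-8)

  # disjoint estimated support scores zero true positives
  wrong <- oracle_fit
  w2 <- oracle_fit$components[[1L]]$wx * 0
  w2[21:30] <- 0.3  # outside both true supports (1:10 and 11:20)
  wrong$components[[1L]]$wx <- w2
  m2 <- evaluate_recovery(sim, wrong)
  expect_equal(m2$tp_x[m2$est_comp == 1L], 0L)
})

test_that("simulation artifacts are written and byte-stable", {
  cfg <- sim_config(n = 6, p = 8, q = 5, n_times = 4,
                    support_x = 3, support_y = 2, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(generate_dataset(cfg), d1)
  write_simulation(generate_dataset(cfg), d2)
  for (f in c("x.csv", "y.csv", "truth_weights.csv", "truth_latent.csv",
              "config.yaml", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$n_rows_x, 6 * 4 - round(0.2 * 24))
  # the long CSV round-trips back into the same view
  v <- read_long_csv(file.path(d1, "x.csv"))
  sim <- generate_dataset(cfg)
  expect_equal(v$features, sim$data$x$features, tolerance = 1e-12)
})
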