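test_that("top-k soft-thresholding matches the hand-worked example and edge cases", {
  w <- c(3, -2, 1, 0.5)
  # lambda = 3rd largest |w| = 1; shrink then normalize
  expect_equal(soft_threshold_topk(w, 2), c(2, -1, 0, 0) / sqrt(5))
  # k = length(w): direction unchanged
  expect_equal(soft_threshold_topk(w, 4), w / sqrt(sum(w^2)))
  # all-zero input flagged, not normalized
  z <- soft_threshold_topk(c(0, 0, 0), 2)
  expect_equal(as.numeric(z), c(0, 0, 0))
  expect_true(attr(z, "degenerate"))
  expect_error(soft_threshold_topk(w, 0), "k must be")
  expect_error(soft_threshold_topk(w, 5), "k must be")
})

test_that("thresholding yields exact cardinality and unit norm on generic vectors", {
  set.seed(1)
  for (rep in 1:25) {
    p <- sample(5:40, 1)
    w <- rnorm(p)
    k <- sample(seq_len(p), 1)
    out <- soft_threshold_topk(w, k)
    expect_equal(sum(out != 0), k)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    # support is the top-k of |w|
    expect_setequal(which(out != 0), order(abs(w), decreasing = TRUE)[seq_len(k)])
    # signs are preserved on the support
    expect_equal(sign(out[out != 0]), sign(w[out != 0]))
  }
})

test_that("deflation projects out the score exactly and is idempotent", {
  set.seed(4)
  M <- matrix(rnorm(60), 12, 5)
  s <- rnorm(12); s <- s / sqrt(sum(s^2))
  D <- deflate(M, s)
  expect_lt(max(abs(drop(crossprod(D, s)))), 1e-10)
  expect_equal(deflate(D, s), D, tolerance = 1e-12)
  expect_equal(deflate(matrix(0, 12, 5), s), matrix(0, 12, 5))
  expect_error(deflate(M, s[1:5]), "length")
})

test_that("a view perfectly correlated with itself yields rho ~ 1", {
  # single shared feature following individual lines, identical grids
  set.seed(11)
  n <- 15; m <- 6
  ids <- rep(sprintf("i%02d", 1:n), each = m)
  t <- rep(1:m, n)
  val <- rnorm(n, sd = 1.5)[match(ids, unique(ids))] + 2 * t +
    rnorm(n * m, sd = 0.05)
  v <- longitudinal_view(ids, t, cbind(f = val))
  pd <- suppressWarnings(paired_longitudinal(v, v))
  sx <- standardize_columns(pd$x)$view
  pd_std <- paired_longitudinal(sx, sx)
  comp <- nipals_component(pd_std, px = 1, qy = 1,
                           spec_x = trajectory_spec("random_intercept_linear"),
                           spec_y = trajectory_spec("random_intercept_linear"),
                           init = 3)
  expect_gte(comp$rho, 0.99)
  # the passthrough reduction attains it exactly
  comp_pt <- nipals_component(pd_std, px = 1, qy = 1,
                              spec_x = trajectory_spec("passthrough"),
                              spec_y = trajectory_spec("passthrough"),
                              init = 3)
  expect_equal(comp_pt$rho, 1, tolerance = 1e-12)
})

test_that("tiny instance matches exhaustive search over 1-sparse weight pairs", {
  set.seed(42)
  n <- 4
  ids <- letters[1:4]; t <- rep(1, 4)
  X <- matrix(rnorm(8), n, 2); Y <- matrix(rnorm(8), n, 2)
  pd <- suppressWarnings(paired_longitudinal(
    longitudinal_view(ids, t, X), longitudinal_view(ids, t, Y)))
  sx <- standardize_columns(pd$x)$view
  sy <- standardize_columns(pd$y)$view
  pd_std <- paired_longitudinal(sx, sy)
  # exhaustive oracle: all unit-norm 1-sparse pairs, sign-free correlation
  brute <- max(abs(outer(1:2, 1:2, Vectorize(function(i, j)
    cor(sx$features[, i], sy$features[, j])))))
  comp <- nipals_component(pd_std, px = 1, qy = 1,
                           spec_x = trajectory_spec("passthrough"),
                           spec_y = trajectory_spec("passthrough"),
                           init = 5)
  expect_equal(comp$rho, brute, tolerance = 1e-3)
})

test_that("single-visit passthrough fits reduce to the plain cross-sectional loop", {
  pd <- single_visit_pair(n = 14, p = 6, q = 5, seed = 9)
  seed <- 31
  fit <- tosccamm(pd, k = 2, px = 3, qy = 2,
                  spec_x = trajectory_spec("passthrough"),
                  spec_y = trajectory_spec("passthrough"),
                  seed = seed)
  # independent oracle run on the same standardized matrices with the same
  # deterministic initialization sequence and deflation scheme
  X <- standardize_columns(pd$x)$view$features
  Y <- standardize_columns(pd$y)$view$features
  set.seed(seed)
  inits <- replicate(2, rnorm(ncol(X)), simplify = FALSE)
  for (kk in 1:2) {
    o <- plain_toscca(X, Y, px = 3, qy = 2, init = inits[[kk]])
    cc <- fit$components[[kk]]
    expect_equal(unname(cc$wx), o$wx, tolerance = 1e-8)
    expect_equal(unname(cc$wy), o$wy, tolerance = 1e-8)
    expect_equal(cc$eta, o$eta, tolerance = 1e-8)
    expect_equal(cc$rho, o$rho, tolerance = 1e-8)
    X <- X - o$eta %*% t(o$eta) %*% X
    Y <- Y - o$gamma %*% t(o$gamma) %*% Y
  }
})

test_that("sequential extraction is prefix-stable and latent scores orthogonal", {
  sim <- small_sim(seed = 13)
  spec <- cubic_spec()
  f1 <- tosccamm(sim$data, k = 1, px = 8, qy = 4, spec_x = spec, spec_y = spec,
                 seed = 6)
  f2 <- tosccamm(sim$data, k = 2, px = 8, qy = 4, spec_x = spec, spec_y = spec,
                 seed = 6)
  expect_equal(f1$components[[1L]]$wx, f2$components[[1L]]$wx)
  expect_equal(f1$components[[1L]]$rho, f2$components[[1L]]$rho)

  f3 <- tosccamm(sim$data, k = 3, px = 8, qy = 4, spec_x = spec, spec_y = spec,
                 seed = 6)
  etas <- sapply(f3$components, `[[`, "eta")
  gammas <- sapply(f3$components, `[[`, "gamma")
  off <- function(M) { G <- crossprod(M); max(abs(G[upper.tri(G)])) }
  expect_lt(off(etas), 1e-6)
  expect_lt(off(gammas), 1e-6)
  # unit sample norm convention for the latent variables
  expect_equal(colSums(etas^2), rep(1, 3), tolerance = 1e-10)
  expect_equal(colSums(gammas^2), rep(1, 3), tolerance = 1e-10)
  expect_true(all(f3$rho >= 0))
})

test_that("fits are deterministic given the seed and error paths are clean", {
  sim <- small_sim(seed = 17, n = 20, p = 15, q = 10)
  spec <- trajectory_spec("random_intercept_linear")
  f1 <- tosccamm(sim$data, k = 2, px = 5, qy = 3, spec_x = spec, spec_y = spec,
                 seed = 99)
  f2 <- tosccamm(sim$data, k = 2, px = 5, qy = 3, spec_x = spec, spec_y = spec,
                 seed = 99)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rho, f2$rho)

  expect_error(tosccamm(sim$data, k = 1, px = 5, qy = 3, spec_x = spec,
                        spec_y = spec), "seed")
  expect_error(tosccamm(sim$data, k = 1, px = 500, qy = 3, spec_x = spec,
                        spec_y = spec, seed = 1), "px")
})

test_that("an all-zero view produces a flagged degenerate component", {
  n <- 10
  ids <- sprintf("i%02d", 1:n)
  pd <- suppressWarnings(paired_longitudinal(
    longitudinal_view(ids, 1:n, matrix(0, n, 3)),
    longitudinal_view(ids, 1:n, matrix(rnorm(n * 2), n, 2))))
  comp <- nipals_component(pd, px = 1, qy = 1,
                           spec_x = trajectory_spec("passthrough"),
                           spec_y = trajectory_spec("passthrough"), init = 1)
  expect_true(comp$degenerate)
  expect_false(comp$converged)
  expect_equal(comp$rho, 0)
})

test_that("methods print, summarize, predict and plot without error", {
  sim <- small_sim(seed = 19, n = 15, p = 10, q = 8, n_times = 6)
  spec <- trajectory_spec("random_intercept_linear")
  fit <- tosccamm(sim$data, k = 2, px = 4, qy = 3, spec_x = spec, spec_y = spec,
                  seed = 2)
  expect_output(print(fit), "component")
  expect_output(print(summary(fit)), "Adjusted CPEV")
  expect_equal(dim(coef(fit, "x")), c(10L, 2L))
  expect_equal(dim(coef(fit, "y")), c(8L, 2L))
  pr <- predict(fit, ids = c(sim$data$x$ids[1L], "unseen"), times = c(2, 2),
                component = 1, view = "x")
  expect_length(pr, 2L)
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit, component = 1, view = "x"))

  dir <- withr::local_tempdir()
  write_tosccamm(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.csv", "scores.csv",
                                               "summary.json")))))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$k, 2L)
  w <- read.csv(file.path(dir, "weights.csv"))
  expect_true(all(w$weight != 0))
})
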