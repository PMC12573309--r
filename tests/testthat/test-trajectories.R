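test_that("design bases match hand-computed values", {
  cp <- trajectory_spec("change_point", change_point = 0)
  expect_equal(unname(design_row(cp, -1)), c(1, -1, 1, -1, 0))
  expect_equal(unname(design_row(cp, 2)), c(1, 2, 4, 8, 2))
  expect_equal(unname(design_row(trajectory_spec("random_intercept_linear"), 0)),
               c(1, 0))
  expect_equal(unname(design_row(trajectory_spec("random_intercept_polynomial",
                                                 degree = 2), 3)),
               c(1, 3, 9))
  # shifted parameterization uses (t - s) after the change point
  cps <- trajectory_spec("change_point", change_point = 1, shifted = TRUE)
  expect_equal(unname(design_row(cps, 3)), c(1, 3, 9, 27, 2))
})

test_that("noiseless family data are recovered exactly", {
  ids <- rep(c("a", "b", "c"), each = 5)
  t <- rep(1:5, 3)
  alpha <- c(a = -1, b = 0, c = 1)
  val <- alpha[ids] + 2 * t
  fit <- fit_trajectory(trajectory_spec("random_intercept_linear"), ids, t, val)
  expect_equal(unname(fit$fixed_effects["t"]), 2, tolerance = 1e-6)
  re <- fit$random_intercepts[c("a", "b", "c")]
  expect_equal(unname(re), unname(alpha - mean(alpha)), tolerance = 1e-4)

  # constant per individual: slope ~ 0, fitted values = individual means
  val2 <- alpha[ids]
  fit2 <- fit_trajectory(trajectory_spec("random_intercept_linear"), ids, t, val2)
  expect_equal(unname(fit2$fixed_effects["t"]), 0, tolerance = 1e-6)
  expect_equal(unname(fit2$fitted), unname(val2), tolerance = 1e-4)

  # noiseless cubic recovered by the cubic family
  ids3 <- rep(c("a", "b"), each = 6)
  t3 <- rep(0:5, 2)
  val3 <- c(a = 0.5, b = -0.5)[ids3] + 1 + 0.3 * t3 - 0.2 * t3^2 + 0.05 * t3^3
  fit3 <- fit_trajectory(trajectory_spec("random_intercept_polynomial", degree = 3),
                         ids3, t3, val3)
  expect_equal(unname(fit3$fixed_effects[-1L]), c(0.3, -0.2, 0.05), tolerance = 1e-5)
})

test_that("simulated random-intercept data recover the generating parameters", {
  set.seed(914)
  n <- 200; m <- 8; beta <- 1.5; sb <- 1.0; se <- 0.5
  ids <- rep(sprintf("i%03d", 1:n), each = m)
  t <- rep(1:m, n)
  b <- rnorm(n, sd = sb)
  val <- b[match(ids, unique(ids))] + beta * t + rnorm(n * m, sd = se)
  fit <- fit_trajectory(trajectory_spec("random_intercept_linear"), ids, t, val)
  # Monte-Carlo SE of the slope for this balanced design
  se_beta <- se / sqrt(n * sum((1:m - mean(1:m))^2))
  expect_lt(abs(fit$fixed_effects[["t"]] - beta), 3 * se_beta)
  expect_lt(abs(fit$variance_components[["var_intercept"]] - sb^2) / sb^2, 0.2)
  expect_lt(abs(fit$variance_components[["var_residual"]] - se^2) / se^2, 0.2)
})

test_that("prediction is consistent, linear, and prior-mean for unseen ids", {
  set.seed(3)
  ids <- rep(c("a", "b", "c", "d"), each = 6)
  t <- rep(1:6, 4)
  val <- rnorm(4, sd = 1)[match(ids, c("a", "b", "c", "d"))] + 0.7 * t +
    rnorm(length(t), sd = 0.3)
  fit <- fit_trajectory(trajectory_spec("random_intercept_linear"), ids, t, val)

  expect_equal(predict_trajectory(fit, ids, t), fit$fitted)
  # unseen id lies exactly on the fixed-effects line
  p_new <- predict_trajectory(fit, c("zz", "zz"), c(0, 1))
  expect_equal(p_new[1L], unname(fit$fixed_effects[1L]))
  expect_equal(diff(p_new), unname(fit$fixed_effects["t"]))
  # seen id: predictions at t and t+1 differ by exactly the slope
  p_a <- predict_trajectory(fit, c("a", "a"), c(10, 11))
  expect_equal(diff(p_a), unname(fit$fixed_effects["t"]))
  expect_equal(p_a[1L],
               unname(fit$fixed_effects[1L] + 10 * fit$fixed_effects["t"] +
                        fit$random_intercepts[["a"]]))
})

test_that("BLUP intercepts equal the closed-form shrinkage of mean residuals", {
  set.seed(21)
  mi <- c(a = 3L, b = 8L, c = 5L, d = 12L)  # unbalanced on purpose
  ids <- rep(names(mi), mi)
  t <- unlist(lapply(mi, seq_len), use.names = FALSE)
  val <- rnorm(4, sd = 1.2)[match(ids, names(mi))] + 0.4 * t +
    rnorm(length(t), sd = 0.8)
  fit <- fit_trajectory(trajectory_spec("random_intercept_linear"), ids, t, val)
  sb2 <- fit$variance_components[["var_intercept"]]
  se2 <- fit$variance_components[["var_residual"]]
  skip_if(sb2 == 0, "boundary fit")
  X <- design_matrix(fit$spec, t)
  resid_fe <- val - drop(X %*% fit$fixed_effects)
  for (id in names(mi)) {
    lam <- sb2 / (sb2 + se2 / mi[[id]])
    expect_equal(fit$random_intercepts[[id]],
                 lam * mean(resid_fe[ids == id]), tolerance = 1e-4)
  }
  # shrinkage factor decreases as residual variance grows (closed form)
  lam_small <- sb2 / (sb2 + se2 / 3)
  lam_big <- sb2 / (sb2 + 4 * se2 / 3)
  expect_lt(lam_big, lam_small)
})

test_that("degenerate designs error or fall back as specified", {
  ids <- rep(c("a", "b"), each = 2)
  expect_error(fit_trajectory(trajectory_spec("random_intercept_polynomial",
                                              degree = 3),
                              ids, rep(1:2, 2), rnorm(4)),
               "rank deficiency|distinct time")
  expect_error(fit_trajectory(trajectory_spec("random_intercept_linear"),
                              rep("a", 5), 1:5, rnorm(5)),
               "2 distinct individuals")
  # data that defeat the mixed model (one observation per individual) fall
  # back to fixed-effects least squares with zero intercept variance
  set.seed(8)
  ids1 <- letters[1:10]
  fit <- fit_trajectory(trajectory_spec("random_intercept_linear"),
                        ids1, 1:10, rnorm(10))
  expect_true(fit$fallback)
  expect_equal(fit$variance_components[["var_intercept"]], 0)
  expect_true(all(fit$random_intercepts == 0))
})

test_that("passthrough returns training scores on the training grid only", {
  ids <- c("a", "a", "b")
  t <- c(1, 2, 1)
  val <- c(0.3, -0.1, 0.5)
  fit <- fit_trajectory(trajectory_spec("passthrough"), ids, t, val)
  expect_equal(predict_trajectory(fit, ids, t), val)
  expect_equal(predict_trajectory(fit, c("b", "a"), c(1, 2)), c(0.5, -0.1))
  expect_error(predict_trajectory(fit, "a", 99), "training")
})
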