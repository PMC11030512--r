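test_that("penalty weights are column standard deviations with unit intercept", {
  d <- toy_data(n = 80, p = 1, seed = 31, prop = c(0.5, 0.3, 0.2))
  dm <- build_design(toy_spec(d), d)
  w <- penalty_weights(dm)
  expect_identical(unname(w["(Intercept)"]), 1)
  n <- dm$n
  for (lv in attr(d, "levels")) {
    q <- unname(dm$dist$marginal$group[lv])
    expect_equal(unname(w[paste0("group[", lv, "]")]),
                 sqrt(q * (1 - q) * n / (n - 1)),  # closed-form 0/1 SD
                 tolerance = 1e-12)
  }
  # standardized continuous column has unit weight
  dms <- build_design(toy_spec(d, standardize = TRUE), d)
  expect_equal(unname(penalty_weights(dms)["x1"]), 1, tolerance = 1e-12)
  # zero-variance non-intercept column is an error
  d0 <- d; d0$x1 <- 0
  dm0 <- build_design(toy_spec(d0), d0)
  expect_error(penalty_weights(dm0), "zero-variance")
})

test_that("ridge reproduces OLS at lambda 0 and shrinks to zero at huge lambda", {
  d <- toy_data(n = 100, p = 2, seed = 32)
  dm <- build_design(toy_spec(d, standardize = TRUE), d)
  cs <- build_constraints(dm, "abc")
  w <- penalty_weights(dm)
  f <- fit_ols(dm, cs)
  r0 <- fit_ridge(dm, cs, 0, weights = w)
  expect_lt(max(abs(r0$theta - f$theta)), 1e-8)
  big <- 1e8 * norm(crossprod(dm$X), "2")
  rb <- fit_ridge(dm, cs, big, weights = w)
  expect_lt(sqrt(sum(rb$theta^2)), 1e-3 * sqrt(sum(r0$theta^2)))
  expect_error(fit_ridge(dm, build_constraints(dm, "over"), 0, weights = w),
               "singular")
})

test_that("ridge closed form agrees with a generic convex minimizer", {
  for (seed in c(41, 42, 43)) {
    dm <- random_instance(seed)
    cs <- build_constraints(dm, sample(c("abc", "rge", "stz", "over"), 1))
    w <- penalty_weights(dm)
    lambda <- stats::runif(1, 0.5, 5)
    r <- fit_ridge(dm, cs, lambda, weights = w)
    oracle <- ridge_optim_oracle(dm, cs, lambda, w)
    expect_lt(max(abs(r$theta - oracle)), 1e-6)
  }
})

test_that("lasso path endpoints bracket OLS and full sparsity", {
  d <- toy_data(n = 150, p = 2, seed = 33, modifier = 0.5)
  dm <- build_design(toy_spec(d, standardize = TRUE), d)
  cs <- build_constraints(dm, "abc")
  w <- penalty_weights(dm)
  f <- fit_ols(dm, cs)
  grid <- lambda_grid(dm, cs, weights = w, nlambda = 60,
                      lambda_min_ratio = 1e-6)
  path <- fit_lasso_path(dm, cs, lambda = grid, weights = w)
  expect_lt(max(abs(path$theta[, 60] - f$theta)), 1e-4)
  expect_lt(max(abs(path$theta[, 1])), 1e-6)
  # at twice the data-derived fully-sparse level, still all zero
  p2 <- fit_lasso_path(dm, cs, lambda = 2 * grid[1], weights = w)
  expect_lt(max(abs(p2$theta)), 1e-6)
})

test_that("constraints and KKT certificates hold along the whole path", {
  d <- toy_data(n = 120, p = 2, seed = 34, modifier = 0.6,
                prop = c(0.5, 0.3, 0.2))
  dm <- build_design(toy_spec(d), d)
  for (sc in c("abc", "rge", "stz")) {
    cs <- build_constraints(dm, sc)
    w <- penalty_weights(dm)
    path <- fit_lasso_path(dm, cs, weights = w)
    resid <- apply(path$theta, 2, function(t) constraint_residual(cs, t))
    expect_lt(max(resid), 1e-6)
    expect_lt(max(path$diagnostics$stationarity), 1e-5)
    expect_lt(max(path$diagnostics$dual_slack), 1e-6)
  }
})

test_that("optimal objective is nondecreasing and the penalty nonincreasing in lambda", {
  d <- toy_data(n = 100, p = 2, seed = 35)
  dm <- build_design(toy_spec(d), d)
  cs <- build_constraints(dm, "abc")
  w <- penalty_weights(dm)
  path <- fit_lasso_path(dm, cs, weights = w)
  lam <- path$lambda
  ssr <- apply(path$theta, 2, function(t) sum((dm$y - dm$X %*% t)^2))
  pen <- apply(path$theta, 2, function(t) sum(w * abs(t)))
  objective <- ssr + lam * pen
  # grid is decreasing, so the optimum must decrease down the grid
  expect_true(all(diff(objective) <= 1e-6 * (1 + abs(objective[-1]))))
  expect_true(all(diff(pen) >= -1e-8 * (1 + pen[-1])))
})

test_that("overparametrized lasso zeroes a coefficient in every variable block", {
  set.seed(36)
  n <- 150
  g <- sample(c("A", "B", "C"), n, TRUE, c(0.5, 0.3, 0.2))
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + x1 - 0.5 * x2 + 0.6 * x1 * (g == "B") + rnorm(n, sd = 0.7)
  d <- data.frame(y = y, x1 = x1, x2 = x2, group = g)
  spec <- abc_spec("y", c("x1", "x2"), list(group = c("A", "B", "C")), "all")
  dm <- build_design(spec, d)
  cs <- build_constraints(dm, "over")
  w <- penalty_weights(dm)
  grid <- lambda_grid(dm, cs, weights = w, nlambda = 50)
  path <- fit_lasso_path(dm, cs, lambda = grid, weights = w)
  th <- path$theta[, 50]  # smallest positive lambda
  for (xv in c("x1", "x2")) {
    blk <- th[c(xv, paste0(xv, ":group[", c("A", "B", "C"), "]"))]
    expect_lt(min(abs(blk)), 1e-6)
  }
  blk0 <- th[c("(Intercept)", paste0("group[", c("A", "B", "C"), "]"))]
  expect_lt(min(abs(blk0)), 1e-6)
})

test_that("a zeroed modifier equates group and average slopes under abundance constraints", {
  d <- toy_data(n = 150, p = 2, seed = 37, modifier = 1.0)
  dm <- build_design(toy_spec(d), d)
  cs <- build_constraints(dm, "abc")
  w <- penalty_weights(dm)
  path <- fit_lasso_path(dm, cs, weights = w)
  slopes <- path_slopes(path)
  pi_hat <- dm$dist$marginal$group
  hit <- 0L
  for (i in seq_along(path$lambda)) {
    th <- path$theta[, i]
    for (xv in c("x1", "x2")) {
      gam <- th[paste0(xv, ":group[", attr(d, "levels"), "]")]
      zeroed <- abs(gam) < 1e-8
      if (!any(zeroed)) next
      hit <- hit + 1L
      s <- slopes[slopes$lambda == path$lambda[i] &
                    slopes$continuous == xv, ]
      avg <- sum(pi_hat[s$level] * s$slope)  # race-averaged slope
      for (lv in attr(d, "levels")[zeroed])
        expect_equal(s$slope[s$level == lv], avg, tolerance = 1e-6)
    }
  }
  expect_gt(hit, 0L)
})

test_that("solver failure surfaces the offending lambda", {
  d <- toy_data(n = 100, p = 2, seed = 38)
  dm <- build_design(toy_spec(d), d)
  cs <- build_constraints(dm, "abc")
  expect_error(fit_lasso_path(dm, cs, max_iter = 2L), "did not converge")
})

test_that("cross-validation follows the one-standard-error rule deterministically", {
  d <- toy_data(n = 150, p = 2, seed = 39, modifier = 0.4)
  dm <- build_design(toy_spec(d), d)
  cs <- build_constraints(dm, "abc")
  w <- penalty_weights(dm)
  grid <- lambda_grid(dm, cs, weights = w, nlambda = 40)
  cv1 <- cross_validate(dm, cs, "lasso", lambda = grid, weights = w,
                        K = 5, seed = 11)
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  expect_equal(cv1$lambda_1se,
               max(grid[cv1$cvm <= min(cv1$cvm) +
                          cv1$cvsd[which.min(cv1$cvm)]]))
  cv2 <- cross_validate(dm, cs, "lasso", lambda = grid, weights = w,
                        K = 5, seed = 11)
  expect_identical(cv1$cvm, cv2$cvm)
  expect_identical(cv1$folds, cv2$folds)
  cv3 <- cross_validate(dm, cs, "ridge", lambda = grid, weights = w,
                        K = 5, seed = 11)
  expect_gte(cv3$lambda_1se, cv3$lambda_min)
})

test_that("folds are stratified and losing a level is an error", {
  d <- toy_data(n = 120, p = 1, seed = 40, prop = c(0.45, 0.45, 0.1))
  dm <- build_design(toy_spec(d), d)
  folds <- abcreg:::stratified_folds(dm, 4, seed = 5)
  for (k in 1:4)
    expect_setequal(unique(dm$labels$group[folds != k]), attr(d, "levels"))

  # a singleton level must trip the fold check
  d1 <- d
  d1$group[1] <- "Z"
  spec1 <- abc_spec("y", "x1", list(group = c(attr(d, "levels"), "Z")),
                    modifiers = "none")
  dm1 <- build_design(spec1, d1)
  cs1 <- build_constraints(dm1, "abc")
  expect_error(cross_validate(dm1, cs1, "ridge", K = 4, seed = 5),
               "loses level")
})
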