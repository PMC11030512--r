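test_that("noiseless identity data are recovered exactly under every scheme", {
  d <- data.frame(y = numeric(12), x1 = rnorm(12),
                  group = rep(c("A", "B"), each = 6))
  d$y <- d$x1
  spec <- abc_spec("y", "x1", list(group = c("A", "B")), modifiers = "all")
  dm <- build_design(spec, d)
  for (sc in c("abc", "rge", "stz")) {
    f <- fit_ols(dm, build_constraints(dm, sc))
    expect_equal(unname(f$theta["x1"]), 1, tolerance = 1e-10)
    others <- setdiff(names(f$theta), "x1")
    expect_lt(max(abs(f$theta[others])), 1e-10)
  }
})

test_that("null-space fit agrees with the bordered KKT oracle", {
  for (seed in 1:30) {
    dm <- random_instance(seed)
    for (sc in c("abc", "rge", "stz")) {
      cs <- build_constraints(dm, sc)
      f1 <- fit_ols(dm, cs)
      f2 <- fit_ols_kkt(dm, cs)
      expect_lt(max(abs(f1$theta - f2$theta)), 1e-8)
      expect_lt(constraint_residual(cs, f1$theta), 1e-8)
    }
  }
})

test_that("reference-group fit reduces to textbook OLS on the dropped-column design", {
  d <- toy_data(n = 80, p = 2, seed = 12)
  dm <- build_design(toy_spec(d, modifiers = "none"), d)
  cs <- build_constraints(dm, "rge")
  f <- fit_ols(dm, cs)
  # classical lm parametrization with treatment contrasts
  lmfit <- stats::lm(y ~ x1 + x2 + factor(group), data = d)
  expect_equal(unname(f$theta["(Intercept)"]),
               unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(unname(f$theta[c("x1", "x2")]),
               unname(coef(lmfit)[2:3]), tolerance = 1e-10)
  expect_equal(unname(f$theta["group[B]"]),
               unname(coef(lmfit)["factor(group)B"]), tolerance = 1e-10)
  expect_equal(unname(f$theta["group[A]"]), 0, tolerance = 1e-12)
})

test_that("fitted values and group slopes are invariant to the scheme under OLS", {
  d <- toy_data(n = 150, p = 2, seed = 13, modifier = 0.8)
  dm <- build_design(toy_spec(d), d)
  fits <- lapply(c("abc", "rge", "stz"), function(sc)
    fit_ols(dm, build_constraints(dm, sc)))
  for (i in 2:3) {
    expect_lt(max(abs(fits[[1]]$fitted - fits[[i]]$fitted)), 1e-8)
    s1 <- group_specific_slopes(fits[[1]], "x1", "group")
    si <- group_specific_slopes(fits[[i]], "x1", "group")
    expect_lt(max(abs(s1$estimate - si$estimate)), 1e-8)
    expect_lt(max(abs(s1$se - si$se)), 1e-8)
  }
})

test_that("the estimate is invariant to the particular null-space basis", {
  d <- toy_data(n = 100, p = 2, seed = 14, modifier = 0.5)
  dm <- build_design(toy_spec(d), d)
  cs <- build_constraints(dm, "abc")
  f <- fit_ols(dm, cs)
  b <- null_space_basis(cs)
  set.seed(99)
  k <- ncol(b$Q)
  rot <- qr.Q(qr(matrix(rnorm(k * k), k)))  # random orthogonal rotation
  Q2 <- b$Q %*% rot
  zeta2 <- qr.coef(qr(dm$X %*% Q2), dm$y)
  theta2 <- drop(Q2 %*% zeta2)
  expect_lt(max(abs(theta2 - f$theta)), 1e-8)
})

test_that("abundance identities hold exactly for the fitted coefficients", {
  d <- toy_data(n = 120, p = 2, seed = 15, prop = c(0.5, 0.3, 0.2),
                modifier = 0.6)
  dm <- build_design(toy_spec(d), d)
  cs <- build_constraints(dm, "abc")
  f <- fit_ols(dm, cs)
  pi_hat <- dm$dist$marginal$group
  beta <- f$theta[dm$meta$role == "dummy"]
  expect_lt(abs(sum(pi_hat * beta)), 1e-10)
  for (xv in c("x1", "x2")) {
    s <- group_specific_slopes(f, xv, "group")
    expect_lt(abs(sum(pi_hat * s$estimate) - f$theta[xv]), 1e-10)
    gam <- f$theta[dm$meta$role == "interaction" &
                     dm$meta$continuous == xv]
    expect_lt(abs(sum(pi_hat * gam)), 1e-10)
  }
})

test_that("equal-abundance two-level effects are equal and opposite with one SE", {
  set.seed(16)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40),
                  sex = rep(c("F", "M"), 20))
  spec <- abc_spec("y", "x1", list(sex = c("F", "M")), modifiers = "all")
  dm <- build_design(spec, d)
  f <- fit_ols(dm, build_constraints(dm, "abc"))
  tab <- coefficient_inference(f)
  lev <- tab[tab$role == "dummy", ]
  expect_equal(lev$estimate[1], -lev$estimate[2], tolerance = 1e-10)
  expect_equal(lev$se[1], lev$se[2], tolerance = 1e-10)
  mod <- tab[tab$role == "interaction", ]
  expect_equal(mod$estimate[1], -mod$estimate[2], tolerance = 1e-10)
  expect_equal(mod$se[1], mod$se[2], tolerance = 1e-10)
})

test_that("reported standard errors match a Monte-Carlo oracle", {
  d <- toy_data(n = 60, p = 1, seed = 17)
  dm <- build_design(toy_spec(d), d)
  cs <- build_constraints(dm, "abc")
  b <- null_space_basis(cs)
  Z <- dm$X %*% b$Q
  H <- b$Q %*% solve(crossprod(Z), t(Z))  # theta-hat = H y
  sigma <- 0.8
  mu <- drop(dm$X %*% rep(0.5, ncol(dm$X)))
  set.seed(18)
  E <- matrix(rnorm(nrow(Z) * 2000, sd = sigma), nrow(Z))
  Theta <- H %*% (mu + E)
  emp_sd <- apply(Theta, 1, stats::sd)
  theo_se <- sqrt(diag(sigma^2 * b$Q %*% solve(crossprod(Z)) %*% t(b$Q)))
  expect_lt(max(abs(emp_sd / theo_se - 1)), 0.05)
  # and the reported SE from one fit is the same functional, with
  # sigma-hat in place of sigma
  f <- fit_ols(dm, cs, y = mu + E[, 1])
  expect_equal(unname(sqrt(diag(f$cov_theta)) / theo_se),
               rep(sqrt(f$sigma2) / sigma, ncol(dm$X)), tolerance = 1e-8)
})

test_that("confidence intervals follow the defining t formula", {
  d <- toy_data(n = 50, p = 1, seed = 19)
  dm <- build_design(toy_spec(d), d)
  f <- fit_ols(dm, build_constraints(dm, "abc"))
  tab <- coefficient_inference(f, level = 0.95)
  tcrit <- stats::qt(0.975, df = f$dof)
  expect_equal(tab$lower, tab$estimate - tcrit * tab$se, tolerance = 1e-12)
  expect_equal(tab$upper, tab$estimate + tcrit * tab$se, tolerance = 1e-12)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_true(all(tab$se > 0))
})

test_that("linear combinations reproduce printed two-term sums", {
  # published bivariate fit: RI main effect -0.032, NHB modifier -0.038
  fit_biv <- list(theta = c(RI = -0.032, `RI:NHB` = -0.038),
                  cov_theta = NULL, dof = Inf)
  lc <- linear_combination(fit_biv, c(RI = 1, `RI:NHB` = 1))
  expect_equal(lc$estimate, -0.070, tolerance = 1e-12)
  # published multivariable fit: -0.020 and -0.020
  fit_mv <- list(theta = c(RI = -0.020, `RI:NHB` = -0.020),
                 cov_theta = NULL, dof = Inf)
  lc2 <- linear_combination(fit_mv, c(RI = 1, `RI:NHB` = 1))
  expect_equal(lc2$estimate, -0.040, tolerance = 1e-12)

  d <- toy_data(n = 40, p = 1, seed = 20)
  dm <- build_design(toy_spec(d), d)
  f <- fit_ols(dm, build_constraints(dm, "abc"))
  lc0 <- linear_combination(f, numeric(ncol(dm$X)))
  expect_identical(lc0$estimate, 0)
  expect_identical(lc0$se, 0)
  expect_error(linear_combination(f, c(bogus = 1)), "unknown")
})

test_that("group-specific slopes specialize correctly per scheme", {
  d <- toy_data(n = 90, p = 1, seed = 21, modifier = 0.7)
  dm <- build_design(toy_spec(d), d)
  f_rge <- fit_ols(dm, build_constraints(dm, "rge"))
  s <- group_specific_slopes(f_rge, "x1", "group")
  # gamma for the reference (first) level is pinned at 0
  expect_equal(s$estimate[1], unname(f_rge$theta["x1"]), tolerance = 1e-12)
  expect_error(group_specific_slopes(f_rge, "x1", "nope"),
               "not a modifier pair")
  d2 <- toy_data(n = 90, p = 2, seed = 22)
  spec2 <- abc_spec("y", c("x1", "x2"), list(group = attr(d2, "levels")),
                    modifiers = list(c("group", "x1")))
  dm2 <- build_design(spec2, d2)
  f2 <- fit_ols(dm2, build_constraints(dm2, "abc"))
  expect_error(group_specific_slopes(f2, "x2", "group"),
               "not a modifier pair")
})

test_that("within-group moments match a two-pass oracle and detect heterogeneity", {
  # location-shifted copies of one multiset: all scaled variances equal
  base <- c(-1.2, -0.4, 0.1, 0.5, 1.0)
  x <- c(base, base + 3, base - 2)
  g <- rep(c("A", "B", "C"), each = 5)
  vd <- variance_condition_diagnostic(x, g)
  expect_equal(vd$summary, 0, tolerance = 1e-12)

  # heterogeneous group SDs 0.7 / 1.0 / 1.3
  set.seed(23)
  sds <- c(0.7, 1.0, 1.3)
  n_r <- c(40, 30, 20)
  x2 <- unlist(mapply(function(n, s) rnorm(n, sd = s), n_r, sds))
  g2 <- rep(c("A", "B", "C"), n_r)
  vd2 <- variance_condition_diagnostic(x2, g2)
  expect_gt(vd2$summary, 0)
  for (i in seq_along(n_r)) {
    xi <- x2[g2 == c("A", "B", "C")[i]]
    two_pass <- mean((xi - mean(xi))^2)  # direct two-pass variance
    expect_equal(unname(vd2$sigma[i, 1, 1]), two_pass, tolerance = 1e-12)
  }
  # pooling identity: law of total variance on the empirical quantities
  w <- n_r / sum(n_r)
  pooled <- sum(w * vd2$sigma[, 1, 1]) +
    sum(w * (vd2$mean[, 1] - sum(w * vd2$mean[, 1]))^2)
  expect_equal(pooled, mean((x2 - mean(x2))^2), tolerance = 1e-12)

  expect_error(variance_condition_diagnostic(x2, rep("A", length(x2))),
               "at least 2 groups")
})

test_that("main-effect estimates are invariant to modifiers under exact equal variance", {
  d <- equal_variance_groups(c(40, 25, 15), c(0, 2, 5), seed = 24)
  set.seed(25)
  d$y <- 1 + d$x + 0.8 * d$x * (d$group == "B") -
    0.3 * d$x * (d$group == "C") + rnorm(nrow(d), sd = 0.5)
  spec_m <- abc_spec("y", "x", list(group = c("A", "B", "C")), "none")
  spec_f <- abc_spec("y", "x", list(group = c("A", "B", "C")), "all")
  dm_m <- build_design(spec_m, d)
  dm_f <- build_design(spec_f, d)
  disc <- sapply(c("abc", "rge", "stz"), function(sc) {
    aM <- fit_ols(dm_m, build_constraints(dm_m, sc))$theta["x"]
    a1 <- fit_ols(dm_f, build_constraints(dm_f, sc))$theta["x"]
    unname(abs(a1 - aM))
  })
  expect_lt(disc["abc"], 1e-8)
  expect_gt(disc["rge"], 1e-3)
  expect_gt(disc["stz"], 1e-3)
})

test_that("multivariable invariance holds under exact equal scaled covariance", {
  Sigma <- matrix(c(1, .4, .2, .4, 1, .3, .2, .3, 1), 3)
  d <- equal_cov_groups(c(50, 35, 20),
                        list(c(0, 0, 0), c(2, 1, 0), c(4, -1, 2)),
                        Sigma, seed = 26)
  set.seed(27)
  d$y <- 1 + as.matrix(d[, 1:3]) %*% c(1, -0.5, 0.7) +
    0.8 * d$x1 * (d$group == "B") - 0.4 * d$x2 * (d$group == "C") +
    rnorm(nrow(d), sd = 0.5)
  spec_m <- abc_spec("y", c("x1", "x2", "x3"),
                     list(group = c("A", "B", "C")), "none")
  spec_f <- abc_spec("y", c("x1", "x2", "x3"),
                     list(group = c("A", "B", "C")), "all")
  dm_m <- build_design(spec_m, d)
  dm_f <- build_design(spec_f, d)
  vd <- variance_condition_diagnostic(d[, 1:3], d$group)
  expect_lt(vd$summary, 1e-10)
  for (sc in c("abc", "rge", "stz")) {
    aM <- fit_ols(dm_m, build_constraints(dm_m, sc))$theta[c("x1", "x2", "x3")]
    a1 <- fit_ols(dm_f, build_constraints(dm_f, sc))$theta[c("x1", "x2", "x3")]
    if (sc == "abc") expect_lt(max(abs(a1 - aM)), 1e-8)
    else expect_gt(max(abs(a1 - aM)), 1e-3)
  }
})

test_that("degenerate fits fail loudly", {
  d <- toy_data(n = 60, p = 2, seed = 28)
  dm <- build_design(toy_spec(d), d)
  expect_error(fit_ols(dm, build_constraints(dm, "over")),
               "not identified for OLS")
  d_col <- d; d_col$x2 <- 2 * d_col$x1  # exact collinearity
  dm_col <- build_design(toy_spec(d_col), d_col)
  expect_error(fit_ols(dm_col, build_constraints(dm_col, "abc")),
               "collinear")
  # more parameters than observations
  d_small <- toy_data(n = 9, p = 2, seed = 29)
  dm_small <- build_design(toy_spec(d_small), d_small)
  expect_error(fit_ols(dm_small, build_constraints(dm_small, "abc")),
               "cannot identify")
})
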