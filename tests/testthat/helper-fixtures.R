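# Shared fixtures: all data are generated in code, deterministically.

# Simple grouped regression dataset with near-unit-scale covariates.
toy_data <- function(n = 120, p = 2, levels = c("A", "B", "C"),
                     prop = NULL, seed = 1, noise_sd = 0.5,
                     modifier = 0) {
  set.seed(seed)
  if (is.null(prop)) prop <- rep(1 / length(levels), length(levels))
  g <- sample(levels, n, replace = TRUE, prob = prop)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X)  # unit sample SD keeps the design well conditioned
  colnames(X) <- paste0("x", seq_len(p))
  y <- 1 + rowSums(X) + modifier * X[, 1] * (g == levels[2]) +
    stats::rnorm(n, sd = noise_sd)
  d <- data.frame(y = y, X, group = g, stringsAsFactors = FALSE)
  attr(d, "levels") <- levels
  d
}

toy_spec <- function(d, modifiers = "all", standardize = FALSE) {
  p <- sum(grepl("^x", names(d)))
  abc_spec("y", paste0("x", seq_len(p)),
           list(group = attr(d, "levels")),
           modifiers = modifiers, standardize = standardize)
}

# Groups of unequal size whose within-group scaled (divide-by-n) variance
# is EXACTLY equal: the hypothesis of the scalar invariance theorem.
equal_variance_groups <- function(n_r, means, var = 1, seed = 1) {
  set.seed(seed)
  x <- unlist(mapply(function(n, m) {
    z <- stats::rnorm(n)
    z <- z - mean(z)
    z <- z / sqrt(mean(z^2)) * sqrt(var)
    z + m
  }, n_r, means, SIMPLIFY = FALSE))
  data.frame(x = x, group = rep(LETTERS[seq_along(n_r)], n_r),
             stringsAsFactors = FALSE)
}

# Multivariate version: exactly equal within-group scaled covariance.
equal_cov_groups <- function(n_r, mus, Sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  tc <- chol(Sigma)
  X <- do.call(rbind, mapply(function(n, mu) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    Z <- sweep(Z, 2, colMeans(Z))
    S <- crossprod(Z) / n
    W <- Z %*% solve(chol(S))
    sweep(W %*% tc, 2, mu, "+")
  }, n_r, mus, SIMPLIFY = FALSE))
  colnames(X) <- paste0("x", seq_len(p))
  data.frame(X, group = rep(LETTERS[seq_along(n_r)], n_r),
             stringsAsFactors = FALSE)
}

# Random small instance for oracle-equivalence checks.
random_instance <- function(seed) {
  set.seed(seed)
  p <- sample(1:3, 1)
  G <- sample(2:4, 1)
  n <- 40 + sample(0:20, 1)
  levels <- LETTERS[seq_len(G)]
  g <- sample(levels, n, replace = TRUE)
  while (min(table(factor(g, levels))) < p + 2)
    g <- sample(levels, n, replace = TRUE)
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  theta_x <- stats::rnorm(p)
  y <- stats::rnorm(1) + drop(X %*% theta_x) + stats::rnorm(G)[match(g, levels)] +
    stats::rnorm(n, sd = 0.7)
  d <- data.frame(y = y, X, group = g, stringsAsFactors = FALSE)
  # random subset of modifier pairs (possibly none, possibly all)
  k <- sample(0:p, 1)
  mods <- if (k == 0) "none" else
    lapply(sample(seq_len(p), k), function(j) c("group", paste0("x", j)))
  spec <- abc_spec("y", paste0("x", seq_len(p)), list(group = levels),
                   modifiers = mods)
  build_design(spec, d)
}

# Generic smooth convex minimizer on the reduced coordinates, used as an
# independent oracle for the ridge closed form.
ridge_optim_oracle <- function(dm, cs, lambda, weights) {
  basis <- null_space_basis(cs)
  Z <- dm$X %*% basis$Q
  W <- weights
  obj <- function(zeta) {
    theta <- drop(basis$Q %*% zeta)
    sum((dm$y - Z %*% zeta)^2) + lambda * sum(W * theta^2)
  }
  gr <- function(zeta) {
    theta <- drop(basis$Q %*% zeta)
    drop(-2 * crossprod(Z, dm$y - Z %*% zeta) +
           2 * lambda * crossprod(basis$Q, W * theta))
  }
  res <- stats::optim(rep(0, ncol(Z)), obj, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  drop(basis$Q %*% res$par)
}
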