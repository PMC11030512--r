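#' Adaptive penalty weights from design column scales
#'
#' The penalty weight for each design column is its sample standard
#' deviation, with weight 1 for the intercept. This standardizes the penalty
#' across columns and, for the group-level columns, avoids overpenalizing
#' coefficients of low-abundance groups (whose identified coefficients are
#' larger by construction).
#'
#' @param dm An [build_design()] result.
#' @return Named numeric vector of positive weights, one per design column.
#' @export
penalty_weights <- function(dm) {
  stopifnot(inherits(dm, "abc_design"))
  w <- apply(dm$X, 2, stats::sd)
  w[dm$meta$role == "intercept"] <- 1
  bad <- names(w)[w <= 0 | !is.finite(w)]
  if (length(bad))
    stop("zero-variance design column(s) cannot be penalized: ",
         paste(bad, collapse = ", "))
  w
}

# Reduced-problem pieces shared by the penalized fitters.
penalized_parts <- function(dm, cs, y, weights) {
  basis <- null_space_basis(cs)
  Z <- dm$X %*% basis$Q
  A <- weights * basis$Q          # rows scaled: A = diag(w) %*% Q
  list(basis = basis, Z = Z, A = A, y = y)
}

#' Penalty level at which the constrained lasso is fully sparse
#'
#' From the stationarity condition at `zeta = 0`, any dual vector `t` with
#' `t(A) %*% t = 2 * t(Z) %*% y` certifies that all coefficients are zero for
#' every `lambda >= max(abs(t))`. This returns the certificate from the
#' minimum-L2-norm dual vector, an upper bound on (and in practice close to)
#' the smallest such `lambda`.
#'
#' @inheritParams fit_ridge
#' @return Positive scalar.
#' @export
lasso_lambda_max <- function(dm, cs, y = NULL,
                             weights = penalty_weights(dm)) {
  if (is.null(y)) y <- dm$y
  pp <- penalized_parts(dm, cs, y, weights)
  g <- 2 * crossprod(pp$Z, y)
  AtA <- crossprod(pp$A)
  t0 <- pp$A %*% solve(AtA, g)
  max(abs(t0))
}

#' Log-spaced penalty grid
#'
#' 100 log-spaced values (by default), decreasing from the fully-sparse
#' level [lasso_lambda_max()] down to `lambda_min_ratio` times it.
#'
#' @inheritParams fit_ridge
#' @param nlambda Grid length.
#' @param lambda_min_ratio Ratio of smallest to largest grid value.
#' @return Decreasing positive numeric vector.
#' @export
lambda_grid <- function(dm, cs, y = NULL, weights = penalty_weights(dm),
                        nlambda = 100, lambda_min_ratio = 1e-4) {
  top <- lasso_lambda_max(dm, cs, y, weights)
  exp(seq(log(top), log(top * lambda_min_ratio), length.out = nlambda))
}

#' Adaptive ridge regression on the constrained parametrization
#'
#' Exact closed-form solution of penalized least squares with penalty
#' `lambda * sum_j w_j theta_j^2` subject to the identification constraints:
#' `theta = Q %*% solve(crossprod(Z) + lambda * crossprod(D), crossprod(Z, y))`
#' with `Z = X %*% Q` and `D = diag(sqrt(w)) %*% Q`. At `lambda = 0` this
#' reproduces constrained OLS (when identified).
#'
#' @param dm An [build_design()] result.
#' @param cs An [build_constraints()] result (any scheme; the
#'   overparametrized scheme requires `lambda > 0`).
#' @param lambda Nonnegative penalty level.
#' @param y Outcome; defaults to the design's outcome.
#' @param weights Positive penalty weights per design column.
#' @return An object of class `"abc_penfit"` with `theta`, `zeta`,
#'   `fitted`, `lambda`, `penalty = "ridge"`, `scheme`, and supporting
#'   objects.
#' @export
fit_ridge <- function(dm, cs, lambda, y = NULL,
                      weights = penalty_weights(dm)) {
  stopifnot(lambda >= 0)
  if (is.null(y)) y <- dm$y
  pp <- penalized_parts(dm, cs, y, weights)
  M <- crossprod(pp$Z) + lambda * crossprod(sqrt(weights) * pp$basis$Q)
  ch <- tryCatch(chol(M), error = function(e)
    stop("singular penalized system (scheme '", cs$scheme, "', lambda = ",
         lambda, "): ", conditionMessage(e)))
  zeta <- drop(chol2inv(ch) %*% crossprod(pp$Z, y))
  theta <- drop(pp$basis$Q %*% zeta)
  names(theta) <- colnames(dm$X)
  structure(list(theta = theta, zeta = zeta,
                 fitted = drop(pp$Z %*% zeta),
                 lambda = lambda, penalty = "ridge",
                 weights = weights, scheme = cs$scheme,
                 basis = pp$basis, cs = cs, dm = dm),
            class = "abc_penfit")
}

# Fast ridge over a whole grid: one generalized eigendecomposition, then
# O(k^2) per lambda. Returns zeta matrix (k x nlambda).
ridge_path_zeta <- function(Z, Q, y, weights, lambdas) {
  DtD <- crossprod(sqrt(weights) * Q)
  R <- chol(DtD)
  Rinv <- backsolve(R, diag(ncol(R)))
  M <- t(Rinv) %*% crossprod(Z) %*% Rinv
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  b <- t(eig$vectors) %*% (t(Rinv) %*% crossprod(Z, y))
  sapply(lambdas, function(l)
    drop(Rinv %*% (eig$vectors %*% (b / (eig$values + l)))))
}

#' @export
print.abc_penfit <- function(x, ...) {
  cat("Penalized fit (", x$penalty, ", ", toupper(x$scheme),
      "), lambda = ", formatC(x$lambda, digits = 4, format = "g"),
      "\n", sep = "")
  invisible(x)
}

#' Constrained adaptive lasso solution path
#'
#' Solves, for each grid value `lambda`, the generalized-lasso problem in
#' the reduced coordinates:
#' `min_zeta  sum (y - Z zeta)^2 + lambda * sum_j w_j |(Q zeta)_j|`,
#' mapping back to `theta = Q %*% zeta` so that the identification
#' constraints hold along the whole path. The solver is an ADMM iteration
#' (split `u = A zeta`, `A = diag(w) Q`) with warm starts down the grid; the
#' returned KKT diagnostics certify stationarity and dual feasibility at
#' each solution.
#'
#' @inheritParams fit_ridge
#' @param lambda Decreasing positive grid; defaults to [lambda_grid()].
#' @param tol ADMM primal/dual convergence tolerance (relative).
#' @param max_iter Iteration cap per grid point; exceeding it is an error
#'   carrying the offending `lambda` and the final primal residual.
#' @return An object of class `"abc_path"`: `lambda`, coefficient matrix
#'   `theta` (design columns x grid), `zeta`, per-lambda `diagnostics`
#'   (iterations, primal residual, relative stationarity residual, dual
#'   feasibility slack), and supporting objects.
#' @export
fit_lasso_path <- function(dm, cs, lambda = NULL, y = NULL,
                           weights = penalty_weights(dm),
                           tol = 1e-9, max_iter = 50000L) {
  if (is.null(y)) y <- dm$y
  if (is.null(lambda)) lambda <- lambda_grid(dm, cs, y, weights)
  stopifnot(all(lambda > 0), !is.unsorted(rev(lambda)))
  pp <- penalized_parts(dm, cs, y, weights)
  res <- admm_genlasso_path(pp$Z, pp$A, y, lambda, tol,
                            as.integer(max_iter), 5.0, FALSE)
  if (any(res$iterations >= max_iter)) {
    i <- which(res$iterations >= max_iter)[1]
    stop("lasso solver did not converge at lambda = ", lambda[i],
         " (primal residual ", formatC(res$primal[i], digits = 3,
                                       format = "e"), ")")
  }
  theta <- pp$basis$Q %*% res$zeta
  rownames(theta) <- colnames(dm$X)
  diag_df <- data.frame(lambda = lambda,
                        iterations = res$iterations,
                        primal = res$primal,
                        stationarity = res$stationarity /
                          max(1, max(abs(2 * crossprod(pp$Z, y)))),
                        dual_slack = res$dual_slack)
  structure(list(lambda = lambda, theta = theta, zeta = res$zeta,
                 diagnostics = diag_df, penalty = "lasso",
                 weights = weights, scheme = cs$scheme,
                 basis = pp$basis, cs = cs, dm = dm, y = y),
            class = "abc_path")
}

#' @export
print.abc_path <- function(x, ...) {
  cat("Lasso path (", toupper(x$scheme), "): ", length(x$lambda),
      " lambda values in [", formatC(min(x$lambda), digits = 3, format = "g"),
      ", ", formatC(max(x$lambda), digits = 3, format = "g"), "]\n", sep = "")
  invisible(x)
}

#' Extract one path solution as a penalized fit
#'
#' @param path An [fit_lasso_path()] result.
#' @param lambda Grid value (the nearest grid point is used).
#' @return An `"abc_penfit"` object.
#' @export
path_solution <- function(path, lambda) {
  i <- which.min(abs(path$lambda - lambda))
  theta <- path$theta[, i]
  structure(list(theta = theta, zeta = path$zeta[, i],
                 fitted = drop(path$dm$X %*% theta),
                 lambda = path$lambda[i], penalty = path$penalty,
                 weights = path$weights, scheme = path$scheme,
                 basis = path$basis, cs = path$cs, dm = path$dm),
            class = "abc_penfit")
}

#' Group-specific slopes along a penalty path
#'
#' Long-format table of `alpha_j + gamma_{l,r,j}` for every modifier pair
#' and level at every grid value.
#'
#' @param path An [fit_lasso_path()] result (or any object with `lambda`,
#'   `theta`, `dm`).
#' @return Data frame with columns `lambda`, `categorical`, `level`,
#'   `continuous`, `slope`.
#' @export
path_slopes <- function(path) {
  dm <- path$dm
  mods <- dm$spec$modifiers
  out <- list()
  for (i in seq_len(nrow(mods))) {
    v <- mods$categorical[i]; xv <- mods$continuous[i]
    for (lv in dm$spec$categoricals[[v]]) {
      int_col <- paste0(xv, ":", v, "[", lv, "]")
      out[[length(out) + 1L]] <- data.frame(
        lambda = path$lambda, categorical = v, level = lv,
        continuous = xv,
        slope = path$theta[xv, ] + path$theta[int_col, ],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a penalty path as long-format CSV
#'
#' One row per (lambda, design column) with the coefficient, followed by the
#' slope table from [path_slopes()] in a second file if requested.
#'
#' @param path An [fit_lasso_path()] result.
#' @param file Coefficient CSV path.
#' @param slope_file Optional slope CSV path.
#' @export
write_path_csv <- function(path, file, slope_file = NULL) {
  long <- data.frame(lambda = rep(path$lambda, each = nrow(path$theta)),
                     column = rep(rownames(path$theta), length(path$lambda)),
                     coefficient = as.vector(path$theta))
  utils::write.csv(long, file, row.names = FALSE)
  if (!is.null(slope_file))
    utils::write.csv(path_slopes(path), slope_file, row.names = FALSE)
  invisible(file)
}

# Row subset of a design, recomputing the sample group distribution.
subset_design <- function(dm, idx) {
  labels <- dm$labels[idx, , drop = FALSE]
  dist <- if (length(dm$spec$categoricals)) {
    group_proportions(labels, levels = dm$spec$categoricals)
  } else NULL
  out <- dm
  out$X <- dm$X[idx, , drop = FALSE]
  out$y <- dm$y[idx]
  out$labels <- labels
  out$dist <- dist
  out$n <- length(dm$y[idx])
  out
}

#' K-fold cross-validation for the penalized fits
#'
#' Folds are stratified by the joint categorical label so that every
#' training split retains every level (a fold that would lose a level is an
#' error). For each fold the model is refit on the training rows — with the
#' abundance constraints recomputed from the training-sample proportions —
#' and held-out mean squared error is recorded per grid value. `lambda_min`
#' minimizes the mean CV error; `lambda_1se` is the largest grid value whose
#' mean error is within one standard error (over fold means) of the minimum.
#'
#' @inheritParams fit_lasso_path
#' @param penalty `"lasso"` or `"ridge"`.
#' @param K Number of folds (>= 2).
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `"abc_cv"`: `lambda`, `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se`, `folds`, `penalty`, `scheme`.
#' @export
cross_validate <- function(dm, cs, penalty = c("lasso", "ridge"),
                           lambda = NULL, y = NULL,
                           weights = penalty_weights(dm),
                           K = 10, seed = 1, tol = 1e-4,
                           max_iter = 50000L) {
  penalty <- match.arg(penalty)
  stopifnot(K >= 2)
  if (is.null(y)) y <- dm$y
  if (is.null(lambda)) lambda <- lambda_grid(dm, cs, y, weights)
  n <- dm$n
  folds <- stratified_folds(dm, K, seed)

  errs <- matrix(NA_real_, K, length(lambda))
  for (k in seq_len(K)) {
    train <- which(folds != k)
    test <- which(folds == k)
    miss <- unlist(lapply(names(dm$spec$categoricals), function(v)
      setdiff(dm$spec$categoricals[[v]], unique(dm$labels[[v]][train]))))
    if (length(miss))
      stop("fold ", k, " training split loses level(s): ",
           paste(miss, collapse = ", "))
    sub <- subset_design(dm, train)
    cs_k <- build_constraints(sub, cs$scheme)
    theta_k <- if (penalty == "ridge") {
      pp <- penalized_parts(sub, cs_k, sub$y, weights)
      pp$basis$Q %*% ridge_path_zeta(pp$Z, pp$basis$Q, sub$y, weights,
                                     lambda)
    } else {
      fit_lasso_path(sub, cs_k, lambda = lambda, weights = weights,
                     tol = tol, max_iter = max_iter)$theta
    }
    pred <- dm$X[test, , drop = FALSE] %*% theta_k
    errs[k, ] <- colMeans((y[test] - pred)^2)
  }

  cvm <- colMeans(errs)
  cvsd <- apply(errs, 2, stats::sd) / sqrt(K)
  i_min <- which.min(cvm)
  ok <- cvm <= cvm[i_min] + cvsd[i_min]
  lambda_1se <- max(lambda[ok])
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[i_min], lambda_1se = lambda_1se,
                 folds = folds, penalty = penalty, scheme = cs$scheme,
                 fold_errors = errs),
            class = "abc_cv")
}

# Deterministic stratified fold assignment (round-robin within each joint
# categorical group after a seeded shuffle).
stratified_folds <- function(dm, K, seed) {
  n <- dm$n
  joint <- if (ncol(dm$labels)) {
    do.call(paste, c(dm$labels, sep = "\r"))
  } else rep("all", n)
  folds <- integer(n)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  offset <- 0L
  for (g in sort(unique(joint))) {
    idx <- which(joint == g)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- 1L + (offset + seq_along(idx) - 1L) %% K
    offset <- offset + length(idx)
  }
  folds
}

#' @export
print.abc_cv <- function(x, ...) {
  cat("Cross-validation (", x$penalty, ", ", toupper(x$scheme), "): ",
      "lambda_min = ", formatC(x$lambda_min, digits = 4, format = "g"),
      ", lambda_1se = ", formatC(x$lambda_1se, digits = 4, format = "g"),
      "\n", sep = "")
  invisible(x)
}
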