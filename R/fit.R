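#' Constrained ordinary least squares via null-space reparametrization
#'
#' Minimizes the residual sum of squares subject to `C theta = 0` by writing
#' `theta = Q_null %*% zeta` with `Q_null` an orthonormal basis of the
#' constraint null space ([null_space_basis()]), fitting unconstrained OLS on
#' the adjusted design `Z = X %*% Q_null`, and mapping back. The residual
#' variance uses the identifiable dimension: `sigma2 = SSR / (n - dim(zeta))`,
#' and the coefficient covariance is
#' `sigma2 * Q_null %*% solve(crossprod(Z)) %*% t(Q_null)`, the exact
#' finite-sample Gaussian covariance of the constrained estimator.
#'
#' @param dm An [build_design()] result.
#' @param cs An [build_constraints()] result. The overparametrized scheme is
#'   not identified for OLS and raises an error.
#' @param y Outcome vector; defaults to the outcome stored in the design.
#'
#' @return An object of class `"abc_fit"` with components `theta` (named
#'   coefficients on the full design columns), `sigma2`, `cov_theta`,
#'   `zeta`, `cov_zeta`, `fitted`, `residuals`, `dof`, `n`, `scheme`,
#'   `basis`, `cs`, and the design `dm`.
#' @export
fit_ols <- function(dm, cs, y = NULL) {
  stopifnot(inherits(dm, "abc_design"), inherits(cs, "abc_constraints"))
  if (cs$scheme == "over")
    stop("the overparametrized scheme is not identified for OLS; ",
         "use ridge or lasso estimation")
  if (is.null(y)) y <- dm$y
  basis <- null_space_basis(cs)
  finish_ls_fit(dm, cs, basis, y)
}

# shared tail of fit_ols / fit_ols_kkt given the reduced design
finish_ls_fit <- function(dm, cs, basis, y, theta = NULL) {
  X <- dm$X
  Q <- basis$Q
  Z <- X %*% Q
  n <- nrow(Z)
  k <- ncol(Z)
  if (n <= k)
    stop("n = ", n, " observations cannot identify ", k, " parameters")

  sv <- svd(Z, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-12 * sv[1]) {
    v <- svd(Z)$v[, k]
    dir <- abs(Q %*% v)
    guilty <- colnames(X)[dir > 0.1 * max(dir)]
    stop("collinear design after reparametrization; dependent columns ",
         "involve: ", paste(guilty, collapse = ", "))
  }

  if (is.null(theta)) {
    qz <- qr(Z)
    zeta <- qr.coef(qz, y)
    theta <- drop(Q %*% zeta)
  } else {
    zeta <- drop(crossprod(Q, theta))
  }
  names(theta) <- colnames(X)
  fitted <- drop(Z %*% zeta)
  resid <- y - fitted
  dof <- n - k
  sigma2 <- sum(resid^2) / dof
  ZtZinv <- chol2inv(chol(crossprod(Z)))
  cov_zeta <- sigma2 * ZtZinv
  cov_theta <- Q %*% cov_zeta %*% t(Q)
  dimnames(cov_theta) <- list(colnames(X), colnames(X))

  structure(list(theta = theta, sigma2 = sigma2, cov_theta = cov_theta,
                 zeta = zeta, cov_zeta = cov_zeta,
                 fitted = fitted, residuals = resid,
                 n = n, dof = dof, scheme = cs$scheme,
                 basis = basis, cs = cs, dm = dm),
            class = "abc_fit")
}

#' Constrained OLS by direct solution of the stationarity (KKT) system
#'
#' Independent check on [fit_ols()]: solves the bordered linear system
#' `rbind(cbind(crossprod(X), t(C)), cbind(C, 0)) %*% c(theta, nu) =
#' c(crossprod(X, y), 0)` for the primal coefficients and Lagrange
#' multipliers, avoiding the null-space route entirely. Intended for tests
#' and audits.
#'
#' @inheritParams fit_ols
#' @return An `"abc_fit"` object (inference pieces computed as in
#'   [fit_ols()]).
#' @export
fit_ols_kkt <- function(dm, cs, y = NULL) {
  stopifnot(inherits(dm, "abc_design"), inherits(cs, "abc_constraints"))
  if (cs$scheme == "over")
    stop("the overparametrized scheme is not identified for OLS")
  if (is.null(y)) y <- dm$y
  X <- dm$X
  C <- cs$C
  d <- ncol(X)
  m <- nrow(C)
  K <- rbind(cbind(crossprod(X), t(C)),
             cbind(C, matrix(0, m, m)))
  rhs <- c(crossprod(X, y), rep(0, m))
  sol <- tryCatch(solve(K, rhs),
                  error = function(e)
                    stop("singular bordered KKT system: ",
                         conditionMessage(e)))
  theta <- sol[seq_len(d)]
  basis <- null_space_basis(cs)
  finish_ls_fit(dm, cs, basis, y, theta = theta)
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("Constrained least-squares fit (", toupper(x$scheme), "), n = ", x$n,
      ", identifiable parameters = ", length(x$zeta),
      ", residual SD = ", formatC(sqrt(x$sigma2), digits = 4, format = "g"),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.abc_fit <- function(object, ...) object$theta

#' Coefficient estimates, standard errors, t tests, and confidence intervals
#'
#' Exact t-based inference on the constrained fit, with
#' `dof = n - dim(zeta)`. Every level of every categorical variable appears
#' as its own row; no level is hidden as an implicit reference.
#'
#' @param fit An [fit_ols()] result.
#' @param level Confidence level, default 0.95.
#' @return A data frame (class `"abc_coef_table"`) with the design metadata
#'   columns plus `estimate`, `se`, `t`, `p`, `lower`, `upper`.
#' @export
coefficient_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "abc_fit"))
  if (fit$dof < 1) stop("no residual degrees of freedom for inference")
  stopifnot(level > 0, level < 1)
  est <- fit$theta
  se <- sqrt(pmax(diag(fit$cov_theta), 0))
  tstat <- est / se
  p <- 2 * stats::pt(abs(tstat), df = fit$dof, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$dof)
  out <- cbind(fit$dm$meta,
               data.frame(estimate = unname(est), se = se, t = tstat, p = p,
                          lower = unname(est) - tcrit * se,
                          upper = unname(est) + tcrit * se))
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "scheme") <- fit$scheme
  attr(out, "n") <- fit$n
  attr(out, "dof") <- fit$dof
  attr(out, "pi_source") <- if (!is.null(fit$cs$dist)) fit$cs$dist$source
                            else NA_character_
  class(out) <- c("abc_coef_table", "data.frame")
  out
}

#' @export
summary.abc_fit <- function(object, level = 0.95, ...)
  coefficient_inference(object, level = level)

#' Inference for a linear combination of coefficients
#'
#' Estimates `c' theta` with standard error `sqrt(c' Sigma c)` and t-based
#' inference; the workhorse behind derived quantities such as group-specific
#' slopes.
#'
#' @param fit An [fit_ols()] result, or any list with `theta`, `cov_theta`,
#'   and `dof`.
#' @param weights Either a full-length numeric vector over the design
#'   columns, or a named numeric vector whose names are design column names
#'   (unnamed columns get weight 0).
#' @param level Confidence level.
#' @return One-row data frame with `estimate`, `se`, `t`, `p`, `lower`,
#'   `upper` (`t`/`p` are `NA` when the SE is 0).
#' @export
linear_combination <- function(fit, weights, level = 0.95) {
  theta <- fit$theta
  d <- length(theta)
  if (!is.null(names(weights)) && length(weights) != d) {
    unknown <- setdiff(names(weights), names(theta))
    if (length(unknown))
      stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
    w <- stats::setNames(numeric(d), names(theta))
    w[names(weights)] <- weights
  } else {
    if (length(weights) != d)
      stop("weights have length ", length(weights), ", expected ", d)
    w <- as.numeric(weights)
  }
  est <- sum(w * theta)
  varc <- if (is.null(fit$cov_theta)) 0
          else drop(t(w) %*% fit$cov_theta %*% w)
  se <- sqrt(max(varc, 0))
  dof <- if (is.null(fit$dof)) Inf else fit$dof
  if (se > 0) {
    tstat <- est / se
    p <- 2 * stats::pt(abs(tstat), df = dof, lower.tail = FALSE)
    tcrit <- stats::qt(1 - (1 - level) / 2, df = dof)
    lo <- est - tcrit * se
    hi <- est + tcrit * se
  } else {
    tstat <- NA_real_; p <- NA_real_; lo <- est; hi <- est
  }
  data.frame(estimate = est, se = se, t = tstat, p = p,
             lower = lo, upper = hi)
}

#' Group-specific slopes for a modified continuous covariate
#'
#' For each level `r` of the modifying categorical variable, the slope of the
#' continuous covariate within that group is `alpha_j + gamma_{l,r,j}`
#' (averaged over any other modifying categoricals). Under abundance-based
#' constraints the proportion-weighted average of these rows equals the main
#' effect `alpha_j` exactly.
#'
#' @param fit An [fit_ols()] result (or penalized fit with `theta`).
#' @param continuous Name of the continuous covariate.
#' @param categorical Name of the modifying categorical variable.
#' @param level Confidence level for the per-row intervals.
#' @return Data frame with one row per level: `level`, `estimate`, `se`,
#'   `t`, `p`, `lower`, `upper`; the proportions used for averaging are
#'   attached as attribute `"pi"`.
#' @export
group_specific_slopes <- function(fit, continuous, categorical,
                                  level = 0.95) {
  dm <- fit$dm
  stopifnot(inherits(dm, "abc_design"))
  pair_ok <- any(dm$spec$modifiers$categorical == categorical &
                   dm$spec$modifiers$continuous == continuous)
  if (!pair_ok)
    stop("('", categorical, "', '", continuous, "') is not a modifier pair")
  lvls <- dm$spec$categoricals[[categorical]]
  main_col <- continuous
  out <- do.call(rbind, lapply(lvls, function(lv) {
    int_col <- paste0(continuous, ":", categorical, "[", lv, "]")
    w <- stats::setNames(c(1, 1), c(main_col, int_col))
    cbind(data.frame(level = lv, stringsAsFactors = FALSE),
          linear_combination(fit, w, level = level))
  }))
  rownames(out) <- NULL
  pi_hat <- if (!is.null(fit$cs$dist)) fit$cs$dist$marginal[[categorical]]
            else NULL
  attr(out, "pi") <- pi_hat
  attr(out, "continuous") <- continuous
  attr(out, "categorical") <- categorical
  out
}
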