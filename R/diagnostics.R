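#' Within-group scaled moments and the equal-variance diagnostic
#'
#' The estimation-invariance guarantee of abundance-based constraints holds
#' when the scaled within-group second moments of the continuous covariates
#' are (approximately) equal across groups. For group `r` with `n_r` members
#' this computes `xbar_r(j) = mean of x_j`, the raw cross-products
#' `s_r(j,h) = sum x_ij x_ih`, and the scaled covariance
#' `sigma_r(j,h) = s_r(j,h)/n_r - xbar_r(j) xbar_r(h)` (the divide-by-`n_r`
#' covariance; in the scalar case the scaled sample variance).
#'
#' The heterogeneity summary is the maximum over the non-reference groups
#' (every group beyond the first) and variable
#' pairs `(j,h)` of `|sigma_r(j,h) - sigma_1(j,h)|` relative to the scale
#' `sqrt(sigma_1(j,j) * sigma_1(h,h))`; it is 0 exactly when the condition
#' holds exactly.
#'
#' @param x Continuous covariate values: a numeric matrix/data frame, a
#'   numeric vector, or an [build_design()] result (its continuous columns
#'   are used and `labels` may then be omitted).
#' @param labels Per-row group labels (a vector, or name of a categorical in
#'   the design).
#' @param variables Optional subset of covariate columns.
#' @return An object of class `"group_moments"`: list with `groups`, `n_r`,
#'   `mean` (G x p), `s` and `sigma` (G x p x p arrays), and scalar
#'   `summary`.
#' @export
variance_condition_diagnostic <- function(x, labels = NULL,
                                          variables = NULL) {
  if (inherits(x, "abc_design")) {
    if (is.null(labels)) {
      if (ncol(x$labels) != 1L)
        stop("supply 'labels' (categorical name) when the design has ",
             "several categorical variables")
      labels <- x$labels[[1L]]
    } else if (is.character(labels) && length(labels) == 1L &&
               labels %in% names(x$labels)) {
      labels <- x$labels[[labels]]
    }
    vars <- if (is.null(variables)) x$spec$continuous else variables
    x <- x$X[, vars, drop = FALSE]
  } else {
    if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1,
                                     dimnames = list(NULL, "x"))
    x <- as.matrix(x)
    if (!is.null(variables)) x <- x[, variables, drop = FALSE]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  p <- ncol(x)
  vn <- colnames(x)

  n_r <- stats::setNames(integer(length(groups)), groups)
  mean_r <- matrix(NA_real_, length(groups), p, dimnames = list(groups, vn))
  s_r <- array(NA_real_, c(length(groups), p, p),
               dimnames = list(groups, vn, vn))
  sigma_r <- s_r
  for (g in groups) {
    idx <- labels == g
    n_g <- sum(idx)
    if (n_g == 0L) stop("empty group '", g, "'")
    xg <- x[idx, , drop = FALSE]
    n_r[g] <- n_g
    mean_r[g, ] <- colMeans(xg)
    s_r[g, , ] <- crossprod(xg)
    sigma_r[g, , ] <- s_r[g, , ] / n_g - tcrossprod(mean_r[g, ])
  }

  ref <- sigma_r[1, , , drop = TRUE]
  ref <- matrix(ref, p, p)
  scale <- sqrt(abs(outer(diag(ref), diag(ref))))
  scale[scale == 0] <- 1
  devs <- vapply(seq_along(groups)[-1], function(i) {
    max(abs(matrix(sigma_r[i, , ], p, p) - ref) / scale)
  }, 1.0)
  summary <- if (length(devs)) max(devs) else 0

  structure(list(groups = groups, n_r = n_r, mean = mean_r,
                 s = s_r, sigma = sigma_r, summary = summary),
            class = "group_moments")
}

#' @export
print.group_moments <- function(x, ...) {
  cat("Within-group scaled moments over", length(x$groups), "groups;",
      "heterogeneity summary =", formatC(x$summary, digits = 4), "\n")
  invisible(x)
}
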