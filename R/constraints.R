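#' Build the identification constraint matrix for a scheme
#'
#' Each categorical variable contributes one constraint on its intercept
#' (dummy) block and one per continuous covariate it modifies, so the matrix
#' has `m = sum_l (1 + p*_l)` rows (`m = L(1+p)` when every categorical
#' modifies every continuous covariate). The schemes differ only in the row
#' weights over the levels of the relevant block:
#'
#' * `abc` — abundance-based constraints: weights are the group proportions,
#'   so the weighted level coefficients sum to zero and main effects are
#'   group-averaged effects;
#' * `rge` — reference group encoding: weight 1 on the first level only
#'   (its coefficients are pinned to zero);
#' * `stz` — sum-to-zero: weight 1 on every level;
#' * `over` — overparametrized: no constraints (`m = 0`); only penalized
#'   estimation applies.
#'
#' @param dm An [build_design()] result.
#' @param scheme One of `"abc"`, `"rge"`, `"stz"`, `"over"`.
#' @param dist Optional [group_proportions()] object supplying the
#'   proportions for ABC rows (e.g., known population proportions); defaults
#'   to the sample proportions stored in the design.
#'
#' @return An object of class `"abc_constraints"`: list with matrix `C`
#'   (`m` rows, one column per design column), `scheme`, a per-row
#'   description data frame `rows`, and `dist`.
#' @export
build_constraints <- function(dm, scheme = c("abc", "rge", "stz", "over"),
                              dist = NULL) {
  stopifnot(inherits(dm, "abc_design"))
  scheme <- match.arg(scheme)
  meta <- dm$meta
  d <- nrow(meta)
  if (is.null(dist)) dist <- dm$dist

  rows <- data.frame(categorical = character(), target = character(),
                     stringsAsFactors = FALSE)
  C <- matrix(0, nrow = 0, ncol = d, dimnames = list(NULL, meta$column))
  if (scheme == "over" || length(dm$spec$categoricals) == 0L) {
    return(structure(list(C = C, scheme = scheme, rows = rows, dist = dist),
                     class = "abc_constraints"))
  }

  cats <- names(dm$spec$categoricals)
  for (v in cats) {
    lv <- dm$spec$categoricals[[v]]
    w <- switch(scheme,
      abc = {
        p <- dist$marginal[[v]]
        if (is.null(p))
          stop("proportions for '", v, "' not available")
        miss <- setdiff(lv, names(p))
        if (length(miss))
          stop("proportions for '", v, "' missing level(s): ",
               paste(miss, collapse = ", "))
        p <- p[lv]
        if (any(p <= 0)) stop("zero proportion for a level of '", v,
                              "' under abundance-based constraints")
        as.numeric(p)
      },
      rge = c(1, rep(0, length(lv) - 1L)),
      stz = rep(1, length(lv)))

    targets <- c("(Intercept)",
                 dm$spec$modifiers$continuous[dm$spec$modifiers$categorical == v])
    for (tg in targets) {
      row <- numeric(d)
      if (tg == "(Intercept)") {
        idx <- which(meta$role == "dummy" & meta$variable == v)
      } else {
        idx <- which(meta$role == "interaction" & meta$variable == v &
                       meta$continuous == tg)
      }
      stopifnot(length(idx) == length(lv))
      row[idx] <- w[match(meta$level[idx], lv)]
      C <- rbind(C, row)
      rows <- rbind(rows, data.frame(categorical = v, target = tg,
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(C) <- NULL
  structure(list(C = C, scheme = scheme, rows = rows, dist = dist),
            class = "abc_constraints")
}

#' @export
print.abc_constraints <- function(x, ...) {
  cat("Constraint set: scheme ", toupper(x$scheme), ", m = ", nrow(x$C),
      " rows over ", ncol(x$C), " design columns\n", sep = "")
  invisible(x)
}

#' Export a constraint matrix to CSV for audit
#'
#' One row per constraint with its categorical variable, its target
#' (intercept block or modified continuous covariate), and the weight on
#' every design column.
#'
#' @param cs An [build_constraints()] result.
#' @param file Output path.
#' @export
write_constraints_csv <- function(cs, file) {
  stopifnot(inherits(cs, "abc_constraints"))
  out <- cbind(cs$rows, as.data.frame(cs$C))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Orthonormal basis of the constraint null space
#'
#' From the QR decomposition of `t(C)`, the trailing columns of the complete
#' orthogonal factor span `{theta : C theta = 0}`; writing `theta = Q_ null
#' %*% zeta` turns constrained least squares into an unconstrained problem in
#' `zeta`. For the overparametrized scheme (no constraints) the basis is the
#' identity. Rank of `C` is checked via singular values at a relative
#' tolerance of `1e-10 * sigma_max`; a deficient rank signals duplicated
#' constraints and is an error.
#'
#' @param cs An [build_constraints()] result.
#' @return An object of class `"abc_basis"`: list with the orthonormal matrix
#'   `Q` (`d x (d - m)`), `m`, and `d`.
#' @export
null_space_basis <- function(cs) {
  stopifnot(inherits(cs, "abc_constraints"))
  C <- cs$C
  d <- ncol(C)
  m <- nrow(C)
  if (m == 0L) {
    Q <- diag(d)
    rownames(Q) <- colnames(C)
    return(structure(list(Q = Q, m = 0L, d = d), class = "abc_basis"))
  }
  sv <- svd(C, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-10 * sv[1])
    stop("constraint matrix is rank-deficient (duplicated constraints?): ",
         "rank ", sum(sv >= 1e-10 * sv[1]), " < m = ", m)
  qrC <- qr(t(C))
  Qfull <- qr.Q(qrC, complete = TRUE)
  Q <- Qfull[, (m + 1L):d, drop = FALSE]
  rownames(Q) <- colnames(C)
  structure(list(Q = Q, m = m, d = d), class = "abc_basis")
}

#' Maximum absolute constraint violation of a coefficient vector
#'
#' Audit of the identification: `max |C theta|`, zero for any vector in the
#' constraint null space (and defined as 0 when there are no constraints).
#'
#' @param cs An [build_constraints()] result.
#' @param theta Coefficient vector on the full design columns.
#' @return Nonnegative scalar.
#' @export
constraint_residual <- function(cs, theta) {
  stopifnot(inherits(cs, "abc_constraints"))
  if (nrow(cs$C) == 0L) return(0)
  if (length(theta) != ncol(cs$C))
    stop("theta has length ", length(theta), ", expected ", ncol(cs$C))
  max(abs(cs$C %*% as.numeric(theta)))
}
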