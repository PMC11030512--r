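#' Estimator-comparison experiment: RMSE across identification schemes
#'
#' For each replicate of the Gaussian main-only design, fits the (deliberately
#' overparametrized) modified model — all covariates, the categorical
#' variable, and all interactions — under each identification scheme and
#' estimator, and records three root-mean-squared errors against the truth:
#' over the regression coefficients (intercept, slopes, level effects,
#' modifier effects), over the group-specific slopes `alpha_j + gamma_{r,j}`,
#' and over the regression function `mu(x, r)` at the observed design points.
#' Ridge and lasso penalties are tuned per fit by K-fold cross-validation
#' with the one-standard-error rule; the overparametrized scheme is skipped
#' for OLS (not identified).
#'
#' @param cfg A [sim_config_main()] configuration.
#' @param schemes Subset of `c("abc", "rge", "stz", "over")`.
#' @param estimators Subset of `c("ols", "ridge", "lasso")`.
#' @param reps Number of replicates (defaults to `cfg$reps`).
#' @param K Cross-validation folds.
#' @param nlambda,lambda_min_ratio Penalty grid controls.
#' @return A list of class `"rmse_experiment"`: `results` (long data frame
#'   with `replicate`, `scheme`, `estimator`, `metric`, `value`, `error`),
#'   `summary` (median per cell), and `cfg`.
#' @export
rmse_experiment <- function(cfg, schemes = c("abc", "rge", "over"),
                            estimators = c("ols", "ridge", "lasso"),
                            reps = cfg$reps, K = 10,
                            nlambda = 100, lambda_min_ratio = 1e-4) {
  stopifnot(inherits(cfg, "sim_config_main"))
  schemes <- match.arg(schemes, c("abc", "rge", "stz", "over"),
                       several.ok = TRUE)
  estimators <- match.arg(estimators, c("ols", "ridge", "lasso"),
                          several.ok = TRUE)
  spec <- abc_spec("y", paste0("x", seq_len(cfg$p)),
                   stats::setNames(list(cfg$groups), "group"),
                   modifiers = "all", standardize = FALSE)
  rows <- list()
  for (i in seq_len(reps)) {
    sim <- simulate_main_only(cfg, i)
    dm <- build_design(spec, sim$data)
    truth <- truth_theta(dm, sim$truth)
    for (sc in schemes) {
      cs <- build_constraints(dm, sc)
      w <- penalty_weights(dm)
      grid <- NULL
      for (est in estimators) {
        if (sc == "over" && est == "ols") next
        cell <- tryCatch({
          theta <- switch(est,
            ols = fit_ols(dm, cs)$theta,
            ridge = {
              if (is.null(grid))
                grid <- lambda_grid(dm, cs, weights = w,
                                    nlambda = nlambda,
                                    lambda_min_ratio = lambda_min_ratio)
              cv <- cross_validate(dm, cs, "ridge", lambda = grid,
                                   weights = w, K = K,
                                   seed = replicate_seed(cfg$seed, i) + 1)
              fit_ridge(dm, cs, cv$lambda_1se, weights = w)$theta
            },
            lasso = {
              if (is.null(grid))
                grid <- lambda_grid(dm, cs, weights = w,
                                    nlambda = nlambda,
                                    lambda_min_ratio = lambda_min_ratio)
              path <- fit_lasso_path(dm, cs, lambda = grid, weights = w)
              cv <- cross_validate(dm, cs, "lasso", lambda = grid,
                                   weights = w, K = K,
                                   seed = replicate_seed(cfg$seed, i) + 2)
              path_solution(path, cv$lambda_1se)$theta
            })
          rmse_metrics(dm, theta, truth, sim$truth$mu, cfg)
        }, error = function(e) {
          list(metrics = c(coefficients = NA_real_, slopes = NA_real_,
                           fitted = NA_real_),
               error = conditionMessage(e))
        })
        err <- if (is.null(cell$error)) NA_character_ else cell$error
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = i, scheme = sc, estimator = est,
          metric = names(cell$metrics), value = unname(cell$metrics),
          error = err, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- stats::aggregate(value ~ scheme + estimator + metric, results,
                              stats::median, na.action = stats::na.omit)
  names(summary)[names(summary) == "value"] <- "median_rmse"
  structure(list(results = results, summary = summary, cfg = cfg,
                 schemes = schemes, estimators = estimators, reps = reps),
            class = "rmse_experiment")
}

# Truth coefficient vector aligned to the design columns (main-only truth:
# interactions are zero).
truth_theta <- function(dm, truth) {
  meta <- dm$meta
  theta <- stats::setNames(numeric(nrow(meta)), meta$column)
  theta["(Intercept)"] <- truth$alpha0
  theta[dm$spec$continuous] <- truth$alpha
  dum <- meta$role == "dummy"
  theta[dum] <- truth$beta[meta$level[dum]]
  theta
}

rmse_metrics <- function(dm, theta, truth, mu_true, cfg) {
  meta <- dm$meta
  rmse_coef <- sqrt(mean((theta - truth)^2))
  slope_err <- vapply(seq_len(nrow(meta))[meta$role == "interaction"],
                      function(i) {
    xv <- meta$continuous[i]
    (theta[xv] + theta[i]) - truth[xv]
  }, 1.0)
  rmse_slope <- sqrt(mean(slope_err^2))
  rmse_mu <- sqrt(mean((drop(dm$X %*% theta) - mu_true)^2))
  list(metrics = c(coefficients = rmse_coef, slopes = rmse_slope,
                   fitted = rmse_mu),
       error = NULL)
}

#' @export
print.rmse_experiment <- function(x, ...) {
  cat("RMSE experiment:", x$reps, "replicates, n =", x$cfg$n, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Estimation-invariance experiment
#'
#' For each replicate of the invariance design, fits the main-only model
#' (`y ~ x + group`) and the modified model (`y ~ x + group + x:group`)
#' under each identification scheme on identical data and records the two
#' slope estimates `alpha1M` (main-only) and `alpha1` (modified). Under
#' abundance-based constraints the pair lies near the 45-degree line; under
#' reference-group or sum-to-zero identification the modified-model slope is
#' a different functional and the pairs separate as the modifier strength
#' grows.
#'
#' @param cfg A [sim_config_invariance()] configuration.
#' @param schemes Subset of `c("abc", "rge", "stz")`.
#' @param reps Number of replicates (defaults to `cfg$reps`).
#' @return A list of class `"invariance_experiment"`: `results`
#'   (`replicate`, `scheme`, `alpha1M`, `alpha1`), `summary` (per scheme:
#'   median and maximum absolute discrepancy, and the slope of the
#'   through-origin regression of `alpha1` on `alpha1M` across replicates —
#'   equal to 1 exactly when the replicate pairs lie on the 45-degree line
#'   `alpha1 = alpha1M`), and `cfg`.
#' @export
invariance_experiment <- function(cfg, schemes = c("abc", "rge", "stz"),
                                  reps = cfg$reps) {
  stopifnot(inherits(cfg, "sim_config_invariance"))
  schemes <- match.arg(schemes, c("abc", "rge", "stz"), several.ok = TRUE)
  spec_main <- abc_spec("y", "x",
                        stats::setNames(list(cfg$groups), "group"),
                        modifiers = "none", standardize = FALSE)
  spec_mod <- abc_spec("y", "x",
                       stats::setNames(list(cfg$groups), "group"),
                       modifiers = "all", standardize = FALSE)
  rows <- list()
  for (i in seq_len(reps)) {
    sim <- simulate_invariance(cfg, i)
    dm_main <- build_design(spec_main, sim$data)
    dm_mod <- build_design(spec_mod, sim$data)
    for (sc in schemes) {
      a_main <- fit_ols(dm_main, build_constraints(dm_main, sc))$theta["x"]
      a_mod <- fit_ols(dm_mod, build_constraints(dm_mod, sc))$theta["x"]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i, scheme = sc,
        alpha1M = unname(a_main), alpha1 = unname(a_mod),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- do.call(rbind, lapply(split(results, results$scheme),
                                   function(d) {
    # through-origin fit: measures agreement with the line alpha1 = alpha1M
    b <- stats::coef(stats::lm(alpha1 ~ 0 + alpha1M, data = d))[1]
    data.frame(scheme = d$scheme[1],
               median_abs_discrepancy = stats::median(abs(d$alpha1 -
                                                            d$alpha1M)),
               max_abs_discrepancy = max(abs(d$alpha1 - d$alpha1M)),
               regression_slope = unname(b),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, cfg = cfg,
                 reps = reps),
            class = "invariance_experiment")
}

#' @export
print.invariance_experiment <- function(x, ...) {
  cat("Invariance experiment:", x$reps, "replicates, n =", x$cfg$n,
      ", gamma =", x$cfg$gamma, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
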