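#' Configuration for the Gaussian main-only simulation design
#'
#' The reference estimator-comparison design: `p = 10` continuous covariates
#' and one four-level categorical variable. Covariates 1,2,3,6,7,8 are
#' independent standard normal; covariates 4,5,9,10 depend on the group,
#' `X_j | R = r ~ N(r, 1)` (mean equal to the group index). The truth is
#' main-only: intercept 1, slopes `alpha = (1,1,1,1,1,0,0,0,0,0)`, group
#' effects `beta = (0, 1, 0, -1)`, and no interactions, so the generating
#' model satisfies both reference-group (`beta_1 = 0`) and abundance-based
#' (`sum(prop * beta) = 0`) identification — a fair comparison across
#' schemes. Gaussian noise is calibrated to a signal-to-noise ratio of one
#' via [noise_scale_for_snr()]. Datasets are redrawn until every group has
#' at least `p + 1` observations (needed for OLS with all interactions).
#'
#' @param n Sample size (the reference study uses 250 and 10,000).
#' @param prop Group proportions; symmetric `c(0.15, 0.35, 0.15, 0.35)` by
#'   default, or uniform `rep(0.25, 4)`.
#' @param alpha0,alpha,beta True intercept, slopes, and group effects.
#' @param snr Signal-to-noise ratio `Var(mu) / sigma^2`.
#' @param dep Indices of the group-dependent covariates.
#' @param reps Default replicate count for experiments.
#' @param seed Base seed; each replicate derives its own stream from
#'   `(seed, replicate)`.
#' @param min_per_group Minimum group count enforced by redrawing
#'   (default `p + 1`).
#' @param max_attempts Redraw cap before erroring.
#' @return A list of class `"sim_config_main"`.
#' @export
sim_config_main <- function(n = 250, prop = c(0.15, 0.35, 0.15, 0.35),
                            alpha0 = 1,
                            alpha = c(rep(1, 5), rep(0, 5)),
                            beta = c(0, 1, 0, -1),
                            snr = 1, dep = c(4, 5, 9, 10),
                            reps = 500, seed = 1,
                            min_per_group = length(alpha) + 1,
                            max_attempts = 1000) {
  p <- length(alpha)
  G <- length(prop)
  stopifnot(length(beta) == G, abs(sum(prop) - 1) < 1e-12, all(prop > 0),
            all(dep >= 1), all(dep <= p), snr > 0, n > 0)
  if (abs(beta[1]) > 1e-12 || abs(sum(prop * beta)) > 1e-12)
    stop("true group effects must satisfy both reference-group (beta[1] = 0)",
         " and abundance (sum(prop*beta) = 0) identification for a fair",
         " scheme comparison")
  structure(list(n = n, p = p, prop = prop, alpha0 = alpha0, alpha = alpha,
                 beta = beta, snr = snr, dep = dep, reps = reps, seed = seed,
                 min_per_group = min_per_group, max_attempts = max_attempts,
                 groups = paste0("G", seq_len(G))),
            class = "sim_config_main")
}

#' Noise standard deviation that attains a target signal-to-noise ratio
#'
#' The signal variance is computed analytically from the generating laws.
#' Writing `a = sum of alpha_j over group-dependent covariates j` (each with
#' conditional mean equal to the group index `r`), the regression function
#' variance decomposes as
#' `Var(mu) = sum_j alpha_j^2 + Var_R(a * R + beta_R)`,
#' since every covariate has unit conditional variance. The returned scale
#' is `sigma = sqrt(Var(mu) / snr)`.
#'
#' @param cfg A [sim_config_main()] configuration.
#' @param snr Target ratio; defaults to `cfg$snr`.
#' @return Positive scalar `sigma`, with the analytic `Var(mu)` attached as
#'   attribute `"var_mu"`.
#' @export
noise_scale_for_snr <- function(cfg, snr = cfg$snr) {
  stopifnot(inherits(cfg, "sim_config_main"), snr > 0)
  a <- sum(cfg$alpha[cfg$dep])
  r <- seq_along(cfg$prop)
  v <- a * r + cfg$beta
  ev <- sum(cfg$prop * v)
  var_group <- sum(cfg$prop * (v - ev)^2)
  var_mu <- sum(cfg$alpha^2) + var_group
  if (var_mu <= 0) stop("zero signal variance")
  structure(sqrt(var_mu / snr), var_mu = var_mu)
}

# deterministic per-replicate stream (kept below 2^31)
replicate_seed <- function(seed, replicate) {
  (as.double(seed) * 1009 + as.double(replicate) * 7919) %% 2147483629
}

#' Draw one dataset from the Gaussian main-only design
#'
#' A pure function of `(cfg, replicate)`: identical calls return identical
#' data. The whole dataset is redrawn until every group reaches
#' `cfg$min_per_group` observations.
#'
#' @param cfg A [sim_config_main()] configuration.
#' @param replicate Replicate index (>= 1).
#' @return List with `data` (data frame: `y`, `x1..xp`, `group`) and
#'   `truth` (`alpha0`, `alpha`, `beta` named by group, `sigma`, `mu`).
#' @export
simulate_main_only <- function(cfg, replicate = 1) {
  stopifnot(inherits(cfg, "sim_config_main"))
  sigma <- as.numeric(noise_scale_for_snr(cfg))
  set.seed(replicate_seed(cfg$seed, replicate))
  G <- length(cfg$prop)
  for (attempt in seq_len(cfg$max_attempts)) {
    r <- sample.int(G, cfg$n, replace = TRUE, prob = cfg$prop)
    if (min(tabulate(r, G)) >= cfg$min_per_group) break
    if (attempt == cfg$max_attempts)
      stop("could not reach ", cfg$min_per_group,
           " observations per group in ", cfg$max_attempts, " attempts")
  }
  X <- matrix(stats::rnorm(cfg$n * cfg$p), cfg$n, cfg$p)
  for (j in cfg$dep) X[, j] <- X[, j] + r
  colnames(X) <- paste0("x", seq_len(cfg$p))
  mu <- cfg$alpha0 + drop(X %*% cfg$alpha) + cfg$beta[r]
  y <- mu + sigma * stats::rnorm(cfg$n)
  data <- data.frame(y = y, X, group = cfg$groups[r],
                     stringsAsFactors = FALSE)
  list(data = data,
       truth = list(alpha0 = cfg$alpha0, alpha = cfg$alpha,
                    beta = stats::setNames(cfg$beta, cfg$groups),
                    sigma = sigma, mu = mu),
       replicate = replicate)
}

#' Configuration for the four-group invariance design
#'
#' One continuous covariate whose distribution differs by group in both
#' location and shape, with unit population variance in each group:
#' `5 + N(0,1)` (group A), `sqrt(12) * Uniform(0,1)` (B), `5 + t_4` scaled
#' to scale 1 as printed (C; note a standard t_4 has population variance 2,
#' a discrepancy in the stated laws that is reproduced, not corrected), and
#' `Gamma(1,1)` (D). The response is
#' `y = 1 + x + gamma * x * 1(A) - gamma * x * 1(B) + t_4 error`.
#'
#' @param n Sample size (100 or 500 in the reference study).
#' @param prop Group proportions over `A, B, C, D`.
#' @param gamma Modifier strength: 0, 0.5, or 1.5 in the reference study.
#' @param reps Default replicate count.
#' @param seed Base seed.
#' @param min_per_group Minimum group count enforced by redrawing.
#' @return A list of class `"sim_config_invariance"`.
#' @export
sim_config_invariance <- function(n = 100,
                                  prop = c(A = 0.55, B = 0.20,
                                           C = 0.10, D = 0.15),
                                  gamma = 0, reps = 500, seed = 1,
                                  min_per_group = 3, max_attempts = 1000) {
  stopifnot(abs(sum(prop) - 1) < 1e-12, all(prop > 0), gamma >= 0, n > 0)
  if (is.null(names(prop))) names(prop) <- c("A", "B", "C", "D")
  structure(list(n = n, prop = prop, gamma = gamma, reps = reps,
                 seed = seed, min_per_group = min_per_group,
                 max_attempts = max_attempts, groups = names(prop)),
            class = "sim_config_invariance")
}

#' Draw one dataset from the invariance design
#'
#' @param cfg A [sim_config_invariance()] configuration.
#' @param replicate Replicate index.
#' @return List with `data` (`y`, `x`, `group`) and `truth`.
#' @export
simulate_invariance <- function(cfg, replicate = 1) {
  stopifnot(inherits(cfg, "sim_config_invariance"))
  set.seed(replicate_seed(cfg$seed, replicate))
  G <- length(cfg$prop)
  for (attempt in seq_len(cfg$max_attempts)) {
    r <- sample.int(G, cfg$n, replace = TRUE, prob = cfg$prop)
    if (min(tabulate(r, G)) >= cfg$min_per_group) break
    if (attempt == cfg$max_attempts)
      stop("could not reach ", cfg$min_per_group,
           " observations per group in ", cfg$max_attempts, " attempts")
  }
  grp <- cfg$groups[r]
  x <- numeric(cfg$n)
  x[grp == "A"] <- 5 + stats::rnorm(sum(grp == "A"))
  x[grp == "B"] <- sqrt(12) * stats::runif(sum(grp == "B"))
  x[grp == "C"] <- 5 + stats::rt(sum(grp == "C"), df = 4)
  x[grp == "D"] <- stats::rgamma(sum(grp == "D"), shape = 1, rate = 1)
  mu <- 1 + x + cfg$gamma * x * (grp == "A") - cfg$gamma * x * (grp == "B")
  y <- mu + stats::rt(cfg$n, df = 4)
  list(data = data.frame(y = y, x = x, group = grp,
                         stringsAsFactors = FALSE),
       truth = list(alpha0 = 1, alpha1 = 1, gamma = cfg$gamma, mu = mu),
       replicate = replicate)
}
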