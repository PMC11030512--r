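#' Expand a model spec against data into the unconstrained design matrix
#'
#' Builds the overparametrized design: an intercept column, the continuous
#' covariates (in spec order), a full set of indicator ("dummy") columns for
#' every level of every categorical variable, and an interaction column for
#' every (categorical level, modified continuous covariate) pair. No level is
#' dropped: identification is deferred to the constraint scheme.
#'
#' Column order contract: intercept; continuous covariates in spec order;
#' per-categorical dummies in level order; interaction columns ordered by
#' (categorical, level, continuous). The column count is
#' `1 + p + sum(G_l) + sum over modifier categoricals of G_l * p*_l`
#' where `G_l` is the number of levels and `p*_l` the number of continuous
#' covariates the l-th categorical modifies.
#'
#' @param spec An [abc_spec()].
#' @param data A data frame containing every column the spec names.
#' @param drop_empty_levels Drop declared levels with zero observed count
#'   (with a warning) instead of raising an error.
#'
#' @return An object of class `"abc_design"`: list with the expanded matrix
#'   `X` (n rows), per-column metadata `meta` (`column`, `role` in
#'   intercept/continuous/dummy/interaction, `variable`, `level`,
#'   `continuous`), row-aligned `labels`, the sample [group_proportions()]
#'   `dist`, the outcome vector `y`, standardization info, and the resolved
#'   spec.
#' @examples
#' d <- data.frame(y = rnorm(8), x = rnorm(8),
#'                 g = rep(c("A", "B"), each = 4))
#' dm <- build_design(abc_spec("y", "x", "g", modifiers = "all"), d)
#' dm$meta
#' @export
build_design <- function(spec, data, drop_empty_levels = FALSE) {
  stopifnot(inherits(spec, "abc_spec"), is.data.frame(data))
  needed <- c(spec$outcome, spec$continuous, names(spec$categoricals))
  if (anyDuplicated(names(data)))
    stop("duplicate column names in data: ",
         paste(unique(names(data)[duplicated(names(data))]), collapse = ", "))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "))

  for (v in c(spec$outcome, spec$continuous)) {
    if (!is.numeric(data[[v]]))
      stop("column '", v, "' must be numeric")
    if (anyNA(data[[v]]))
      stop("missing values in column '", v, "' (",
           sum(is.na(data[[v]])), " rows); remove or impute before fitting")
  }
  for (v in names(spec$categoricals)) {
    if (anyNA(data[[v]]))
      stop("missing values in column '", v, "'")
  }

  n <- nrow(data)
  if (n == 0L) stop("no rows")
  y <- as.numeric(data[[spec$outcome]])

  labels <- data.frame(lapply(data[names(spec$categoricals)], as.character),
                       stringsAsFactors = FALSE)
  if (length(spec$categoricals) == 0L)
    labels <- data.frame(row.names = seq_len(n))

  dist <- if (length(spec$categoricals)) {
    group_proportions(labels, levels = spec$categoricals,
                      drop_empty = drop_empty_levels)
  } else NULL
  lvls <- if (is.null(dist)) list() else dist$levels

  centers <- stats::setNames(numeric(length(spec$continuous)),
                             spec$continuous)
  scales <- stats::setNames(rep(1, length(spec$continuous)), spec$continuous)
  xcont <- lapply(spec$continuous, function(v) as.numeric(data[[v]]))
  names(xcont) <- spec$continuous
  if (spec$standardize) {
    for (v in spec$continuous) {
      s <- stats::sd(xcont[[v]])
      if (!is.finite(s) || s == 0)
        stop("zero-variance continuous column '", v,
             "' cannot be standardized")
      centers[v] <- mean(xcont[[v]])
      scales[v] <- s
      xcont[[v]] <- (xcont[[v]] - centers[v]) / s
    }
  }

  cols <- list(`(Intercept)` = rep(1, n))
  meta <- data.frame(column = "(Intercept)", role = "intercept",
                     variable = NA_character_, level = NA_character_,
                     continuous = NA_character_, stringsAsFactors = FALSE)

  for (v in spec$continuous) {
    cols[[v]] <- xcont[[v]]
    meta <- rbind(meta, data.frame(column = v, role = "continuous",
                                   variable = v, level = NA_character_,
                                   continuous = v, stringsAsFactors = FALSE))
  }

  for (v in names(lvls)) {
    for (lv in lvls[[v]]) {
      nm <- paste0(v, "[", lv, "]")
      cols[[nm]] <- as.numeric(labels[[v]] == lv)
      meta <- rbind(meta, data.frame(column = nm, role = "dummy",
                                     variable = v, level = lv,
                                     continuous = NA_character_,
                                     stringsAsFactors = FALSE))
    }
  }

  if (nrow(spec$modifiers)) {
    for (v in names(lvls)) {
      mods <- spec$modifiers$continuous[spec$modifiers$categorical == v]
      if (!length(mods)) next
      for (lv in lvls[[v]]) {
        ind <- as.numeric(labels[[v]] == lv)
        for (xv in mods) {
          nm <- paste0(xv, ":", v, "[", lv, "]")
          cols[[nm]] <- xcont[[xv]] * ind
          meta <- rbind(meta,
                        data.frame(column = nm, role = "interaction",
                                   variable = v, level = lv,
                                   continuous = xv, stringsAsFactors = FALSE))
        }
      }
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(meta) <- NULL

  spec$categoricals <- lvls  # resolved level ordering

  structure(list(X = X, meta = meta, y = y, labels = labels, dist = dist,
                 spec = spec, n = n,
                 centers = centers, scales = scales),
            class = "abc_design")
}

#' @export
print.abc_design <- function(x, ...) {
  cat("Design matrix: ", x$n, " rows x ", ncol(x$X), " columns (",
      sum(x$meta$role == "continuous"), " continuous, ",
      sum(x$meta$role == "dummy"), " dummy, ",
      sum(x$meta$role == "interaction"), " interaction)\n", sep = "")
  invisible(x)
}

#' Number of design columns implied by a spec
#'
#' Evaluates the column-count formula without touching data; used for audits
#' and in tests against the built matrix.
#'
#' @param spec An [abc_spec()] whose categorical level lists are resolved.
#' @return Integer column count.
#' @export
design_column_count <- function(spec) {
  G <- vapply(spec$categoricals, length, 1L)
  p_star <- vapply(names(spec$categoricals), function(v)
    sum(spec$modifiers$categorical == v), 1L)
  as.integer(1L + length(spec$continuous) + sum(G) + sum(G * p_star))
}

#' Export a design matrix to CSV with metadata header lines
#'
#' Writes `# column,role,variable,level,continuous` comment lines followed by
#' the matrix itself, for external audit.
#'
#' @param dm An [build_design()] result.
#' @param file Output path.
#' @export
write_design_csv <- function(dm, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", dm$meta$column, ",", dm$meta$role, ",",
                    ifelse(is.na(dm$meta$variable), "", dm$meta$variable), ",",
                    ifelse(is.na(dm$meta$level), "", dm$meta$level), ",",
                    ifelse(is.na(dm$meta$continuous), "",
                           dm$meta$continuous)), con)
  utils::write.csv(as.data.frame(dm$X), con, row.names = FALSE)
  invisible(file)
}
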