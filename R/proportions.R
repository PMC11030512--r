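#' Group abundance distributions
#'
#' Computes the per-variable level proportions (and, with more than one
#' categorical variable, the joint table) that define abundance-based
#' constraints. Sample mode uses empirical frequencies `count / n`;
#' population mode accepts externally known proportions.
#'
#' @param labels A data frame of categorical label columns (one column per
#'   categorical variable), or a vector for a single variable.
#' @param levels Optional named list mapping variable name to its ordered
#'   level vector; defaults to the lexicographic order of observed labels.
#' @param mode `"sample"` (empirical frequencies) or `"population"`.
#' @param population For population mode: a named list mapping each variable
#'   to a named numeric vector of proportions over its levels.
#' @param drop_empty If `TRUE`, levels with zero observed count are dropped
#'   with a warning instead of raising an error (sample mode only).
#'
#' @return An object of class `"group_distribution"` with components
#'   `marginal` (named list of named proportion vectors), `joint` (an array
#'   over the cross of levels when there is more than one variable, else
#'   `NULL`), `source`, and `n`.
#' @examples
#' group_proportions(data.frame(g = c("A", "A", "B", "B")))
#' @export
group_proportions <- function(labels, levels = NULL,
                              mode = c("sample", "population"),
                              population = NULL, drop_empty = FALSE) {
  mode <- match.arg(mode)
  if (!is.data.frame(labels)) {
    labels <- data.frame(group = as.character(labels),
                         stringsAsFactors = FALSE)
  }
  labels[] <- lapply(labels, as.character)
  vars <- names(labels)
  n <- nrow(labels)
  if (n == 0L) stop("no observations")

  lvls <- lapply(vars, function(v) {
    declared <- if (!is.null(levels)) levels[[v]] else NULL
    obs <- unique(labels[[v]])
    if (is.null(declared)) return(sort(obs))
    unseen <- setdiff(obs, declared)
    if (length(unseen))
      stop("unseen label(s) for '", v, "': ", paste(unseen, collapse = ", "))
    as.character(declared)
  })
  names(lvls) <- vars

  if (mode == "population") {
    if (is.null(population)) stop("population mode requires 'population'")
    marginal <- lapply(vars, function(v) {
      p <- population[[v]]
      if (is.null(p)) stop("population table missing variable '", v, "'")
      miss <- setdiff(lvls[[v]], names(p))
      if (length(miss))
        stop("population table for '", v, "' missing level(s): ",
             paste(miss, collapse = ", "))
      p <- p[lvls[[v]]]
      validate_proportions(p, v)
      p
    })
    names(marginal) <- vars
    joint <- NULL
  } else {
    marginal <- vector("list", length(vars))
    names(marginal) <- vars
    for (v in vars) {
      cnt <- table(factor(labels[[v]], levels = lvls[[v]]))
      if (any(cnt == 0L)) {
        zero <- names(cnt)[cnt == 0L]
        if (!drop_empty)
          stop("level(s) with zero count for '", v, "': ",
               paste(zero, collapse = ", "),
               " (not OLS-identifiable; use drop_empty = TRUE to drop)")
        warning("dropping ", length(zero), " empty level(s) of '", v, "': ",
                paste(zero, collapse = ", "))
        lvls[[v]] <- setdiff(lvls[[v]], zero)
        cnt <- cnt[lvls[[v]]]
      }
      p <- as.numeric(cnt) / n
      names(p) <- lvls[[v]]
      validate_proportions(p, v)
      marginal[[v]] <- p
    }
    joint <- NULL
    if (length(vars) > 1L) {
      joint <- table(lapply(vars, function(v)
        factor(labels[[v]], levels = lvls[[v]])))
      dimnames(joint) <- lvls
      joint <- joint / n
    }
  }

  structure(list(marginal = marginal, joint = joint,
                 source = mode, n = n, levels = lvls),
            class = "group_distribution")
}

validate_proportions <- function(p, var) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("invalid proportions for '", var, "'")
  if (abs(sum(p) - 1) > 1e-12)
    stop("proportions for '", var, "' sum to ", format(sum(p)), ", not 1")
  if (any(p == 0))
    stop("zero-abundance level in '", var, "'")
  invisible(p)
}

#' @export
print.group_distribution <- function(x, ...) {
  cat("Group distribution (", x$source, ", n = ", x$n, ")\n", sep = "")
  for (v in names(x$marginal)) {
    cat("  ", v, ": ", sep = "")
    p <- x$marginal[[v]]
    cat(paste0(names(p), "=", formatC(p, digits = 4, format = "g"),
               collapse = ", "), "\n")
  }
  invisible(x)
}
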