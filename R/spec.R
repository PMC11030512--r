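#' Declare a regression model with categorical effect modifiers
#'
#' An `abc_spec` names the outcome, the continuous covariates, the categorical
#' covariates (with an optional explicit level ordering), and the set of
#' (categorical, continuous) modifier pairs whose interactions enter the model.
#' The spec is purely declarative; [build_design()] expands it against data.
#'
#' @param outcome Name of the outcome column.
#' @param continuous Character vector of continuous covariate columns, in the
#'   order they should appear in the design matrix. May be empty.
#' @param categoricals Either a character vector of categorical column names
#'   (levels inferred from the data, in lexicographic order) or a named list
#'   mapping column name to an ordered character vector of levels (or `NULL`
#'   to infer).
#' @param modifiers Which interactions to include: `"all"` for every
#'   (categorical, continuous) pair, `"none"` (or `NULL`) for a main-only
#'   model, or a two-column data frame / list of length-2 character vectors
#'   giving `(categorical, continuous)` pairs.
#' @param standardize Logical; center and scale each continuous covariate by
#'   its sample standard deviation before interactions are formed.
#' @param intercept_only Allow a spec with no covariates at all.
#'
#' @return An object of class `"abc_spec"`.
#' @examples
#' abc_spec("y", continuous = c("x1", "x2"),
#'          categoricals = list(race = c("NHW", "NHB", "Hisp")),
#'          modifiers = "all")
#' @export
abc_spec <- function(outcome, continuous = character(), categoricals = list(),
                     modifiers = "none", standardize = FALSE,
                     intercept_only = FALSE) {
  stopifnot(is.character(outcome), length(outcome) == 1L, nzchar(outcome))
  continuous <- as.character(continuous)
  if (anyDuplicated(continuous))
    stop("duplicate continuous covariate names: ",
         paste(unique(continuous[duplicated(continuous)]), collapse = ", "))

  if (is.character(categoricals)) {
    categoricals <- stats::setNames(vector("list", length(categoricals)),
                                    categoricals)
  }
  if (length(categoricals) && is.null(names(categoricals)))
    stop("'categoricals' must be named by column")
  if (anyDuplicated(names(categoricals)))
    stop("duplicate categorical covariate names")
  for (nm in names(categoricals)) {
    lv <- categoricals[[nm]]
    if (!is.null(lv)) {
      lv <- as.character(lv)
      if (length(lv) == 0L) stop("empty level list for '", nm, "'")
      if (anyDuplicated(lv)) stop("duplicate levels for '", nm, "'")
      categoricals[[nm]] <- lv
    }
  }

  all_names <- c(outcome, continuous, names(categoricals))
  if (anyDuplicated(all_names))
    stop("a column may appear in only one role: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))

  pairs <- normalize_modifier_pairs(modifiers, names(categoricals), continuous)

  if (length(continuous) == 0L && length(categoricals) == 0L &&
      !isTRUE(intercept_only))
    stop("no covariates declared; set intercept_only = TRUE for an ",
         "intercept-only model")

  structure(
    list(outcome = outcome,
         continuous = continuous,
         categoricals = categoricals,
         modifiers = pairs,
         standardize = isTRUE(standardize)),
    class = "abc_spec")
}

# Canonical modifier representation: data.frame(categorical, continuous),
# ordered by (categorical in spec order, continuous in spec order).
normalize_modifier_pairs <- function(modifiers, cat_names, cont_names) {
  empty <- data.frame(categorical = character(), continuous = character(),
                      stringsAsFactors = FALSE)
  if (is.null(modifiers)) return(empty)
  if (is.character(modifiers) && length(modifiers) == 1L) {
    if (modifiers == "none") return(empty)
    if (modifiers == "all") {
      if (length(cat_names) == 0L || length(cont_names) == 0L) return(empty)
      return(data.frame(
        categorical = rep(cat_names, each = length(cont_names)),
        continuous = rep(cont_names, times = length(cat_names)),
        stringsAsFactors = FALSE))
    }
    stop("unknown modifiers shorthand '", modifiers, "'")
  }
  if (is.list(modifiers) && !is.data.frame(modifiers)) {
    modifiers <- do.call(rbind, lapply(modifiers, function(p) {
      if (length(p) != 2L) stop("each modifier pair must be length 2")
      data.frame(categorical = p[[1]], continuous = p[[2]],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(modifiers)) return(empty)
  }
  stopifnot(is.data.frame(modifiers), ncol(modifiers) >= 2L)
  names(modifiers)[1:2] <- c("categorical", "continuous")
  modifiers$categorical <- as.character(modifiers$categorical)
  modifiers$continuous <- as.character(modifiers$continuous)
  bad_cat <- setdiff(modifiers$categorical, cat_names)
  if (length(bad_cat))
    stop("modifier references undeclared categorical: ",
         paste(bad_cat, collapse = ", "))
  bad_cont <- setdiff(modifiers$continuous, cont_names)
  if (length(bad_cont))
    stop("modifier references undeclared continuous covariate: ",
         paste(bad_cont, collapse = ", "))
  if (anyDuplicated(modifiers[c("categorical", "continuous")]))
    stop("duplicate modifier pairs")
  # canonical order
  modifiers <- modifiers[order(match(modifiers$categorical, cat_names),
                               match(modifiers$continuous, cont_names)), ,
                         drop = FALSE]
  rownames(modifiers) <- NULL
  modifiers[c("categorical", "continuous")]
}

#' @export
print.abc_spec <- function(x, ...) {
  cat("Model spec: ", x$outcome, " ~ ", sep = "")
  terms <- c("1", x$continuous, names(x$categoricals),
             if (nrow(x$modifiers))
               paste0(x$modifiers$continuous, ":", x$modifiers$categorical))
  cat(paste(terms, collapse = " + "), "\n")
  if (x$standardize)
    cat("  continuous covariates centered and scaled\n")
  invisible(x)
}

#' Read a model spec from a JSON configuration file
#'
#' The JSON object holds `outcome`, `continuous` (array), `categoricals`
#' (array of names, or object mapping name to level array), `modifiers`
#' ("all", "none", or array of `[categorical, continuous]` pairs) and
#' `standardize` (boolean, default true for data analysis).
#'
#' @param path Path to a JSON file.
#' @return An [abc_spec()] object.
#' @export
read_spec_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$outcome)) stop("config is missing 'outcome'")
  cats <- cfg$categoricals
  if (is.null(cats)) cats <- list()
  mods <- cfg$modifiers
  if (is.null(mods)) mods <- "none"
  if (!is.character(mods) || length(mods) != 1L) {
    if (is.matrix(mods)) mods <- as.data.frame(mods, stringsAsFactors = FALSE)
    if (is.list(mods) && !is.data.frame(mods))
      mods <- lapply(mods, unlist)
  }
  abc_spec(outcome = cfg$outcome,
           continuous = if (is.null(cfg$continuous)) character()
                        else cfg$continuous,
           categoricals = cats,
           modifiers = mods,
           standardize = if (is.null(cfg$standardize)) TRUE
                         else isTRUE(cfg$standardize))
}
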