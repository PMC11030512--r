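#' Full-level regression output table
#'
#' Renders a coefficient table in the equitable "all levels" layout: the
#' intercept, each continuous main effect, then each categorical variable
#' with every one of its levels, then each modifier block with every level —
#' no level is hidden as an implicit reference. Estimates are rounded to 3
#' decimals with the standard error in parentheses; p-values below 0.001
#' print as `<0.001`. Under reference-group encoding the constrained-to-zero
#' reference rows are rendered explicitly as `0 (reference)`. A footnote
#' records the scheme, sample size, and the provenance of the group
#' proportions.
#'
#' @param tab An [coefficient_inference()] result (class
#'   `"abc_coef_table"`).
#' @param digits Display digits for estimates and SEs.
#' @return An object of class `"abc_output_table"`: `display` (data frame of
#'   formatted strings with grouping headers), `full` (the unrounded input
#'   table), and `footnote`.
#' @export
format_coefficient_table <- function(tab, digits = 3) {
  stopifnot(inherits(tab, "abc_coef_table"))
  scheme <- attr(tab, "scheme")
  fmt_num <- function(x) formatC(round(x, digits), format = "f",
                                 digits = digits)
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001",
                              formatC(round(p, 3), format = "f", digits = 3))
  is_ref <- function(rows) {
    # first level of each categorical under RGE is pinned to zero
    if (scheme != "rge") return(rep(FALSE, nrow(rows)))
    vapply(seq_len(nrow(rows)), function(i) {
      v <- rows$variable[i]
      !is.na(rows$level[i]) &&
        rows$level[i] == ref_levels[[v]]
    }, TRUE)
  }

  cats <- unique(tab$variable[tab$role == "dummy"])
  ref_levels <- lapply(stats::setNames(cats, cats), function(v)
    tab$level[tab$role == "dummy" & tab$variable == v][1])

  lines <- list()
  add <- function(variable, rows) {
    if (!is.na(variable))
      lines[[length(lines) + 1L]] <<- data.frame(
        Variable = variable, `Estimate (SE)` = "", `p-value` = "",
        check.names = FALSE, stringsAsFactors = FALSE)
    ref <- is_ref(rows)
    for (i in seq_len(nrow(rows))) {
      nm <- if (!is.na(rows$level[i])) {
        pre <- if (!is.na(rows$continuous[i]) &&
                   rows$role[i] == "interaction")
          paste0(rows$continuous[i], ":") else "  "
        paste0(pre, rows$level[i])
      } else rows$column[i]
      est <- if (ref[i]) "0 (reference)"
             else paste0(fmt_num(rows$estimate[i]), " (",
                         fmt_num(rows$se[i]), ")")
      pv <- if (ref[i]) "" else fmt_p(rows$p[i])
      lines[[length(lines) + 1L]] <<- data.frame(
        Variable = nm, `Estimate (SE)` = est, `p-value` = pv,
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }

  add(NA, tab[tab$role == "intercept", ])
  for (v in tab$column[tab$role == "continuous"])
    add(NA, tab[tab$role == "continuous" & tab$column == v, ])
  for (v in cats)
    add(v, tab[tab$role == "dummy" & tab$variable == v, ])
  mods <- unique(tab[tab$role == "interaction", c("continuous", "variable")])
  for (i in seq_len(nrow(mods)))
    add(paste0(mods$continuous[i], " × ", mods$variable[i]),
        tab[tab$role == "interaction" &
              tab$variable == mods$variable[i] &
              tab$continuous == mods$continuous[i], ])

  display <- do.call(rbind, lines)
  rownames(display) <- NULL
  footnote <- paste0("Scheme: ", toupper(scheme), "; n = ", attr(tab, "n"),
                     "; group proportions: ",
                     switch(attr(tab, "pi_source"),
                            sample = "sample",
                            population = "known population",
                            "none"),
                     "; CI level ", attr(tab, "level"), ".")
  structure(list(display = display, full = tab, footnote = footnote),
            class = "abc_output_table")
}

#' @export
print.abc_output_table <- function(x, ...) {
  w1 <- max(nchar(x$display$Variable))
  w2 <- max(nchar(x$display[["Estimate (SE)"]]), nchar("Estimate (SE)"))
  cat(formatC("Variable", width = -w1), "  ",
      formatC("Estimate (SE)", width = -w2), "  p-value\n", sep = "")
  for (i in seq_len(nrow(x$display)))
    cat(formatC(x$display$Variable[i], width = -w1), "  ",
        formatC(x$display[["Estimate (SE)"]][i], width = -w2), "  ",
        x$display[["p-value"]][i], "\n", sep = "")
  cat(x$footnote, "\n")
  invisible(x)
}

#' Write an output table (formatted and full precision)
#'
#' @param x An [format_coefficient_table()] result.
#' @param file Path for the formatted table; format from `format`.
#' @param full_file Optional path for the full-precision CSV of the
#'   underlying coefficient table (always the exact fitted numbers).
#' @param format `"text"`, `"csv"`, or `"markdown"` for the formatted table.
#' @export
write_output_table <- function(x, file, full_file = NULL,
                               format = c("text", "csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "abc_output_table"))
  if (format == "csv") {
    utils::write.csv(x$display, file, row.names = FALSE)
  } else if (format == "markdown") {
    md <- c("| Variable | Estimate (SE) | p-value |",
            "|---|---|---|",
            sprintf("| %s | %s | %s |", x$display$Variable,
                    x$display[["Estimate (SE)"]], x$display[["p-value"]]),
            "", x$footnote)
    writeLines(md, file)
  } else {
    out <- utils::capture.output(print(x))
    writeLines(out, file)
  }
  if (!is.null(full_file))
    utils::write.csv(as.data.frame(x$full), full_file, row.names = FALSE)
  invisible(file)
}
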