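#' Format a percentage the way the reports print it
#'
#' Percentages in summary reports are printed to two significant figures,
#' so small fractions keep one decimal (1.4\%) while larger ones are whole
#' numbers (14\%, 33\%).
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param percent If `FALSE`, return the numeric value instead of a string.
#' @return A character vector like `"1.4%"`, or a numeric vector when
#'   `percent = FALSE`.
#' @examples
#' format_percent(17, 1201)    # "1.4%"
#' format_percent(1112, 3353)  # "33%"
#' @export
format_percent <- function(numerator, denominator, percent = TRUE) {
  stopifnot(all(denominator > 0))
  value <- signif(100 * numerator / denominator, 2)
  if (!percent) {
    return(value)
  }
  paste0(format(value, trim = TRUE, scientific = FALSE, drop0trailing = TRUE), "%")
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix for user input problems
#' @noRd
input_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
assert_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    input_error("%s is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
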