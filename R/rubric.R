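# The LE8 scoring rubric is shipped as a plain-text, versioned table
# (inst/extdata/le8_rubric_v1.csv) so the point bands are auditable and can
# be swapped without touching code. Bands are half-open: lower <= x < upper.

.rubric_cache <- new.env(parent = emptyenv())

#' Load the LE8 scoring rubric
#'
#' Reads the versioned band table used by all component scorers. Each row is
#' either a numeric band (`lower <= x < upper -> points`), a categorical level
#' (e.g. smoking status), or a named constant (treatment deductions, diet
#' quartile points).
#'
#' @param path Optional path to an alternative rubric file with the same
#'   columns (`table, level, lower, upper, points`); defaults to the rubric
#'   shipped with the package.
#' @return A data frame with columns `table`, `level`, `lower`, `upper`,
#'   `points`.
#' @export
le8_rubric <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rubric_cache$default)) {
      return(.rubric_cache$default)
    }
    path <- system.file("extdata", "le8_rubric_v1.csv", package = "le8af",
                        mustWork = TRUE)
  }
  rub <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("table", "level", "lower", "upper", "points")
  if (!all(need %in% names(rub))) {
    fail("rubric file must have columns: ", paste(need, collapse = ", "))
  }
  rub$lower <- as.numeric(rub$lower)
  rub$upper <- as.numeric(rub$upper)
  if (path == system.file("extdata", "le8_rubric_v1.csv", package = "le8af")) {
    .rubric_cache$default <- rub
  }
  rub
}

# Vectorised half-open band lookup for one rubric table.
rubric_band <- function(x, table, rubric = le8_rubric()) {
  rows <- rubric[rubric$table == table & !is.na(rubric$lower), , drop = FALSE]
  if (nrow(rows) == 0) fail("no rubric bands for table '", table, "'")
  out <- rep(NA_real_, length(x))
  for (i in seq_len(nrow(rows))) {
    hit <- x >= rows$lower[i] & x < rows$upper[i]
    out[hit] <- rows$points[i]
  }
  out
}

# Named constant from the rubric (categorical level or deduction).
rubric_constant <- function(table, level, rubric = le8_rubric()) {
  row <- rubric[rubric$table == table & !is.na(rubric$level) &
                  rubric$level == level, , drop = FALSE]
  if (nrow(row) != 1) fail("rubric constant '", table, "/", level, "' not found")
  row$points
}
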