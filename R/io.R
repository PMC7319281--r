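#' Read a delimited curve matrix
#'
#' Reads a numeric matrix of curves (rows = subjects, columns = grid
#' points) from a CSV/TSV/whitespace-delimited file.  The first row may
#' optionally carry the observation grid; with \code{grid_row = "auto"}
#' the first row is treated as the grid when all its values lie in
#' [0, 1] and are strictly increasing.
#'
#' @param path File path.
#' @param sep Field separator; \code{"auto"} tries comma, tab, then
#'   whitespace.
#' @param grid_row \code{"auto"}, \code{"yes"} or \code{"no"}.
#' @return A \code{\link{curve_set}}.  Without a grid row an equispaced
#'   grid on [0, 1] is attached.
#' @export
read_curve_matrix <- function(path, sep = "auto", grid_row = "auto") {
  grid_row <- match.arg(grid_row, c("auto", "yes", "no"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  if (identical(sep, "auto")) {
    first <- lines[[1L]]
    sep <- if (grepl(",", first, fixed = TRUE)) ","
           else if (grepl("\t", first, fixed = TRUE)) "\t"
           else "[[:space:]]+"
  }
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), sep)[[1L]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("non-numeric cell on line %d of %s", i, path))
    vals
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged file: line %d of %s has %d fields, expected %d",
                 bad, path, widths[bad], widths[1L]))
  }
  mat <- do.call(rbind, rows)
  has_grid <- switch(grid_row,
    yes = TRUE,
    no = FALSE,
    auto = nrow(mat) > 1L && all(mat[1L, ] >= 0 & mat[1L, ] <= 1) &&
           all(diff(mat[1L, ]) > 0))
  if (has_grid) {
    curve_set(mat[-1L, , drop = FALSE], mat[1L, ])
  } else {
    g <- ncol(mat)
    curve_set(mat, seq(0, 1, length.out = g))
  }
}

#' Write a curve matrix with its grid as the header row
#'
#' @param curves A \code{curve_set}.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @export
write_curve_matrix <- function(curves, path, sep = ",") {
  stopifnot(inherits(curves, "curve_set"))
  mat <- rbind(curves$grid, curves$values)
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a test report to JSON or CSV
#'
#' Serializes a test result (see \code{\link{flute_test}} /
#' \code{\link{scalar_test}}) together with the analysis decisions that
#' were applied, so a report is self-describing.
#'
#' @param result A \code{flute_result}.
#' @param path Output path; extension selects the format unless
#'   \code{format} is given.
#' @param format \code{"json"} or \code{"csv"}.
#' @export
write_report <- function(result, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(result, "flute_result"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  flat <- unclass(result)
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    scal <- flat[vapply(flat, function(v) is.atomic(v) && length(v) == 1L,
                        logical(1L))]
    utils::write.csv(data.frame(field = names(scal),
                                value = vapply(scal, as.character, "")),
                     path, row.names = FALSE)
  }
  invisible(path)
}
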