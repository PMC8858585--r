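#' Bundled daily PM2.5 series from Bangkok monitoring stations
#'
#' Two series of 31 daily PM2.5 concentrations (micrograms per cubic
#' metre) recorded in January 2021 by the Pollution Control Department of
#' Thailand: \code{"din_daeng"}, a high-traffic inner-city district, and
#' \code{"bang_khun_thian"}, a district with mixed construction and
#' industrial sources.  Both series are strongly right-skewed and are
#' well described by an inverse Gaussian distribution (see
#' [compare_families()]).
#'
#' @param station \code{"din_daeng"} or \code{"bang_khun_thian"}.
#' @return numeric vector of 31 daily concentrations.
#' @examples
#' ig_fit(pm25_data("din_daeng"))
#' @export
pm25_data <- function(station = c("din_daeng", "bang_khun_thian")) {
  station <- match.arg(station)
  path <- system.file("extdata", paste0(station, ".csv"),
                      package = "igcv", mustWork = TRUE)
  read_sample(path)
}

#' Read a univariate positive sample from a single-column CSV
#'
#' Reads one column of positive reals from a plain-text CSV (decimal
#' point \code{"."}, no thousands separators).  A header row is
#' auto-detected: if the first cell does not parse as a number it is
#' treated as a column name.  Parse and domain problems are reported with
#' the offending data row number.
#'
#' @param path path to the file.
#' @param column column index to read (default 1).
#' @return numeric vector of positive values.
#' @export
read_sample <- function(path, column = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty file: %s", path), call. = FALSE)
  cells <- vapply(strsplit(lines, ","),
                  function(f) trimws(f[min(column, length(f))]), character(1))
  has_header <- is.na(suppressWarnings(as.numeric(cells[1])))
  if (has_header) cells <- cells[-1]
  if (!length(cells)) stop(sprintf("no data rows in %s", path), call. = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    row <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value %s at data row %d of %s",
                 dQuote(cells[row]), row, path), call. = FALSE)
  }
  if (any(vals <= 0)) {
    row <- which(vals <= 0)[1]
    stop(sprintf("non-positive value %g at data row %d of %s",
                 vals[row], row, path), call. = FALSE)
  }
  vals
}

#' Write result tables to TSV or JSON
#'
#' Serializes a result data frame (interval tables from [ig_cv_ci()],
#' coverage tables from [cv_coverage()], model tables from
#' [compare_families()]) as tab-separated text with 6-decimal fixed-point
#' numbers and a trailing newline, or as JSON at full precision.  Field
#' order is the column order of the input, so output is deterministic.
#'
#' @param results a non-empty data frame.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("'results' must be a non-empty data frame", call. = FALSE)
  df <- as.data.frame(results)
  if (format == "tsv") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(col) sprintf("%.6f", col))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con)
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
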