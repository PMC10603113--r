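# Plain-text I/O: time-series CSV and flat key-value parameter files.
#
# The CSV dialect is fixed (comma separator, UTF-8, '.' decimal, one header
# row, '#' comment lines) rather than sniffed, for reproducibility. Values
# round-trip at 17 significant digits, i.e. losslessly for doubles.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1L))
  out
}

#' Write a time series to CSV
#'
#' Writes `time_h` plus all channel columns, preceded by `#` comment lines
#' recording the package version plus any caller-supplied metadata (e.g.
#' seed, input digests). Values are written with 17 significant digits so a
#' read/write round trip is lossless.
#'
#' @param ts Data frame with a `time_h` column.
#' @param path Output file path.
#' @param comments Optional character vector of extra comment lines
#'   (written without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, comments = NULL) {
  stopifnot(is.data.frame(ts), "time_h" %in% names(ts))
  header <- c(sprintf("# redoxlan %s", as.character(packageVersion("redoxlan"))),
              if (length(comments)) paste0("# ", comments))
  cols <- vapply(ts, fmt_num, character(nrow(ts)))
  if (nrow(ts) == 1L) cols <- matrix(cols, nrow = 1L)
  body <- apply(cols, 1L, paste, collapse = ",")
  writeLines(c(header, paste(names(ts), collapse = ","), body), path)
  invisible(path)
}

#' Read a time series from CSV
#'
#' Parses a channel table written by [write_timeseries()] (or any CSV with
#' a `time_h` column). Comment lines starting with `#` are skipped.
#' Entirely empty channel columns are treated as absent (dropped, recorded
#' in the `absent_channels` attribute) rather than zero-filled. Times must
#' be strictly increasing and all present cells numeric; violations are
#' reported with the offending data row number.
#'
#' @param path Input file path.
#' @return A data frame with `time_h` and the present channels.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!"time_h" %in% names(df)) stop("missing required column 'time_h' in ", path)
  absent <- names(df)[vapply(df, function(col) all(trimws(col) == "" | is.na(col)),
                             logical(1L))]
  df <- df[setdiff(names(df), absent)]
  for (nm in names(df)) {
    raw <- trimws(df[[nm]])
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals) & raw != "")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   raw[bad[1L]], nm, bad[1L]))
    df[[nm]] <- vals
  }
  if (anyNA(df$time_h)) stop("missing values in 'time_h'")
  nd <- which(diff(df$time_h) <= 0)
  if (length(nd))
    stop(sprintf("times are not strictly increasing at data row %d", nd[1L] + 1L))
  attr(df, "absent_channels") <- absent
  df
}

#' Write a flat key-value parameter file
#'
#' One `key = value` line per entry, with `#` comment lines for metadata.
#' Co-culture parameter sets use the per-species symbol names
#' (`E_S ... N_R`, `fe_total`, initial conditions) so a reader can
#' cross-check the file against the model equations directly.
#'
#' @param values Named numeric vector or [lan_parameters()] object.
#' @param path Output file path.
#' @param comments Optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_params <- function(values, path, comments = NULL) {
  if (inherits(values, "lan_parameters")) values <- lan_to_symbols(values)
  stopifnot(is.numeric(values), !is.null(names(values)), all(nzchar(names(values))))
  lines <- c(sprintf("# redoxlan %s", as.character(packageVersion("redoxlan"))),
             if (length(comments)) paste0("# ", comments),
             sprintf("%s = %s", names(values), fmt_num(values)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value parameter file
#'
#' @param path Input file path.
#' @return Named numeric vector.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: '%s'", bad[1L], path, lines[bad[1L]]))
  keys <- trimws(vapply(parts, `[[`, character(1L), 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, character(1L), 2L))))
  if (anyNA(vals))
    stop(sprintf("non-numeric value for key '%s' in %s", keys[which(is.na(vals))[1L]], path))
  setNames(vals, keys)
}

#' Read a co-culture parameter file
#'
#' Reads a flat key-value file of model symbols (as written by
#' [write_params()] on a [lan_parameters()] object) and rebuilds the
#' parameter object.
#'
#' @param path Input file path.
#' @return A [lan_parameters()] object.
#' @export
read_lan_parameters <- function(path) {
  lan_from_symbols(read_params(path))
}
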