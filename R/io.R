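#' Read observation records from CSV
#'
#' Expects a header row with a `behavior` column, an optional `out_of_sight`
#' column (`0/1/true/false`; absent means all in sight), and any grouping
#' columns such as `subject` and `session`. RFC-4180 quoting, UTF-8.
#'
#' @param path CSV file path.
#' @return A tibble of records suitable for [tally_behaviors()].
#' @export
read_records <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  recs <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!"behavior" %in% names(recs)) {
    abort(paste0("Records file ", path, " has no `behavior` column."))
  }
  recs
}

#' Read a behavior count table from CSV
#'
#' Accepts either the two-column form `behavior,count` (one analysis unit per
#' file) or the long form `unit,behavior,count` (many units). Counts must be
#' non-negative integers; violations are reported with their line number.
#'
#' @param path CSV file path.
#' @return A tibble with columns (`unit`,) `behavior`, `count`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  counts <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  need <- c("behavior", "count")
  if (!all(need %in% names(counts))) {
    abort(paste0("Counts file ", path,
                 " must have `behavior` and `count` columns (optional `unit`)."))
  }
  n <- suppressWarnings(as.numeric(counts$count))
  bad <- which(is.na(n) | n < 0 | n != round(n))
  if (length(bad) > 0) {
    abort(paste0("Malformed count(s) in ", path, " at data line(s): ",
                 paste(utils::head(bad, 10), collapse = ", "),
                 " (must be non-negative integers)."))
  }
  counts$count <- as.integer(n)
  counts[, intersect(c("unit", "behavior", "count"), names(counts))]
}

#' Read an expected-repertoire file
#'
#' One behavior label per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of labels.
#' @export
read_repertoire <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  labels <- lines[nzchar(lines)]
  if (length(labels) == 0) {
    abort(paste0("Expected-repertoire file ", path, " contains no labels."))
  }
  unique(labels)
}

#' Write index results to CSV
#'
#' Serialises a tidy results table to the interchange format
#' `unit,index,value,S,N,F1,F2,note`. Undefined values become an empty field
#' with the explanatory note alongside. Values are printed at a fixed
#' precision (default 6 decimal places) for spreadsheet-stable output.
#'
#' @param results A results tibble, e.g. `tidy(behavioral_diversity(...))`.
#' @param path Output CSV path.
#' @param precision Decimal places for `value` (default 6).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, precision = 6) {
  out <- as_tibble(results)
  unit_cols <- setdiff(names(out),
                       c("index", "value", "S", "N", "F1", "F2", "note"))
  if (length(unit_cols) == 0) {
    out$unit <- "all"
  } else {
    out$unit <- do.call(paste, c(out[unit_cols], sep = "/"))
  }
  out$value <- ifelse(is.na(out$value), "",
                      formatC(out$value, digits = precision, format = "f"))
  out <- out[, c("unit", "index", "value", "S", "N", "F1", "F2", "note")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}
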