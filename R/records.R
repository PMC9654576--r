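#' Define an ethogram
#'
#' An ethogram is the catalogue of discrete behavior categories used to code
#' observations of a species. It optionally carries the *expected* (wild-type)
#' repertoire used by the Behavioral Variety Index, i.e. the full set of
#' behavior categories the species is known to express in its natural state.
#'
#' @param categories Character vector of behavior-category labels. Labels are
#'   opaque, case-sensitive strings; they must be unique and non-empty.
#' @param expected Optional character vector: the expected (wild-type)
#'   repertoire. Must be non-empty when supplied. Defaults to `NULL`.
#' @return An object of class `"ethogram"`: a list with elements `categories`
#'   and `expected`.
#' @examples
#' eth <- ethogram(c("rest", "feed", "groom"), expected = c("rest", "feed",
#'   "groom", "play", "forage"))
#' eth
#' @export
ethogram <- function(categories, expected = NULL) {
  categories <- as.character(categories)
  if (length(categories) == 0) {
    abort("An ethogram needs at least one behavior category.")
  }
  if (anyNA(categories) || any(!nzchar(categories))) {
    abort("Behavior-category labels must be non-empty strings.")
  }
  if (anyDuplicated(categories)) {
    abort(paste0(
      "Duplicate behavior-category labels: ",
      paste(unique(categories[duplicated(categories)]), collapse = ", ")
    ))
  }
  if (!is.null(expected)) {
    expected <- as.character(expected)
    if (length(expected) == 0 || anyNA(expected) || any(!nzchar(expected))) {
      abort("`expected`, when supplied, must be a non-empty vector of non-empty labels.")
    }
    if (anyDuplicated(expected)) {
      abort("Duplicate labels in the expected repertoire.")
    }
  }
  structure(list(categories = categories, expected = expected),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat("<ethogram> ", length(x$categories), " categories: ",
      paste(x$categories, collapse = ", "), "\n", sep = "")
  if (!is.null(x$expected)) {
    cat("  expected repertoire (", length(x$expected), "): ",
        paste(x$expected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tally observation records into behavior counts
#'
#' Aggregates long-format observation records (one row per scan or sample)
#' into per-behavior counts, the form every diversity index consumes. Records
#' flagged out of sight are excluded from the counts by default -- visibility
#' is a sampling-effort confound, not a behavior -- but their number is
#' retained per group in the `"out_of_sight"` attribute so that effort can be
#' audited.
#'
#' Every record must either carry a behavior label or be flagged out of
#' sight, never both and never neither; violating rows are reported by row
#' number.
#'
#' @param records A data frame with a `behavior` column (character; may be
#'   `NA` or `""` on out-of-sight rows), an optional logical/0-1
#'   `out_of_sight` column (missing column means all in sight), and any
#'   grouping columns (typically `subject` and/or `session`).
#' @param group_by Character vector of column names to aggregate within
#'   (e.g. `"subject"`, `c("subject", "session")`). `NULL` pools all records
#'   into a single count vector.
#' @param out_of_sight Policy for out-of-sight records: `"exclude"` (default)
#'   drops them from the counts; `"pseudo_category"` tallies them as a
#'   behavior category named `".out_of_sight"`, for sensitivity analysis.
#' @return A tibble with the grouping columns plus `behavior` and `count`,
#'   one row per observed behavior per group, sorted by group then behavior.
#'   The `"out_of_sight"` attribute holds a tibble of per-group out-of-sight
#'   tallies.
#' @examples
#' recs <- tibble::tibble(
#'   subject  = c("a", "a", "a", "b", "b"),
#'   behavior = c("rest", "rest", "feed", "rest", NA),
#'   out_of_sight = c(0, 0, 0, 0, 1)
#' )
#' tally_behaviors(recs, group_by = "subject")
#' @export
tally_behaviors <- function(records,
                            group_by = NULL,
                            out_of_sight = c("exclude", "pseudo_category")) {
  out_of_sight <- match.arg(out_of_sight)
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    abort("`records` is empty: nothing to tally.")
  }
  if (!"behavior" %in% names(records)) {
    abort("`records` must have a `behavior` column.")
  }
  if (!is.null(group_by)) {
    missing_cols <- setdiff(group_by, names(records))
    if (length(missing_cols) > 0) {
      abort(paste0("Grouping column(s) not in `records`: ",
                   paste(missing_cols, collapse = ", ")))
    }
  }

  beh <- as.character(records$behavior)
  beh[!is.na(beh) & !nzchar(beh)] <- NA_character_
  oos <- parse_out_of_sight(records$out_of_sight, nrow(records))

  bad <- which(is.na(beh) == !oos)  # neither label nor flag, or both
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed record(s): each row needs either a behavior label or an ",
      "out-of-sight flag, not both/neither. Offending row(s): ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) ", ..." else ""
    ))
  }

  records$behavior <- beh
  records$.oos <- oos

  grp <- group_by %||% character(0)
  oos_tab <- records |>
    group_by(across(all_of(grp))) |>
    summarise(out_of_sight = sum(.data$.oos), .groups = "drop")

  if (out_of_sight == "pseudo_category") {
    records$behavior[oos] <- ".out_of_sight"
    visible <- records
  } else {
    visible <- filter(records, !.data$.oos)
  }

  counts <- visible |>
    count(across(all_of(c(grp, "behavior"))), name = "count") |>
    arrange(across(all_of(c(grp, "behavior"))))

  # groups whose every record was out of sight still appear, with no rows of
  # counts; callers see them through the attribute
  counts$count <- as.integer(counts$count)
  attr(counts, "out_of_sight") <- oos_tab
  counts
}

parse_out_of_sight <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) return(ifelse(is.na(x), FALSE, x != 0))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("1", "true", "t", "yes")
  bad <- !is.na(x) & nzchar(x) & !x %in% c("0", "1", "true", "false", "t", "f", "yes", "no")
  if (any(bad)) {
    abort(paste0("Unparseable `out_of_sight` value(s) at row(s): ",
                 paste(utils::head(which(bad), 10), collapse = ", ")))
  }
  out
}

#' Check a count table against an ethogram
#'
#' Reports behavior labels present in a count table but absent from the
#' ethogram's recognized categories. This is a report, not a gate: unknown
#' labels are returned, never raised as errors, so that coding slips can be
#' reviewed without interrupting a batch run.
#'
#' @param counts A data frame with a `behavior` column (e.g. from
#'   [tally_behaviors()]), or a named numeric count vector.
#' @param eth An [ethogram()].
#' @return Character vector of unknown labels (empty when fully consistent).
#' @examples
#' eth <- ethogram(c("rest", "feed"))
#' validate_against_ethogram(c(rest = 3, fly = 1), eth)
#' @export
validate_against_ethogram <- function(counts, eth) {
  stopifnot(inherits(eth, "ethogram"))
  labels <- if (is.data.frame(counts)) {
    as.character(counts$behavior)
  } else {
    names(counts)
  }
  if (is.null(labels)) abort("`counts` carries no behavior labels.")
  setdiff(unique(labels), c(eth$categories, ".out_of_sight"))
}

#' Summarize a count table
#'
#' Computes the summary statistics every index is built from: observed
#' richness `S` (categories with at least one observation), sampling effort
#' `N` (total observations), and the singleton and doubleton counts `F1` and
#' `F2` (categories seen exactly once or exactly twice) used by Chao1.
#'
#' @param counts A data frame with `count` (and optionally `behavior` and
#'   grouping) columns, or a numeric count vector.
#' @param group_by Optional character vector of grouping columns; one summary
#'   row is returned per group.
#' @return A tibble with columns `S`, `N`, `F1`, `F2` (plus any grouping
#'   columns).
#' @examples
#' count_summary(c(rest = 5, feed = 1, groom = 1, play = 2))
#' @export
count_summary <- function(counts, group_by = NULL) {
  if (!is.data.frame(counts)) {
    return(as_tibble(as.list(summarize_counts(as_count_vector(counts)))))
  }
  grp <- group_by %||% character(0)
  counts |>
    group_by(across(all_of(grp))) |>
    summarise(
      S  = sum(.data$count > 0),
      N  = as.integer(sum(.data$count)),
      F1 = sum(.data$count == 1),
      F2 = sum(.data$count == 2),
      .groups = "drop"
    )
}

# coerce a data frame / (named) numeric vector to a clean integer count vector
as_count_vector <- function(x, arg = "counts") {
  if (is.data.frame(x)) {
    if (!"count" %in% names(x)) {
      abort(paste0("`", arg, "` data frame must have a `count` column."))
    }
    v <- x$count
    if ("behavior" %in% names(x)) names(v) <- as.character(x$behavior)
  } else {
    v <- x
  }
  if (!is.numeric(v)) abort(paste0("`", arg, "` must be numeric counts."))
  if (anyNA(v)) abort(paste0("`", arg, "` contains missing values."))
  if (any(v < 0)) abort(paste0("`", arg, "` contains negative counts."))
  if (any(abs(v - round(v)) > 1e-8)) {
    abort(paste0("`", arg, "` must be whole-number counts; for proportion ",
                 "(duration) data use `index_shannon(..., input = \"proportions\")`."))
  }
  round(v)
}

# S, N, F1, F2 from a numeric count vector
summarize_counts <- function(n_i) {
  c(S  = sum(n_i > 0),
    N  = as.integer(sum(n_i)),
    F1 = sum(n_i == 1),
    F2 = sum(n_i == 2))
}
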