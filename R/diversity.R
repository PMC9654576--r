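#' Compute a battery of behavioral diversity indices
#'
#' One-call battery running every applicable index over a behavior count
#' table, per analysis unit. The Behavioral Variety Index is included only
#' when an expected (wild-type) repertoire is supplied, since it needs a
#' reference ethogram. Indices undefined for a given unit (for instance
#' Simpson's D when fewer than two observations were made) are reported with
#' an explanatory note, never silently dropped, so that batch sweeps over
#' heterogeneous units always return a complete roster.
#'
#' @param data A count table: data frame with `behavior` and `count` columns
#'   (e.g. from [tally_behaviors()]), plus any grouping columns; or a named
#'   numeric count vector for a single unit.
#' @param indices Character vector of index names to compute (see
#'   [index_names()]), or `"all"` (default).
#' @param group_by Character vector of columns identifying analysis units;
#'   `NULL` treats `data` as one unit.
#' @param ethogram Optional [ethogram()] whose expected repertoire enables
#'   the Behavioral Variety Index.
#' @param chao1_variant `"bias_corrected"` (default) or `"classic"`; see
#'   [index_chao1()].
#' @return An object of class `"behavdiv"`. Use [tidy()] for the per-index
#'   rows (`unit columns, index, value, S, N, F1, F2, note`), [glance()] for
#'   one summary row per unit, and [autoplot()] to visualise.
#' @examples
#' counts <- c(rest = 10, feed = 5, groom = 2, play = 1)
#' fit <- behavioral_diversity(counts)
#' tidy(fit)
#' glance(fit)
#' @export
behavioral_diversity <- function(data,
                                 indices = "all",
                                 group_by = NULL,
                                 ethogram = NULL,
                                 chao1_variant = c("bias_corrected", "classic")) {
  chao1_variant <- match.arg(chao1_variant)
  funs <- count_index_funs(chao1_variant)

  if (identical(indices, "all")) {
    roster <- names(funs)
    if (!is.null(ethogram) && !is.null(ethogram$expected)) {
      roster <- c(roster, "bvi")
    }
  } else {
    unknown <- setdiff(indices, index_names())
    if (length(unknown) > 0) {
      abort(paste0("Unknown index name(s): ", paste(unknown, collapse = ", "),
                   ". Known: ", paste(index_names(), collapse = ", ")))
    }
    roster <- indices
    if ("bvi" %in% roster &&
        (is.null(ethogram) || is.null(ethogram$expected))) {
      abort("The Behavioral Variety Index needs an ethogram with an expected repertoire.")
    }
  }
  if (length(roster) == 0) abort("Empty index roster.")

  if (!is.data.frame(data)) {
    data <- tibble(behavior = names(data) %||% paste0("b", seq_along(data)),
                   count = as.numeric(data))
  }
  grp <- group_by %||% character(0)
  units <- if (length(grp) > 0) {
    data |> distinct(across(all_of(grp)))
  } else {
    tibble(.rows = 1)
  }

  one_unit <- function(key) {
    unit_counts <- if (length(grp) > 0) {
      dplyr::semi_join(data, key, by = grp)
    } else {
      data
    }
    rows <- map_dfr(roster, function(idx) {
      if (idx == "bvi") {
        observed <- unit_counts$behavior[unit_counts$count > 0]
        index_bvi(as.character(observed), ethogram)
      } else {
        funs[[idx]](unit_counts)
      }
    })
    if (length(grp) > 0) dplyr::bind_cols(key[rep(1, nrow(rows)), , drop = FALSE], rows) else rows
  }

  results <- map_dfr(seq_len(nrow(units)), function(i) {
    one_unit(units[i, , drop = FALSE])
  })

  structure(
    list(results = results, group_by = grp, roster = roster,
         chao1_variant = chao1_variant),
    class = "behavdiv"
  )
}

#' @export
print.behavdiv <- function(x, ...) {
  cat("<behavdiv> ", length(x$roster), " indices",
      if (length(x$group_by) > 0) {
        paste0(" per ", paste(x$group_by, collapse = " x "))
      } else "",
      "\n", sep = "")
  print(x$results, ...)
  invisible(x)
}

#' Tidy a behavioral diversity result
#'
#' @param x A `"behavdiv"` object from [behavioral_diversity()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per unit and index (`index`,
#'   `value`, `S`, `N`, `F1`, `F2`, `note`, plus unit columns). `glance()`:
#'   one row per unit with the count summary and how many indices were
#'   computed or undefined.
#' @export
tidy.behavdiv <- function(x, ...) {
  x$results
}

#' @rdname tidy.behavdiv
#' @export
glance.behavdiv <- function(x, ...) {
  grp <- x$group_by
  x$results |>
    group_by(across(all_of(grp))) |>
    summarise(
      S = max(.data$S, na.rm = TRUE),
      N = suppressWarnings(max(.data$N, na.rm = TRUE)),
      F1 = suppressWarnings(max(.data$F1, na.rm = TRUE)),
      F2 = suppressWarnings(max(.data$F2, na.rm = TRUE)),
      n_indices = dplyr::n(),
      n_undefined = sum(is.na(.data$value)),
      .groups = "drop"
    )
}

#' Plot a behavioral diversity result
#'
#' Bar chart of index values, faceted by index (indices live on very
#' different scales), with one bar per analysis unit.
#'
#' @param object A `"behavdiv"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.behavdiv <- function(object, ...) {
  d <- object$results
  grp <- object$group_by
  d$unit <- if (length(grp) > 0) {
    do.call(paste, c(d[grp], sep = "/"))
  } else {
    "all"
  }
  d$index <- factor(d$index, levels = unique(d$index))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$value,
                                  fill = .data$unit)) +
    ggplot2::geom_col(show.legend = FALSE, na.rm = TRUE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "index value",
                  title = "Behavioral diversity indices") +
    ggplot2::theme_minimal()
}
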