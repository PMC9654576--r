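#' Define a deterministic count-profile scenario
#'
#' Scenarios generate synthetic behavior-count profiles that isolate one
#' property of the diversity indices at a time. They are fully deterministic
#' constructions -- no sampling noise -- so that index sensitivities to
#' richness, evenness and sampling effort can be read off exactly:
#'
#' * `"equal"`: `S` categories, each observed `m` times (maximal evenness).
#' * `"dominant_first"`: the first category is observed `k * m` times, the
#'   remaining `S - 1` categories `m` times each; increasing the dominance
#'   factor `k` lowers evenness at fixed richness.
#' * `"effort_sweep"`: equal-abundance profiles recomputed at each
#'   per-behavior count in `effort_levels`, exposing sampling-effort
#'   sensitivity at fixed richness and evenness.
#' * `"singleton_sweep"`: of `S` categories, `n_singletons` are reduced to a
#'   single observation and the rest keep the base count `m >= 2`, driving
#'   the singleton count `F1` that the Chao1 estimator responds to.
#'
#' `"equal"` is `"dominant_first"` with `k = 1`.
#'
#' @param kind One of `"equal"`, `"dominant_first"`, `"effort_sweep"`,
#'   `"singleton_sweep"`.
#' @param S Integer vector of richness values to sweep (default `1:10`).
#' @param m Per-behavior base count (default 5).
#' @param k Dominance multiplier(s) applied to the first behavior (default 1;
#'   may be a vector such as `c(1, 2, 10, 100)` to sweep dominance).
#' @param effort_levels Per-behavior counts for `"effort_sweep"` (default
#'   `c(1, 2, 3, 4, 5, 10, 100)`).
#' @param n_singletons Integer vector: how many of the `S` categories are
#'   reduced to count 1 in a `"singleton_sweep"` (default `0:9`).
#' @return An object of class `"scenario"`.
#' @examples
#' sc <- scenario("dominant_first", S = 1:10, m = 5, k = c(1, 2, 10, 100))
#' make_counts(sc, S = 3, k = 10)
#' @export
scenario <- function(kind = c("equal", "dominant_first", "effort_sweep",
                              "singleton_sweep"),
                     S = 1:10,
                     m = 5L,
                     k = 1L,
                     effort_levels = c(1L, 2L, 3L, 4L, 5L, 10L, 100L),
                     n_singletons = 0:9) {
  kind <- match.arg(kind)
  check_pos_int <- function(x, name, min = 1) {
    if (length(x) == 0 || anyNA(x) || any(x != round(x)) || any(x < min)) {
      abort(paste0("`", name, "` must be integer(s) >= ", min, "."))
    }
    as.integer(x)
  }
  S <- check_pos_int(S, "S")
  m <- check_pos_int(m, "m")
  k <- check_pos_int(k, "k")
  effort_levels <- check_pos_int(effort_levels, "effort_levels")
  n_singletons <- check_pos_int(n_singletons, "n_singletons", min = 0)
  if (length(m) != 1) abort("`m` must be a single base count.")
  if (kind == "equal" && any(k != 1)) {
    abort("`kind = \"equal\"` means no dominance: k must be 1.")
  }
  if (kind == "singleton_sweep") {
    if (m < 2) abort("Singleton sweeps need a base count m >= 2, so singletons are distinct.")
    if (any(n_singletons > min(S))) {
      abort("`n_singletons` cannot exceed S: a sweep cannot single out more categories than exist.")
    }
  }
  structure(list(kind = kind, S = S, m = m, k = k,
                 effort_levels = effort_levels, n_singletons = n_singletons),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario:", x$kind, "> S in {", paste(x$S, collapse = ","), "}, m =",
      x$m, "\n")
  if (x$kind == "dominant_first") cat("  k in {", paste(x$k, collapse = ","), "}\n")
  if (x$kind == "effort_sweep") {
    cat("  effort levels {", paste(x$effort_levels, collapse = ","), "}\n")
  }
  if (x$kind == "singleton_sweep") {
    cat("  n_singletons in {", paste(x$n_singletons, collapse = ","), "}\n")
  }
  invisible(x)
}

#' Generate one count profile from a scenario
#'
#' @param sc A [scenario()].
#' @param S Richness (number of behavior categories) for this profile.
#' @param m Per-behavior base count; defaults to the scenario's `m` (for
#'   effort sweeps, pass one of the scenario's `effort_levels`).
#' @param k Dominance factor; defaults to the scenario's first `k`.
#' @param n_singletons Number of singleton categories; defaults to the
#'   scenario's first value. Only used by singleton sweeps.
#' @return A tibble with columns `behavior` (`b1` ... `bS`, the first being
#'   the dominant one) and `count`.
#' @export
make_counts <- function(sc, S, m = sc$m, k = sc$k[1],
                        n_singletons = sc$n_singletons[1]) {
  stopifnot(inherits(sc, "scenario"))
  if (length(S) != 1 || is.na(S) || S < 1 || S != round(S)) {
    abort("`S` must be a single integer >= 1.")
  }
  S <- as.integer(S)
  counts <- switch(
    sc$kind,
    equal = ,
    effort_sweep = rep(m, S),
    dominant_first = c(k * m, rep(m, S - 1L))[seq_len(S)],
    singleton_sweep = {
      if (n_singletons > S) {
        abort("`n_singletons` exceeds S for this profile.")
      }
      c(rep(1L, n_singletons), rep(sc$m, S - n_singletons))
    }
  )
  tibble(behavior = paste0("b", seq_len(S)), count = as.integer(counts))
}

#' Run an index sweep over a scenario grid
#'
#' Evaluates the requested indices on every count profile the scenario
#' defines and returns one tidy row per (grid point, index). The grid depends
#' on the scenario kind: richness `S` crossed with the dominance factors `k`
#' (`"equal"`/`"dominant_first"`), with the `effort_levels`
#' (`"effort_sweep"`), or with `n_singletons` (`"singleton_sweep"`). Sweeps
#' contain no randomness: re-running one yields identical rows.
#'
#' @param sc A [scenario()].
#' @param indices Character vector of count-based index names (see
#'   [index_names()]; `"bvi"` is excluded -- it needs an expected repertoire,
#'   not a count profile).
#' @return A tibble with columns `kind`, `S`, `m`, `k`, `n_singletons`, `N`,
#'   `index`, `value`, `note`; undefined values carry notes.
#' @examples
#' sw <- run_sweep(scenario("equal", S = 1:5, m = 10), "shannon")
#' sw
#' @export
run_sweep <- function(sc, indices) {
  stopifnot(inherits(sc, "scenario"))
  if (length(indices) == 0) abort("`indices` must name at least one index.")
  bad <- setdiff(indices, setdiff(index_names(), "bvi"))
  if (length(bad) > 0) {
    abort(paste0("Not sweepable index name(s): ", paste(bad, collapse = ", ")))
  }
  grid <- switch(
    sc$kind,
    equal = ,
    dominant_first = tidyr::expand_grid(S = sc$S, m = sc$m, k = sc$k,
                                        n_singletons = NA_integer_),
    effort_sweep = tidyr::expand_grid(S = sc$S, m = sc$effort_levels, k = 1L,
                                      n_singletons = NA_integer_),
    singleton_sweep = tidyr::expand_grid(S = sc$S, m = sc$m, k = 1L,
                                         n_singletons = sc$n_singletons)
  )
  funs <- count_index_funs()
  rows <- pmap_dfr(grid, function(S, m, k, n_singletons) {
    cv <- make_counts(sc, S = S, m = m, k = k,
                      n_singletons = if (is.na(n_singletons)) 0L else n_singletons)
    map_dfr(indices, function(idx) {
      res <- funs[[idx]](cv)
      tibble(kind = sc$kind, S = S, m = m, k = k,
             n_singletons = n_singletons, N = res$N,
             index = idx, value = res$value, note = res$note)
    })
  })
  attr(rows, "grid") <- tidyr::expand_grid(grid, index = indices)
  rows
}

#' Built-in demonstration sweeps
#'
#' Seven canonical sweeps, each isolating one index property on a
#' deterministic grid (richness `S` 1--10, per-behavior counts
#' `{1, 2, 3, 4, 5, 10, 100}` where effort is swept, dominance factors
#' `{1, 2, 10, 100}` where evenness is swept):
#'
#' 1. Shannon-Wiener against richness, at dominance factors 1/2/10/100 --
#'    equal representation maximises `H'` at `ln S`; dominance lowers it.
#' 2. The three Simpson variants on one shared equal-abundance grid -- the
#'    `1 - D` and `1 / D` identities hold cell-wise.
#' 3. Simpson's D against richness at the same dominance factors.
#' 4. Simpson's D across per-behavior counts at fixed proportions -- unlike
#'    Shannon, D changes with the number of observations.
#' 5. Menhinick's index across per-behavior counts -- decreasing in effort.
#' 6. Margalef's index across per-behavior counts -- decreasing in effort.
#' 7. Chao1 on ten categories as 0--9 of them become singletons -- the
#'    estimate starts at the observed richness and never decreases.
#'
#' @param id Integer 1--7.
#' @return A sweep tibble as from [run_sweep()].
#' @examples
#' reference_sweep(7)
#' @export
reference_sweep <- function(id) {
  if (length(id) != 1 || !id %in% 1:7) abort("`id` must be one of 1..7.")
  dominance <- scenario("dominant_first", S = 1:10, m = 5, k = c(1, 2, 10, 100))
  effort <- scenario("effort_sweep", S = 1:10)
  switch(
    id,
    run_sweep(dominance, "shannon"),
    run_sweep(scenario("equal", S = 1:10, m = 5),
              c("simpson_d", "simpson_diversity", "simpson_reciprocal")),
    run_sweep(dominance, "simpson_d"),
    run_sweep(effort, "simpson_d"),
    run_sweep(effort, "menhinick"),
    run_sweep(effort, "margalef"),
    run_sweep(scenario("singleton_sweep", S = 10, m = 5, n_singletons = 0:9),
              "chao1")
  )
}

#' Export a sweep as a tidy table
#'
#' Writes a sweep to CSV after checking the grid is complete: every
#' (grid point, index) combination the sweep promised must be present exactly
#' once. Incomplete results are rejected with the missing cells listed, and
#' nothing is written.
#'
#' @param sweep A sweep tibble from [run_sweep()] or [reference_sweep()].
#' @param path Output CSV path.
#' @param plot Optional path: also render [plot_sweep()] there (format from
#'   the extension).
#' @return `path`, invisibly.
#' @export
export_sweep_table <- function(sweep, path, plot = NULL) {
  if (is.null(sweep) || nrow(sweep) == 0) {
    abort("Empty sweep: nothing to export.")
  }
  grid <- attr(sweep, "grid")
  if (!is.null(grid)) {
    key_cols <- intersect(names(grid), names(sweep))
    have <- dplyr::count(sweep, across(all_of(key_cols)))
    check <- left_join(grid, have, by = key_cols)
    missing_cells <- filter(check, is.na(.data$n))
    if (nrow(missing_cells) > 0) {
      abort(paste0(
        "Incomplete sweep; missing grid cells: ",
        paste(utils::capture.output(print(as.data.frame(
          utils::head(missing_cells, 10)))), collapse = "\n")
      ))
    }
    if (any(check$n > 1, na.rm = TRUE)) {
      abort("Sweep has duplicated grid cells.")
    }
  }
  readr::write_csv(sweep, path, na = "")
  if (!is.null(plot)) {
    ggplot2::ggsave(plot, plot_sweep(sweep), width = 7, height = 4.5)
  }
  invisible(path)
}

#' Plot a sweep
#'
#' Line plot of index values across the sweep grid. The x axis is the swept
#' quantity (`n_singletons` for singleton sweeps, otherwise richness `S`);
#' series distinguish dominance factors, effort levels, or index variants,
#' whichever the sweep varies.
#'
#' @param sweep A sweep tibble from [run_sweep()] or [reference_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  if (nrow(sweep) == 0) abort("Empty sweep.")
  kind <- sweep$kind[1]
  if (kind == "singleton_sweep") {
    xvar <- "n_singletons"; xlab <- "singleton categories (F1)"
  } else {
    xvar <- "S"; xlab <- "behavior categories observed (S)"
  }
  series <- if (dplyr::n_distinct(sweep$k) > 1) {
    sweep$series <- factor(sweep$k); "dominance factor k"
  } else if (dplyr::n_distinct(sweep$m) > 1) {
    sweep$series <- factor(sweep$m); "per-behavior count m"
  } else {
    sweep$series <- factor(sweep$index); "index"
  }
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data[[xvar]], y = .data$value,
                               colour = .data$series, group = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::labs(x = xlab, y = "index value", colour = series) +
    ggplot2::theme_minimal()
}
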