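#' Behavioral diversity indices
#'
#' Each `index_*()` function computes one diversity index from a single
#' analysis unit's behavior counts and returns a one-row tibble recording the
#' value together with the input summary (`S`, `N`, `F1`, `F2`) for
#' auditability. Inputs may be a data frame with a `count` column (e.g. one
#' unit of [tally_behaviors()] output) or a plain (optionally named) numeric
#' vector of counts.
#'
#' Conventions shared by all indices:
#' * zero-count categories never contribute -- observed richness `S` counts
#'   categories actually seen;
#' * natural logarithms throughout;
#' * `0 * log(0)` is taken as 0 (the standard entropy convention);
#' * an index that is undefined for the given input (e.g. Simpson's D with
#'   fewer than two observations) returns `value = NA` with an explanatory
#'   `note` rather than throwing, so batch sweeps complete.
#'
#' The indices:
#' * **richness** -- `S`, the number of behavior categories observed.
#' * **shannon** -- Shannon-Wiener entropy `H' = -sum(p_i * ln p_i)` over the
#'   behavioral proportions `p_i = n_i / N`; 0 when a single behavior is seen,
#'   at most `ln S`, with equality when all behaviors are equally represented.
#'   Proportion (e.g. duration-based) data are accepted via
#'   `input = "proportions"`.
#' * **simpson_d** -- Simpson's index
#'   `D = sum(n_i * (n_i - 1)) / (N * (N - 1))`, the probability that two
#'   observations drawn without replacement are of the same behavior;
#'   1 = lowest diversity, 0 = highest. Requires `N >= 2`. Unlike Shannon,
#'   it runs on raw counts, so it is sensitive to the number of observations.
#' * **simpson_diversity** -- Simpson's index of diversity, `1 - D`
#'   (1 = highest diversity).
#' * **simpson_reciprocal** -- Simpson's reciprocal index, `1 / D` (lowest
#'   value 1, unbounded above); undefined when `D = 0`.
#' * **menhinick** -- `R1 = S / sqrt(N)`.
#' * **margalef** -- `R2 = (S - 1) / ln(N)`; requires `N >= 2`.
#' * **chao1** -- nonparametric estimate of the true number of behavior
#'   categories, including unobserved ones. The bias-corrected form (default)
#'   is `Sobs + F1 * (F1 - 1) / (2 * (F2 + 1))`, defined for any `F2` and
#'   equal to `Sobs` when `F1 <= 1`. `variant = "classic"` gives
#'   `Sobs + F1^2 / (2 * F2)`, undefined when `F2 = 0`.
#'
#' @param x Counts: a data frame with a `count` column, or a numeric vector.
#' @param input For [index_shannon()]: `"counts"` (default) or
#'   `"proportions"` for pre-normalized proportion/duration data summing to 1.
#' @param variant For [index_chao1()]: `"bias_corrected"` (default) or
#'   `"classic"`.
#' @return A one-row tibble with columns `index`, `value`, `S`, `N`, `F1`,
#'   `F2`, `note` (`note` is `NA` unless the value is undefined or flagged).
#' @examples
#' index_shannon(c(rest = 2, feed = 1, groom = 1))
#' index_simpson_d(c(a = 5, b = 5))
#' index_chao1(c(rep(3, 7), 1, 1, 1))
#' @name indices
NULL

index_result <- function(index, value, summ, note = NA_character_) {
  tibble(index = index, value = as.numeric(unname(value)),
         S = unname(summ["S"]), N = unname(summ["N"]),
         F1 = unname(summ["F1"]), F2 = unname(summ["F2"]),
         note = note)
}

#' @rdname indices
#' @export
index_richness <- function(x) {
  n_i <- as_count_vector(x)
  summ <- summarize_counts(n_i)
  index_result("richness", as.numeric(summ["S"]), summ)
}

#' @rdname indices
#' @export
index_shannon <- function(x, input = c("counts", "proportions")) {
  input <- match.arg(input)
  if (input == "proportions") {
    p <- if (is.data.frame(x)) x$count else x
    if (!is.numeric(p) || anyNA(p)) abort("Proportions must be numeric and complete.")
    if (any(p < 0)) abort("Proportions must be non-negative.")
    if (abs(sum(p) - 1) > 1e-9) {
      abort("Proportions must sum to 1 (tolerance 1e-9).")
    }
    p <- p[p > 0]
    summ <- c(S = length(p), N = NA_integer_, F1 = NA_integer_, F2 = NA_integer_)
    return(index_result("shannon", -sum(p * log(p)) + 0, summ,
                        note = "input: proportions"))
  }
  n_i <- as_count_vector(x)
  summ <- summarize_counts(n_i)
  if (summ["N"] < 1) {
    return(index_result("shannon", NA_real_, summ, "undefined: N = 0"))
  }
  p <- n_i[n_i > 0] / summ["N"]
  index_result("shannon", -sum(p * log(p)) + 0, summ)  # + 0 normalizes -0
}

simpson_d_value <- function(n_i, N) {
  sum(n_i * (n_i - 1)) / (N * (N - 1))
}

#' @rdname indices
#' @export
index_simpson_d <- function(x) {
  n_i <- as_count_vector(x)
  summ <- summarize_counts(n_i)
  if (summ["N"] < 2) {
    return(index_result("simpson_d", NA_real_, summ,
                        "undefined: insufficient observations (N < 2)"))
  }
  index_result("simpson_d", simpson_d_value(n_i, summ["N"]), summ)
}

#' @rdname indices
#' @export
index_simpson_diversity <- function(x) {
  res <- index_simpson_d(x)
  res$index <- "simpson_diversity"
  res$value <- 1 - res$value
  res
}

#' @rdname indices
#' @export
index_simpson_reciprocal <- function(x) {
  res <- index_simpson_d(x)
  res$index <- "simpson_reciprocal"
  if (is.na(res$value)) return(res)
  if (res$value == 0) {
    res$value <- NA_real_
    res$note <- "undefined: reciprocal diverges (D = 0)"
    return(res)
  }
  res$value <- 1 / res$value
  res
}

#' @rdname indices
#' @export
index_menhinick <- function(x) {
  n_i <- as_count_vector(x)
  summ <- summarize_counts(n_i)
  if (summ["N"] < 1) {
    return(index_result("menhinick", NA_real_, summ, "undefined: N = 0"))
  }
  index_result("menhinick", summ["S"] / sqrt(summ["N"]), summ)
}

#' @rdname indices
#' @export
index_margalef <- function(x) {
  n_i <- as_count_vector(x)
  summ <- summarize_counts(n_i)
  if (summ["N"] < 2) {
    return(index_result("margalef", NA_real_, summ,
                        "undefined: N <= 1 (ln N vanishes)"))
  }
  index_result("margalef", (summ["S"] - 1) / log(summ["N"]), summ)
}

#' @rdname indices
#' @export
index_chao1 <- function(x, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  n_i <- as_count_vector(x)
  summ <- summarize_counts(n_i)
  if (summ["N"] < 1) {
    return(index_result("chao1", NA_real_, summ, "undefined: no observations"))
  }
  S <- summ["S"]; F1 <- summ["F1"]; F2 <- summ["F2"]
  if (variant == "bias_corrected") {
    value <- S + F1 * (F1 - 1) / (2 * (F2 + 1))
    note <- NA_character_
  } else if (F2 == 0) {
    value <- NA_real_
    note <- "undefined: classic variant needs F2 > 0"
  } else {
    value <- S + F1^2 / (2 * F2)
    note <- "variant: classic"
  }
  index_result("chao1", unname(value), summ, note)
}

#' Behavioral Variety Index
#'
#' The Behavioral Variety Index (BVI) compares the behavioral repertoire
#' observed in a study against the full repertoire the species is expected to
#' express in its natural state: `BVI = Ob / Ex * 100`, a percentage per
#' animal. `Ob` is the number of expected behavior categories observed at
#' least once; `Ex` is the size of the expected repertoire. Low values
#' indicate poorer behavioral diversity. Evenness plays no role -- only
#' presence or absence of each category is recorded.
#'
#' When `observed` and `expected` are both label vectors, `Ob` is the size of
#' their intersection; observed categories absent from the expected repertoire
#' do not count toward `Ob` (the index measures expression of the wild-type
#' repertoire) and trigger a warning. With integer inputs, `Ob > Ex` is
#' allowed -- captive animals may show behaviors absent from the wild
#' ethogram -- but flagged in the `note`.
#'
#' @param observed Integer `Ob`, or a character vector of observed behavior
#'   labels, or a counts data frame/named vector (categories with count > 0
#'   count as observed).
#' @param expected Integer `Ex >= 1`, a character vector of expected labels,
#'   or an [ethogram()] with an expected repertoire.
#' @return A one-row tibble as the other `index_*()` functions (`S` is `Ob`;
#'   `N`, `F1`, `F2` are `NA` when only presence/absence is known).
#' @examples
#' index_bvi(7, 20)
#' index_bvi(c("rest", "feed"), c("rest", "feed", "play", "forage"))
#' @export
index_bvi <- function(observed, expected) {
  if (inherits(expected, "ethogram")) {
    if (is.null(expected$expected)) {
      abort("This ethogram carries no expected repertoire.")
    }
    expected <- expected$expected
  }
  if (is.character(expected)) {
    expected <- unique(expected)
    ex <- length(expected)
  } else {
    ex <- expected
    expected <- NULL
  }
  if (length(ex) != 1 || is.na(ex) || ex < 1) {
    abort("`expected` must give a repertoire of at least one category (Ex >= 1).")
  }

  note <- NA_character_
  if (is.character(observed)) {
    observed <- unique(observed)
  } else if (is.data.frame(observed) || !is.null(names(observed))) {
    v <- as_count_vector(observed, arg = "observed")
    observed <- names(v)[v > 0]
  }
  if (is.character(observed)) {
    if (!is.null(expected)) {
      extras <- setdiff(observed, expected)
      if (length(extras) > 0) {
        warn(paste0("Observed categories outside the expected repertoire are ",
                    "not counted toward Ob: ", paste(extras, collapse = ", ")))
        note <- paste0("excluded from Ob: ", paste(extras, collapse = ";"))
      }
      ob <- length(intersect(observed, expected))
    } else {
      ob <- length(observed)
    }
  } else {
    ob <- observed
    if (length(ob) != 1 || is.na(ob) || ob < 0) {
      abort("`observed` must be a count Ob >= 0 or a vector of labels.")
    }
  }
  if (ob > ex) {
    note <- paste(stats::na.omit(c(note, "Ob exceeds Ex")), collapse = "; ")
  }
  summ <- c(S = as.integer(ob), N = NA_integer_, F1 = NA_integer_,
            F2 = NA_integer_)
  index_result("bvi", ob / ex * 100, summ, note)
}

# roster of count-based indices, in reporting order
count_index_funs <- function(chao1_variant = "bias_corrected") {
  list(
    richness           = index_richness,
    shannon            = index_shannon,
    simpson_d          = index_simpson_d,
    simpson_diversity  = index_simpson_diversity,
    simpson_reciprocal = index_simpson_reciprocal,
    menhinick          = index_menhinick,
    margalef           = index_margalef,
    chao1              = function(x) index_chao1(x, variant = chao1_variant)
  )
}

#' @rdname behavioral_diversity
#' @export
index_names <- function() c(names(count_index_funs()), "bvi")
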