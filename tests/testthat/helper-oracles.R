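# Independent oracles, deliberately naive: they never share code with the
# index implementations they check.

# probability that two observations drawn without replacement share a
# behavior, by exhaustive enumeration of ordered pairs
simpson_pair_oracle <- function(counts) {
  obs <- rep(seq_along(counts), counts)
  N <- length(obs)
  if (N < 2) return(NA_real_)
  matches <- 0L
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j && obs[i] == obs[j]) matches <- matches + 1L
    }
  }
  matches / (N * (N - 1))
}

# all count vectors over exactly `slots` categories with total in n_range
# (zero-count slots allowed, so this covers S <= slots)
enumerate_count_vectors <- function(slots, n_max, n_min = 2) {
  grid <- do.call(expand.grid, rep(list(0:n_max), slots))
  grid <- grid[rowSums(grid) >= n_min & rowSums(grid) <= n_max, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
}

# brute-force tally of a record data frame, independent of tally_behaviors
brute_tally <- function(records, keys) {
  visible <- records[!as.logical(records$out_of_sight), , drop = FALSE]
  split_key <- interaction(visible[keys], drop = TRUE)
  lapply(split(visible$behavior, split_key), function(b) table(b))
}

# deterministic pseudo-random record sets for property tests
random_records <- function(n, n_subjects = 3, n_behaviors = 5, p_oos = 0.1) {
  tibble::tibble(
    subject = sample(paste0("s", seq_len(n_subjects)), n, replace = TRUE),
    session = sample(c("am", "pm"), n, replace = TRUE),
    behavior = sample(paste0("beh", seq_len(n_behaviors)), n, replace = TRUE),
    out_of_sight = as.integer(runif(n) < p_oos)
  ) |>
    dplyr::mutate(behavior = ifelse(out_of_sight == 1, NA_character_, behavior))
}
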