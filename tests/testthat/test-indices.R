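test_that("richness counts observed categories only", {
  expect_equal(index_richness(rep(3, 8))$value, 8)
  expect_equal(index_richness(numeric(0))$value, 0)
  expect_equal(index_richness(c(a = 1, b = 0, c = 5))$value, 2)
})

test_that("Shannon-Wiener matches hand-computed entropy and vegan", {
  expect_equal(index_shannon(c(a = 25))$value, 0)
  expect_equal(index_shannon(c(7, 7, 7, 7))$value, log(4))
  # p = (0.5, 0.25, 0.25): -(0.5 ln 0.5 + 2 * 0.25 ln 0.25)
  expect_equal(index_shannon(c(a = 2, b = 1, c = 1))$value, 1.039721,
               tolerance = 1e-6)

  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    x <- sample(1:20, sample(2:8, 1), replace = TRUE)
    expect_equal(index_shannon(x)$value, vegan::diversity(x, "shannon"))
  }
})

test_that("Shannon accepts proportion (duration) input", {
  expect_equal(index_shannon(c(0.5, 0.25, 0.25), input = "proportions")$value,
               1.039721, tolerance = 1e-6)
  expect_error(index_shannon(c(0.5, 0.4), input = "proportions"), "sum to 1")
  expect_error(index_shannon(c(1.2, -0.2), input = "proportions"),
               "non-negative")
  expect_equal(index_shannon(c(a = 0))$note, "undefined: N = 0")
})

test_that("Simpson family follows the without-replacement formula", {
  expect_equal(index_simpson_d(c(a = 10))$value, 1)
  expect_equal(index_simpson_d(c(a = 5, b = 5))$value, 40 / 90)
  expect_equal(index_simpson_d(c(a = 1, b = 1))$value, 0)

  expect_equal(index_simpson_diversity(c(a = 10))$value, 0)
  expect_equal(index_simpson_diversity(c(a = 5, b = 5))$value, 1 - 40 / 90)
  expect_equal(index_simpson_diversity(c(a = 1, b = 1))$value, 1)

  expect_equal(index_simpson_reciprocal(c(a = 10))$value, 1)
  expect_equal(index_simpson_reciprocal(c(a = 5, b = 5))$value, 2.25)
  rec <- index_simpson_reciprocal(c(a = 1, b = 1))
  expect_true(is.na(rec$value))
  expect_match(rec$note, "diverges")

  one_obs <- index_simpson_d(c(a = 1))
  expect_true(is.na(one_obs$value))
  expect_match(one_obs$note, "insufficient")
})

test_that("Menhinick is S over the square root of N", {
  expect_equal(index_menhinick(c(2, 2))$value, 1)       # S=2, N=4
  expect_equal(index_menhinick(c(3, 3, 3))$value, 1)    # S=3, N=9
  expect_equal(index_menhinick(c(a = 1))$value, 1)
  expect_true(is.na(index_menhinick(c(a = 0))$value))
})

test_that("Margalef is (S - 1) over ln N", {
  expect_equal(index_margalef(c(a = 10))$value, 0)
  expect_equal(index_margalef(c(20, 20, 20, 20, 20))$value, 4 / log(100))
  expect_true(is.na(index_margalef(c(a = 1))$value))
  # fixed S, growing N: strictly decreasing
  vals <- sapply(c(2, 5, 20, 100), function(m) index_margalef(rep(m, 5))$value)
  expect_true(all(diff(vals) < 0))
})

test_that("Chao1 bias-corrected estimator matches hand values and vegan", {
  expect_equal(index_chao1(rep(2, 10))$value, 10)
  # Sobs=10, F1=3, F2=2 -> 10 + 3*2 / (2*3) = 11
  x <- c(1, 1, 1, 2, 2, 5, 5, 5, 5, 5)
  expect_equal(index_chao1(x)$value, 11)
  # all singletons: S + S(S-1)/2
  expect_equal(index_chao1(rep(1, 6))$value, 6 + 6 * 5 / 2)

  skip_if_not_installed("vegan")
  set.seed(3)
  for (i in 1:10) {
    y <- sample(1:6, 10, replace = TRUE)
    expect_equal(index_chao1(y)$value,
                 unname(vegan::estimateR(y)["S.chao1"]))
  }
})

test_that("classic Chao1 variant is available and guarded", {
  x <- c(1, 1, 1, 2, 2, 5, 5)
  expect_equal(index_chao1(x, variant = "classic")$value, 7 + 9 / 4)
  no_doubletons <- index_chao1(c(1, 1, 5, 5), variant = "classic")
  expect_true(is.na(no_doubletons$value))
  expect_match(no_doubletons$note, "F2")
})

test_that("BVI is the percentage of the expected repertoire expressed", {
  expect_equal(index_bvi(12, 12)$value, 100)
  expect_equal(index_bvi(0, 20)$value, 0)
  expect_equal(index_bvi(7, 20)$value, 35)
  expect_error(index_bvi(5, 0), "Ex >= 1")

  # label inputs: Ob is the intersection with the expected repertoire
  expect_equal(index_bvi(c("rest", "feed"), c("rest", "feed", "play", "dig"))$value, 50)
  expect_warning(
    res <- index_bvi(c("rest", "pace"), c("rest", "feed")),
    "not counted"
  )
  expect_equal(res$value, 50)
  flagged <- index_bvi(8, 5)
  expect_match(flagged$note, "exceeds")
})

test_that("the index battery matches individual index calls and flags undefined values", {
  cv <- c(rest = 9, feed = 3, groom = 1, play = 1)
  eth <- ethogram(names(cv), expected = c(names(cv), "forage"))
  fit <- behavioral_diversity(cv, ethogram = eth)
  res <- tidy(fit)
  expect_equal(nrow(res), 9)

  singles <- list(
    richness = index_richness(cv), shannon = index_shannon(cv),
    simpson_d = index_simpson_d(cv),
    simpson_diversity = index_simpson_diversity(cv),
    simpson_reciprocal = index_simpson_reciprocal(cv),
    menhinick = index_menhinick(cv), margalef = index_margalef(cv),
    chao1 = index_chao1(cv)
  )
  for (nm in names(singles)) {
    expect_equal(res$value[res$index == nm], singles[[nm]]$value, info = nm)
  }
  expect_equal(res$value[res$index == "bvi"], 80)

  # N = 1: Simpson and Margalef undefined but present, with notes
  small <- tidy(behavioral_diversity(c(rest = 1)))
  expect_equal(nrow(small), 8)
  undef <- small[small$index %in% c("simpson_d", "simpson_diversity",
                                    "simpson_reciprocal", "margalef"), ]
  expect_true(all(is.na(undef$value)))
  expect_true(all(!is.na(undef$note)))
})

test_that("the battery computes per-unit results and glance summarises them", {
  counts <- tibble::tibble(
    unit = rep(c("a", "b"), each = 3),
    behavior = rep(c("rest", "feed", "groom"), 2),
    count = c(4, 2, 0, 1, 1, 1)
  )
  fit <- behavioral_diversity(counts, group_by = "unit")
  res <- tidy(fit)
  expect_equal(sort(unique(res$unit)), c("a", "b"))
  expect_equal(unique(res$S[res$unit == "a"]), 2L)
  g <- glance(fit)
  expect_equal(g$N[g$unit == "b"], 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("unknown index names are rejected", {
  expect_error(behavioral_diversity(c(a = 3), indices = "pielou"), "Unknown index")
  expect_error(behavioral_diversity(c(a = 3), indices = "bvi"), "expected repertoire")
})
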