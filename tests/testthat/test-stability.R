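test_that("median-of-ratios size factors match the hand-evaluated formula", {
  m <- rbind(a = c(10, 20), b = c(30, 60))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)

  # identical samples -> all factors 1
  m2 <- matrix(rep(c(3, 7, 11), 4), ncol = 4,
               dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m2)), rep(1, 4))

  # a transcript with a zero is excluded from the reference set: removing
  # it leaves the factors unchanged
  m3 <- rbind(a = c(10, 20), b = c(30, 60), z = c(0, 5))
  expect_equal(size_factors(m3), size_factors(m3[c("a", "b"), ]))

  # all-zero-containing matrix -> informative error
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "reference")
})

test_that("normalization inverts the factors and is a fixed point", {
  set.seed(11)
  m <- matrix(rpois(60, 50) + 1, 10, 6,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  expect_equal(normalize_counts(m, rep(1, 6)), m)

  m_scaled <- m
  m_scaled[, 3] <- m[, 3] * 2
  expect_equal(normalize_counts(m_scaled, c(1, 1, 2, 1, 1, 1))[, 3], m[, 3])

  norm <- normalize_counts(m)
  # size factors of a normalized matrix are all 1
  expect_equal(unname(size_factors(norm)), rep(1, 6), tolerance = 1e-9)
  # hence idempotence
  expect_equal(normalize_counts(norm), norm, tolerance = 1e-9)

  expect_error(normalize_counts(m, c(1, 2)), "per sample")
})

test_that("cv is the n-1 sd over the mean, scale invariant, NA at mean 0", {
  expect_equal(cv(rep(4, 5)), 0)
  expect_equal(cv(c(2, 4)), sqrt(2) / 3, tolerance = 1e-10)
  expect_equal(round(cv(c(2, 4)), 4), 0.4714)
  expect_true(is.na(cv(c(0, 0, 0))))
  set.seed(1)
  for (i in 1:20) {
    x <- runif(8, 1, 100)
    c_ <- runif(1, 0.01, 50)
    expect_equal(cv(c_ * x), cv(x), tolerance = 1e-12)
  }
})

test_that("percentile rank counts values <= v over n", {
  expect_equal(unname(percentile_rank(c(0.2, 0.5, 0.9, 1.4))),
               c(0.25, 0.5, 0.75, 1))
  expect_equal(unname(percentile_rank(rep(3, 5))), rep(1, 5))
  x <- c(5, 1, 9, 2)
  expect_equal(min(percentile_rank(x)), 1 / 4)
  expect_length(percentile_rank(numeric()), 0)
  # invariant to strictly increasing transforms, monotone in the statistic
  set.seed(2)
  for (i in 1:10) {
    v <- rnorm(50)
    expect_equal(percentile_rank(v), percentile_rank(exp(v)))
    expect_equal(order(percentile_rank(v)), order(rank(v, ties.method = "first")))
  }
  # NA values are excluded from the denominator
  expect_equal(unname(percentile_rank(c(1, NA, 2))), c(0.5, NA, 1))
})

test_that("geometric mean propagates zeros", {
  expect_equal(geometric_mean(c(4, 9)), 6)
  expect_equal(geometric_mean(c(1, 1, 8)), 2)
  expect_equal(geometric_mean(c(3, 0, 9)), 0)
})

test_that("low-expression filter keeps mean raw count >= 1", {
  m <- rbind(zero = c(0, 0, 0), low = c(1, 1, 0.97), edge = c(1, 1, 1),
             high = c(5, 5, 5))
  f <- low_expression_filter(m)
  expect_equal(unname(f), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(names(f), rownames(m))
})

test_that("stability table ranks only filtered transcripts", {
  set.seed(3)
  m <- matrix(rpois(50 * 10, 40) + 1, 50, 10,
              dimnames = list(sprintf("t%02d", 1:50), sprintf("s%02d", 1:10)))
  m[1:5, ] <- 0            # filtered out
  st <- stability_table(m)
  expect_equal(nrow(st), 50)
  expect_false(any(st$passes_filter[1:5]))
  expect_true(all(is.na(st$cv_percentile[1:5])))
  kept <- st[st$passes_filter, ]
  expect_equal(max(kept$cv_percentile), 1)
  expect_equal(min(kept$cv_percentile), 1 / nrow(kept))
  expect_true(all(kept$cv >= 0))
  # metadata coverage check
  md <- data.frame(sample = sprintf("s%02d", 1:9), tissue = "x", stage = "y")
  expect_error(stability_table(m, md), "does not cover")
})

test_that("size factors agree with the reference estimator up to a scalar", {
  skip_if_not_installed("DESeq2")
  set.seed(19)
  m <- matrix(rnbinom(300 * 8, mu = 60, size = 10), 300, 8,
              dimnames = list(sprintf("t%03d", 1:300), sprintf("s%d", 1:8)))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ratio <- ours / ref
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
})
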