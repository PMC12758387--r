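test_that("cpm closed forms and scaling", {
  counts <- matrix(c(50, 1e6 - 50), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(cpm(counts)["a", 1], 50)
  expect_equal(unname(colSums(cpm(counts))), 1e6)
  expect_equal(cpm(counts, library_sizes = 2e6)["a", 1], 25)
  expect_error(cpm(counts, library_sizes = 0), "zero library")
})

test_that("replicate correlation: identity, depth invariance, hand Pearson", {
  base <- matrix(rpois(200, 30), 100, 2)
  base[, 2] <- base[, 1]
  r <- replicate_correlation(base)
  expect_equal(r[1, 2], 1)

  scaled <- cbind(base[, 1], 2 * base[, 1])  # exact 2x depth
  expect_equal(replicate_correlation(scaled)[1, 2], 1)

  # hand Pearson formula as the oracle on the log2-CPM transform
  set.seed(51)
  tab <- matrix(rpois(60, 40), 30, 2)
  got <- replicate_correlation(tab)[1, 2]
  lv <- log2(t(t(tab) * 1e6 / colSums(tab)) + 1)
  x <- lv[, 1]; y <- lv[, 2]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got, hand)
  # the worked Pearson example: r((1,2,3),(2,4,7)) by the closed form
  expect_equal(round(sum((c(1,2,3)-2) * (c(2,4,7)-13/3)) /
    sqrt(sum((c(1,2,3)-2)^2) * sum((c(2,4,7)-13/3)^2)), 5), 0.99340)

  expect_warning(r2 <- replicate_correlation(cbind(c(1, 1, 1), c(1, 2, 3))),
                 "constant")
  expect_true(is.na(attr(r2, "merge_ok")))
})

test_that("ma_stat computes D and A with ranking and flags", {
  merged <- matrix(c(10, 0, 0,
                     10, 8, 0), 3, 2,
                   dimnames = list(c("p1", "p2", "p3"), c("mid", "old")))
  ma <- ma_stat(merged, "mid", "old", normalized = FALSE)
  expect_equal(ma$D, c(0, 8, 0))
  expect_equal(ma$A[1], 1)          # log10((10+10)/2)
  expect_equal(ma$A[2], log10(4))   # (0 + 8)/2
  expect_true(ma$flagged[3])
  expect_true(is.na(ma$rank[3]))
  expect_equal(ma$rank[2], 1)

  # CPM mode: D sums to zero over the shared universe
  set.seed(52)
  m2 <- matrix(rpois(40, 100), 20, 2, dimnames = list(NULL, c("mid", "old")))
  ma2 <- ma_stat(m2, "mid", "old")
  expect_equal(sum(ma2$D), 0, tolerance = 1e-9)
})

test_that("poisson_rate_test: closed forms, symmetry, oracle agreement", {
  expect_equal(poisson_rate_test(7, 100, 7, 100), 1)
  expect_equal(poisson_rate_test(0, 1e6, 10, 1e6), 2 * 0.5^10)
  expect_equal(poisson_rate_test(0, 1e6, 10, 1e6), 0.001953125)
  expect_equal(poisson_rate_test(3, 50, 9, 150), 1)  # proportional rates
  expect_equal(poisson_rate_test(12, 100, 30, 200),
               poisson_rate_test(30, 200, 12, 100))
  expect_equal(poisson_rate_test(0, 10, 0, 10), 1)

  # base-R exact Poisson comparison as an independent oracle
  for (case in list(c(5, 100, 15, 100), c(40, 1000, 22, 800),
                    c(2, 50, 9, 60))) {
    expect_equal(poisson_rate_test(case[1], case[2], case[3], case[4]),
                 stats::poisson.test(c(case[1], case[3]),
                                     c(case[2], case[4]))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("track_score_intervals averages normalized signal, vs loop oracle", {
  g <- c(chrA = 1000)
  uni <- make_track(list(chrA = rep(1, 1000)), 1, g)
  iv <- data.frame(chrom = "chrA", start = c(0, 100), end = c(50, 200))
  expect_equal(track_score_intervals(uni, iv), c(1, 1))

  half <- make_track(list(chrA = c(rep(10, 50), rep(0, 950))), 1, g)
  expect_equal(track_score_intervals(half, data.frame(chrom = "chrA",
                                                      start = 0, end = 100)), 5)

  set.seed(53)
  v <- runif(1000)
  tr <- make_track(list(chrA = v), 1, g)
  ivx <- data.frame(chrom = "chrA", start = s <- sample(0:900, 20, TRUE))
  ivx$end <- ivx$start + sample(1:100, 20, TRUE)
  oracle <- vapply(seq_len(20), function(i) mean(v[(ivx$start[i] + 1):ivx$end[i]]),
                   numeric(1))
  expect_equal(track_score_intervals(tr, ivx), oracle)
  expect_error(track_score_intervals(tr, data.frame(chrom = "chrA",
                                                    start = 990, end = 1100)),
               "outside")
  # binned track agrees with the per-base answer on bin-aligned intervals
  trb <- make_track(list(chrA = vapply(seq(1, 1000, 10), function(s)
    mean(v[s:(s + 9)]), numeric(1))), 10, g)
  aligned <- data.frame(chrom = "chrA", start = c(0, 200), end = c(100, 500))
  expect_equal(track_score_intervals(trb, aligned),
               track_score_intervals(tr, aligned))
})

test_that("quartile_rank is descending with ties sharing the better quartile", {
  expect_equal(quartile_rank(1:8), rev(rep(1:4, each = 2)))
  expect_equal(quartile_rank(rep(3, 5)), rep(1L, 5))
  q <- quartile_rank(c(10, 10, 5, 1))
  expect_equal(q, c(1L, 1L, 3L, 4L))
})
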