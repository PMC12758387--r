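test_that("read_fragments validates, sorts and handles edge cases", {
  f <- withr::local_tempfile(fileext = ".bed")

  writeLines(character(), f)
  empty <- read_fragments(f, tiny_genome)
  expect_s3_class(empty, "FragmentSet")
  expect_equal(nrow(empty), 0)

  writeLines(c("chrB\t10\t60\tc1", "chrA\t500\t650\tc2", "chrA\t5\t155\tc1"), f)
  fr <- read_fragments(f, tiny_genome)
  expect_equal(nrow(fr), 3)
  expect_equal(fr$chrom, c("chrA", "chrA", "chrB"))
  expect_equal(fr$start, c(5, 500, 10))

  writeLines(c("chrA\t10\t60", "chrA\t100\t100"), f)
  expect_error(read_fragments(f, tiny_genome), "line\\(s\\) 2")

  writeLines("chrZ\t10\t60", f)
  expect_error(read_fragments(f, tiny_genome), "chrZ")

  writeLines("chrA\t990\t1100", f)
  expect_error(read_fragments(f, tiny_genome), "outside")
})

test_that("coverage matches a per-base brute-force oracle", {
  fr <- make_frags("chrA", 0, 10, genome = c(chrA = 100))
  tr <- coverage_track(fr, bin = 1)
  expect_equal(unclass(tr)$chrA, c(rep(1, 10), rep(0, 90)))

  # linearity: duplicated fragment doubles the track
  fr2 <- make_frags(c("chrA", "chrA"), c(0, 0), c(10, 10), genome = c(chrA = 100))
  expect_equal(unclass(coverage_track(fr2, bin = 1))$chrA,
               2 * unclass(tr)$chrA)

  # random instance vs naive loop, per-base and binned
  set.seed(42)
  n <- 50
  chrom <- sample(names(tiny_genome), n, replace = TRUE)
  start <- floor(runif(n) * (tiny_genome[chrom] - 60))
  fr3 <- make_frags(chrom, start, start + sample(10:60, n, replace = TRUE))
  got <- coverage_track(fr3, bin = 1)
  naive <- lapply(names(tiny_genome), function(ch) {
    v <- numeric(tiny_genome[[ch]])
    for (i in which(fr3$chrom == ch)) {
      idx <- (fr3$start[i] + 1):fr3$end[i]
      v[idx] <- v[idx] + 1
    }
    v
  })
  names(naive) <- names(tiny_genome)
  expect_equal(unclass(got)[names(tiny_genome)], naive,
               ignore_attr = TRUE)

  binned <- coverage_track(fr3, bin = 64)
  expect_equal(unclass(binned)$chrA[1], mean(naive$chrA[1:64]))
  # last partial bin of chrB (500 = 7*64 + 52) averages its true width
  expect_equal(unclass(binned)$chrB[8], mean(naive$chrB[449:500]))

  # record order invariance
  perm <- fr3[sample(nrow(fr3)), ]
  expect_equal(coverage_track(fragment_set(perm, tiny_genome), bin = 1), got)
})

test_that("normalize_track maps uniform coverage to one and handles zeros", {
  g <- c(chrA = 1000)
  uni <- make_track(list(chrA = rep(1, 1000)), 1, g, normalization = "raw")
  expect_equal(unclass(normalize_track(uni))$chrA, rep(1, 1000))

  one <- coverage_track(make_frags("chrA", 40, 50, genome = c(chrA = 100)),
                        bin = 1)
  nt <- normalize_track(one)
  expect_equal(unclass(nt)$chrA[41:50], rep(10, 10))  # scale = 100/10
  expect_equal(sum(unclass(nt)$chrA), 100)

  zero <- coverage_track(make_frags(character(), numeric(), numeric(),
                                    genome = g), bin = 1)
  expect_warning(nz <- normalize_track(zero), "all-zero")
  expect_equal(sum(unclass(nz)$chrA), 0)
})

test_that("merge_intervals has bedtools-merge semantics", {
  g <- function(...) data.frame(chrom = "chrA", ...)
  expect_equal(merge_intervals(list(g(start = 0, end = 10),
                                    g(start = 10, end = 20)))$end, 20)
  two <- merge_intervals(list(g(start = c(0, 20), end = c(5, 30))))
  expect_equal(nrow(two), 2)

  # brute-force boolean-mask union oracle on random intervals
  set.seed(7)
  iv <- data.frame(chrom = "chrA",
                   start = sample(0:900, 100, replace = TRUE))
  iv$end <- iv$start + sample(1:80, 100, replace = TRUE)
  merged <- merge_intervals(list(iv))
  mask <- logical(1000)
  for (i in seq_len(nrow(iv))) mask[(iv$start[i] + 1):min(iv$end[i], 1000)] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  expect_equal(merged$start, (ends - r$lengths)[r$values])
  expect_equal(merged$end, ends[r$values])
})

test_that("count_over_intervals double-counts across intervals and matches a scan oracle", {
  iv <- data.frame(chrom = "chrA", start = c(0, 10), end = c(10, 20))
  expect_equal(count_over_intervals(make_frags(character(), numeric(), numeric()), iv),
               c(0L, 0L))
  fr <- make_frags("chrA", 5, 15)
  expect_equal(count_over_intervals(fr, iv), c(1L, 1L))

  set.seed(11)
  n <- 80
  frx <- make_frags("chrA", s <- sample(0:950, n, TRUE), s + sample(1:50, n, TRUE))
  ivx <- data.frame(chrom = "chrA", start = s2 <- sample(0:900, 30, TRUE),
                    end = s2 + sample(1:100, 30, TRUE))
  got <- count_over_intervals(frx, ivx)
  oracle <- vapply(seq_len(nrow(ivx)), function(i)
    sum(frx$start < ivx$end[i] & frx$end > ivx$start[i]), numeric(1))
  expect_equal(as.numeric(got), oracle)
})
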