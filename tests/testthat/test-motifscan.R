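hand_pwm <- function(p = 0.7, w = 2, pseudocount = 0) {
  m <- matrix((1 - p) / 3, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[1, ] <- p
  pwm(m, name = "hand", pseudocount = pseudocount)
}

test_that("score_site closed forms: consensus max, uniform zero, hand PWM", {
  hp <- hand_pwm()
  expect_equal(score_site(hp, "AA"), 2 * log2(0.7 / 0.25))
  expect_equal(score_site(hp, pwm_consensus(hp)), pwm_max_score(hp))

  unif <- pwm(matrix(0.25, 4, 5), pseudocount = 0)
  expect_equal(score_site(unif, "ACGTA"), 0)
  expect_true(is.na(score_site(unif, "ACGTN")))
  expect_error(score_site(unif, "ACG"), "length")
})

test_that("site_pvalue: consensus of a unique-argmax PWM has p = 4^-w", {
  hp <- hand_pwm(p = 0.7, w = 3)
  expect_equal(site_pvalue(hp, pwm_max_score(hp)), 4^-3, tolerance = 1e-9)
  expect_equal(site_pvalue(hp, -1e6), 1)
  expect_equal(site_pvalue(hp, -Inf), 1)
})

all_kmers <- function(w) {
  do.call(expand.grid, rep(list(c("A", "C", "G", "T")), w))
}

test_that("DP p-values match exhaustive enumeration for widths <= 6", {
  set.seed(41)
  for (w in c(3, 4, 6)) {
    counts <- matrix(rexp(4 * w) + 0.1, 4, w)
    p <- pwm(counts, name = sprintf("w%d", w), pseudocount = 0.1)
    kmers <- all_kmers(w)
    scores <- apply(kmers, 1, function(k)
      sum(p$score[cbind(match(k, c("A", "C", "G", "T")), seq_len(w))]))
    bgp <- rep(4^-w, length(scores))
    for (s in sample(unique(scores), 12)) {
      exact <- sum(bgp[scores >= s - 1e-12])
      expect_equal(site_pvalue(p, s), exact, tolerance = 1e-3)
    }
    # monotonicity: higher score, smaller or equal p
    ss <- sort(sample(unique(scores), 10))
    pv <- vapply(ss, function(s) site_pvalue(p, s), numeric(1))
    expect_true(all(diff(pv) <= 1e-15))
  }
})

test_that("scan finds planted sites on both strands and skips N runs", {
  set.seed(43)
  p <- hand_pwm(p = 0.9, w = 6, pseudocount = 0)
  cons <- pwm_consensus(p)  # AAAAAA
  bases <- c("C", "G", "T")  # background without A keeps the site unique
  seqs <- c(fwd = paste0(paste(sample(bases, 30, TRUE), collapse = ""), cons,
                         paste(sample(bases, 20, TRUE), collapse = "")),
            rev = paste0(paste(sample(bases, 10, TRUE), collapse = ""),
                         "TTTTTT",
                         paste(sample(bases, 40, TRUE), collapse = "")))
  hits <- scan_pwm(p, seqs, p_threshold = 1e-3)
  fwd <- hits[hits$sequence == "fwd", ]
  expect_equal(fwd$offset, 30)
  expect_equal(fwd$strand, "+")
  rev <- hits[hits$sequence == "rev", ]
  expect_equal(rev$offset, 10)
  expect_equal(rev$strand, "-")

  expect_equal(nrow(scan_pwm(p, c(n = strrep("N", 50)))), 0)
  expect_equal(nrow(scan_pwm(p, c(short = "ACG"))), 0)
})

test_that("scanning is strand-symmetric", {
  set.seed(44)
  counts <- matrix(rexp(4 * 5) + 0.1, 4, 5)
  p <- pwm(counts, "m")
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_pwm(p, c(x = s), p_threshold = 1e-2)
  h2 <- scan_pwm(p, c(x = rc), p_threshold = 1e-2)
  flip <- data.frame(strand = ifelse(h2$strand == "+", "-", "+"),
                     offset = 300 - 5 - h2$offset, score = h2$score)
  o1 <- h1[order(h1$offset, h1$strand), c("strand", "offset", "score")]
  o2 <- flip[order(flip$offset, flip$strand), ]
  expect_equal(o1$offset, o2$offset)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$score, o2$score)
})

test_that("false-hit counts on random sequence match the exact DP expectation", {
  set.seed(45)
  counts <- matrix(rexp(4 * 8) + 0.1, 4, 8)
  p <- pwm(counts, "rand")
  n_seq <- 300; L <- 200
  seqs <- vapply(seq_len(n_seq), function(i)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("s%03d", seq_len(n_seq))
  thr <- 1e-3
  hits <- scan_pwm(p, seqs, p_threshold = thr)
  # exact per-site pass probability from the DP distribution itself
  dp <- guttag:::.pwm_dp(p)
  sf <- rev(cumsum(rev(dp$probs)))
  pass_prob <- max(sf[sf < thr])
  expected <- 2 * (L - 8 + 1) * pass_prob * n_seq
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected))
})

test_that("motif enrichment: closed-form odds ratio and degenerate cases", {
  hits <- data.frame(sequence = c(sprintf("fg%02d", 1:10), sprintf("bg%02d", 1:5)),
                     motif = "m1")
  fg <- sprintf("fg%02d", 1:20); bg <- sprintf("bg%02d", 1:50)
  enr <- motif_enrichment(hits, fg, bg)
  expect_equal(enr$odds_ratio, 10 * 45 / (10 * 5))
  expect_equal(enr$p, fisher.test(matrix(c(10, 10, 5, 45), 2, byrow = TRUE))$p.value)

  # identical proportions -> p = 1
  h2 <- data.frame(sequence = c("fg01", "bg01"), motif = "m2")
  e2 <- motif_enrichment(h2, c("fg01", "fg02"), c("bg01", "bg02"))
  expect_equal(e2$p, 1)
  expect_error(motif_enrichment(hits, character(), bg), "empty")
})

test_that("MEME round trip preserves motif probabilities", {
  m1 <- matrix(c(0.7, 0.1, 0.1, 0.1), 4, 3)
  m2 <- matrix(c(0.1, 0.2, 0.3, 0.4), 4, 5)
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(alpha = m1, beta = m2), f)
  got <- read_meme(f, pseudocount = 0)
  expect_equal(names(got), c("alpha", "beta"))
  expect_equal(unname(got$alpha$prob), m1, tolerance = 1e-5)
  expect_equal(got$beta$width, 5)
})
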