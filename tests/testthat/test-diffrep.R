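test_that("pseudobulk sums per group and matches a loop oracle", {
  set.seed(31)
  m <- Matrix::Matrix(matrix(rpois(60, 4), 12, 5), sparse = TRUE)
  rownames(m) <- sprintf("c%02d", 1:12)
  cells <- data.frame(barcode = rownames(m),
                      cell_type = rep(c("EC", "EE"), 6),
                      age = rep(c("young", "old"), each = 6),
                      replicate = rep(c("chip1", "chip2"), times = c(5, 7)))
  # some (type, age, chip) combinations are empty: reported, not silent
  expect_warning(pb <- pseudobulk(m, cells), "0 cells")
  meta <- attr(pb, "meta")
  for (i in seq_len(ncol(pb))) {
    sel <- cells$cell_type == meta$cell_type[i] & cells$age == meta$age[i] &
      cells$replicate == meta$replicate[i]
    expect_equal(unname(pb[, i]), unname(Matrix::colSums(m[sel, , drop = FALSE])))
  }
  # order invariance
  perm <- sample(12)
  pb2 <- suppressWarnings(pseudobulk(m[perm, ], cells[perm, ]))
  expect_equal(unclass(pb2)[, colnames(pb)], unclass(pb)[, colnames(pb)])

  # a single cell in a group reproduces that cell's row
  one <- suppressWarnings(pseudobulk(m[1, , drop = FALSE], cells[1, ]))
  expect_equal(unname(one[, 1]), unname(as.numeric(m[1, ])))
})

test_that("cpkm normalizes by length and library, with closed-form checks", {
  counts <- matrix(c(100, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  counts["b", 1] <- 1e6 - 100  # library exactly 1e6
  got <- cpkm(counts, lengths = c(2000, 1000))
  expect_equal(got["a", 1], 50)
  expect_equal(cpkm(counts * 2, lengths = c(2000, 1000))["a", 1], 50)  # depth cancels
  # doubling library at fixed count halves CPKM
  c2 <- counts; c2["b", 1] <- 2e6 - 100
  expect_equal(cpkm(c2, lengths = c(2000, 1000))["a", 1], 25)
  expect_error(cpkm(counts, lengths = c(0, 1000)), "zero-length")
})

test_that("differential: degenerate equality, contrast symmetry, direction rule", {
  # equal library sizes so the flat feature stays flat after normalization
  counts <- matrix(c(10, 10, 10, 10,
                     30, 35, 5, 8,
                     20, 15, 45, 42), 3, 4, byrow = TRUE,
                   dimnames = list(c("flat", "changed", "filler"), NULL))
  cond <- c("A", "A", "B", "B")
  dt <- suppressWarnings(differential(counts, cond, contrast = c("B", "A")))
  expect_equal(dt$log2FC[1], 0)
  expect_equal(dt$p[1], 1)
  expect_lt(dt$log2FC[2], 0)

  rev <- suppressWarnings(differential(counts, cond, contrast = c("A", "B")))
  expect_equal(rev$log2FC, -dt$log2FC)
  expect_equal(rev$p, dt$p)

  expect_true(all(dt$direction[dt$fdr < 0.05 & abs(dt$log2FC) >= 1] != "ns"))
  expect_error(differential(counts[, 1:3], cond[1:3], c("B", "A")),
               ">= 2 replicates")
})

test_that("differential is calibrated on a Poisson null and recovers planted folds", {
  set.seed(33)
  n_feat <- 2000
  lambda <- rexp(n_feat, 1 / 150) + 20
  null_counts <- matrix(rpois(4 * n_feat, rep(lambda, 4)), n_feat, 4)
  # on Poisson data the moment estimate of the common dispersion can be
  # negative; the documented behaviour is a clamp to 0 with a warning
  expect_warning(
    dt <- differential(null_counts, c("A", "A", "B", "B"), c("B", "A")),
    "clamped")
  fpr <- mean(dt$p < 0.05)
  expect_gt(fpr, 0.02)
  expect_lt(fpr, 0.09)

  # planted 4-fold changes at high depth are recovered
  planted <- sample(n_feat, 100)
  alt <- null_counts
  alt[planted, 3:4] <- rpois(200, 4 * lambda[planted])
  da <- suppressWarnings(differential(alt, c("A", "A", "B", "B"), c("B", "A")))
  called <- which(da$fdr < 0.05 & abs(da$log2FC) >= 1)
  expect_gte(mean(planted %in% called), 0.8)
  expect_lte(mean(!(called %in% planted)), 0.1)
})

test_that("BH correction follows the step-up definition on a worked example", {
  # hand step-up: q_i = min_{j >= i} p_(j) * m / j -> all 0.04 here
  counts <- matrix(rpois(40, 20), 10, 4)
  dt <- suppressWarnings(differential(counts, c("A", "A", "B", "B"), c("B", "A")))
  expect_equal(dt$fdr, stats::p.adjust(dt$p, "BH"))
  hand_bh <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / rev(seq_len(m))))[ro]
  }
  expect_equal(hand_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(dt$fdr, hand_bh(dt$p))
})

test_that("zscore_rows standardizes rows and flags constant ones", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1) * 1.224745, tolerance = 1e-6)
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant_rows"), c(b = 2L))
  set.seed(2)
  r <- zscore_rows(matrix(rnorm(50), 5))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(unname(rowMeans(r)), rep(0, 5))
  expect_equal(unname(apply(r, 1, pop_sd)), rep(1, 5))
})

test_that("recovered per-type differential gene counts preserve the planted ordering", {
  run <- default_run()
  tr <- default_synth()$truth
  called <- vapply(c("EC", "EE", "ISC-EB"), function(t) {
    dt <- read_run_tsv(run, sprintf("diff_genes_%s.tsv", t))
    sum(dt$direction != "ns")
  }, numeric(1))
  expect_gt(called[["EC"]], called[["EE"]])
  expect_gte(called[["EE"]], called[["ISC-EB"]])
  # recovered calls are dominated by planted genes
  dt_ec <- read_run_tsv(run, "diff_genes_EC.tsv")
  planted_ec <- tr$diff_genes$gene[tr$diff_genes$type == "EC"]
  expect_gte(mean(dt_ec$feature[dt_ec$direction != "ns"] %in% planted_ec), 0.9)
})
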