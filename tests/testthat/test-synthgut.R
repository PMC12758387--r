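# Small configs keep these tests fast; the default-scale dataset is
# exercised by the recovery tests and the acceptance suite.

small_cfg <- function(...) {
  synth_config(
    cell_counts = rbind(`ISC/EB` = c(young = 6L, mid = 6L, old = 10L),
                        EE = c(young = 5L, mid = 5L, old = 5L),
                        EC = c(young = 12L, mid = 10L, old = 7L)),
    ...)
}

test_that("generation is byte-identical under a fixed seed and differs across seeds", {
  a <- generate_single_cell(small_cfg(seed = 7L))
  b <- generate_single_cell(small_cfg(seed = 7L))
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- generate_single_cell(small_cfg(seed = 8L))
  expect_false(identical(a$fragments, c$fragments))

  b1 <- generate_bulk(small_cfg(seed = 7L), "RNAPIIS5P")
  b2 <- generate_bulk(small_cfg(seed = 7L), "RNAPIIS5P")
  expect_identical(b1, b2)
})

test_that("emitted singlet counts equal the configured counts exactly", {
  cfg <- small_cfg(seed = 2L)
  tr <- generate_single_cell(cfg)$truth
  singlets <- tr$cells[!tr$cells$is_doublet & !tr$cells$is_artifact, ]
  got <- table(singlets$type, singlets$age)
  for (t in rownames(cfg$cell_counts)) for (a in colnames(cfg$cell_counts)) {
    expect_equal(unname(got[t, a]), unname(cfg$cell_counts[t, a]))
  }
  # truth covers every emitted barcode exactly once
  fr <- generate_single_cell(cfg)$fragments
  expect_setequal(unique(fr$label), tr$cells$barcode)
  expect_false(anyDuplicated(tr$cells$barcode) > 0)
})

test_that("snr = 1 with no doublets/artifacts puts every fragment in its cell's domains", {
  cfg <- small_cfg(seed = 3L, snr = 1, doublet_rate = 0, artifact_rate = 0)
  out <- generate_single_cell(cfg)
  tr <- out$truth
  for (bc in sample(tr$cells$barcode, 12)) {
    info <- tr$cells[tr$cells$barcode == bc, ]
    dom <- tr$domain_sets[[info$type]][[info$age]]
    sub <- out$fragments[out$fragments$label == bc, , drop = FALSE]
    # fragment starts are drawn inside the domains; the fixed 150 bp length
    # may only overhang the right edge
    inside <- vapply(seq_len(nrow(sub)), function(i)
      any(dom$chrom == sub$chrom[i] & dom$start <= sub$start[i] &
            sub$start[i] < dom$end), logical(1))
    expect_true(all(inside))
  }
})

test_that("mean in-domain fragment fraction matches the snr mixture law", {
  cfg <- synth_config(seed = 4L)
  out <- generate_single_cell(cfg)
  tr <- out$truth
  singlets <- tr$cells[!tr$cells$is_doublet & !tr$cells$is_artifact, ]
  union_bp <- sum(tr$all_domains$end - tr$all_domains$start)
  dom_frac <- union_bp / sum(cfg$chrom_sizes)
  # expected per-fragment in-domain probability: snr for planted draws plus
  # the chance a uniform background draw overlaps a domain
  expected <- cfg$snr + (1 - cfg$snr) * dom_frac
  ov <- GenomicRanges::findOverlaps(guttag:::.as_gr(out$fragments),
                                    guttag:::.as_gr(tr$all_domains))
  hit_idx <- unique(S4Vectors::queryHits(ov))
  frac_by_cell <- tapply(seq_len(nrow(out$fragments)) %in% hit_idx,
                         out$fragments$label, mean)
  expect_lt(abs(mean(frac_by_cell[singlets$barcode]) - expected), 0.02)
})

test_that("every planted differential gene overlaps a planted domain", {
  tr <- default_synth()$truth
  genes <- tr$genes[match(tr$diff_genes$gene, tr$genes$name), ]
  ov <- GenomicRanges::findOverlaps(guttag:::.as_gr(genes),
                                    guttag:::.as_gr(tr$all_domains))
  expect_equal(sort(unique(S4Vectors::queryHits(ov))), seq_len(nrow(genes)))
  # planted counts follow the enterocyte >> enteroendocrine >> ISC/EB ordering
  counts <- table(tr$diff_genes$type)
  expect_gt(counts[["EC"]], counts[["EE"]])
  expect_gt(counts[["EE"]], counts[["ISC/EB"]])
})

test_that("a config with an empty domain set for any type is rejected", {
  expect_error(small_cfg(shared_domains = 0L,
                         type_domains = c(`ISC/EB` = 0L, EE = 2L, EC = 2L)),
               "empty domain set.*ISC/EB")
  expect_error(small_cfg(snr = 1.2), "snr")
  expect_error(small_cfg(doublet_rate = 1), "doublet_rate")
})

test_that("IgG bulk counts are Poisson-dispersed in 10 kb bins", {
  cfg <- synth_config(seed = 5L)
  igg <- generate_bulk(cfg, "IgG")
  bins <- do.call(rbind, lapply(names(cfg$chrom_sizes), function(ch)
    data.frame(chrom = ch, start = seq(0, cfg$chrom_sizes[[ch]] - 1e4, 1e4))))
  bins$end <- bins$start + 1e4
  counts <- count_over_intervals(igg[[1]], bins)
  dispersion <- var(counts) / mean(counts)
  expect_gt(dispersion, 0.8)
  expect_lt(dispersion, 1.2)
})

test_that("histone_fold = 1 leaves old and mid histone promoters exchangeable", {
  cfg <- synth_config(seed = 6L, histone_fold = 1)
  bulk <- generate_bulk(cfg, "RNAPIIS5P")
  tr <- generate_single_cell(cfg)$truth
  prom <- tr$promoters
  counts <- promoter_counts(bulk, prom)
  merged <- merge_replicates(counts, sub("_rep\\d+$", "", colnames(counts)))
  his <- prom$class != "gene"
  p <- poisson_rate_test(merged[his, "mid"], sum(merged[, "mid"]),
                         merged[his, "old"], sum(merged[, "old"]))
  expect_lt(mean(p < 0.05), 0.15)
  expect_gt(mean(p), 0.3)
})

test_that("histone_fold = 10 concentrates the old/mid His2A/His2B ratio near 10", {
  cfg <- synth_config(seed = 7L)
  bulk <- generate_bulk(cfg, "RNAPIIS5P")
  tr <- generate_single_cell(cfg)$truth
  counts <- promoter_counts(bulk, tr$promoters)
  merged <- merge_replicates(counts, sub("_rep\\d+$", "", colnames(counts)))
  sel <- tr$promoters$class %in% c("His2A", "His2B")
  ratio <- merged[sel, "old"] / merged[sel, "mid"]
  expect_true(all(ratio >= 6 & ratio <= 14))
})
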