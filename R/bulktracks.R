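# Bulk-profile analysis: promoter count tables, replicate agreement,
# Pc-vs-IgG promoter scoring with quartile ranking, the
# difference-versus-average hypertranscription statistic, and an exact
# Poisson rate test (conditional binomial).

#' Build a promoter count table from bulk replicates
#'
#' @param frag_list Named list of FragmentSets (e.g. from
#'   [generate_bulk()]), one per replicate.
#' @param promoters Promoter interval data.frame with a `name` column.
#' @return `PromoterCountTable`: promoters x samples matrix, with the
#'   replicate metadata (if present on `frag_list`) in attribute `meta`.
#' @export
promoter_counts <- function(frag_list, promoters) {
  counts <- vapply(frag_list, function(f) count_over_intervals(f, promoters),
                   numeric(nrow(promoters)))
  rownames(counts) <- promoters$name
  structure(counts, meta = attr(frag_list, "meta"),
            promoters = promoters,
            class = c("PromoterCountTable", class(counts)))
}

#' CPM normalization (counts per million)
#'
#' @param counts Features x samples matrix.
#' @param library_sizes Per-sample totals (default: column sums).
#' @return CPM matrix.
#' @export
cpm <- function(counts, library_sizes = colSums(counts)) {
  if (any(library_sizes <= 0)) stop("zero library size")
  counts * rep(1e6 / library_sizes, each = nrow(counts))
}

#' Pairwise replicate Pearson correlation
#'
#' Pearson r on `log2(CPM + 1)` promoter vectors for every replicate pair.
#' The `merge_ok` attribute records whether the minimum pairwise r clears
#' the merge threshold.
#'
#' @param counts Promoters x replicates count matrix (>= 2 columns).
#' @param threshold Minimum pairwise r permitting replicate merging
#'   (default 0.8).
#' @return Correlation matrix; pairs with a constant vector are NA and
#'   reported with a warning.
#' @export
replicate_correlation <- function(counts, threshold = 0.8) {
  if (ncol(counts) < 2) stop("need >= 2 replicates")
  lv <- base::log2(cpm(counts) + 1)
  constant <- apply(lv, 2, stats::sd) == 0
  if (any(constant)) {
    warning("constant replicate vector(s): ",
            paste(colnames(counts)[constant], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(lv))
  off <- r[upper.tri(r)]
  merge_ok <- if (all(is.na(off))) NA else min(off, na.rm = TRUE) >= threshold
  structure(r, merge_ok = merge_ok, threshold = threshold)
}

#' Merge replicate columns by summing counts
#' @param counts Promoters x samples matrix.
#' @param groups Factor/character grouping the columns (e.g. age).
#' @return Promoters x groups matrix of summed counts.
#' @export
merge_replicates <- function(counts, groups) {
  lev <- unique(groups)
  out <- vapply(lev, function(g)
    rowSums(counts[, groups == g, drop = FALSE]), numeric(nrow(counts)))
  colnames(out) <- lev
  out
}

#' Difference-versus-average (MA) hypertranscription table
#'
#' Per promoter, on the CPM scale by default: `D = count_B - count_A` and
#' `A = log10((count_B + count_A) / 2)`, ranked by descending D. Promoters
#' with zero counts in both ages are flagged and excluded from ranking.
#'
#' @param merged Promoters x ages matrix of merged counts.
#' @param ageA Reference age column (e.g. "mid" for an old-vs-mid
#'   comparison).
#' @param ageB Contrast age column (e.g. "old").
#' @param normalized Use CPM (default TRUE); FALSE uses raw merged counts.
#' @return `MaTable` data.frame: promoter, count_A, count_B, D, A, rank
#'   (NA for flagged rows).
#' @export
ma_stat <- function(merged, ageA, ageB, normalized = TRUE) {
  stopifnot(all(c(ageA, ageB) %in% colnames(merged)))
  m <- if (normalized) cpm(merged) else merged
  a <- m[, ageA]; b <- m[, ageB]
  flagged <- a + b == 0
  D <- b - a
  A <- base::log10((a + b) / 2)
  A[flagged] <- NA
  rank <- rep(NA_integer_, length(D))
  rank[!flagged] <- rank(-D[!flagged], ties.method = "first")
  out <- data.frame(promoter = rownames(merged) %||% seq_along(D),
                    count_A = a, count_B = b, D = D, A = A,
                    flagged = flagged, rank = rank, row.names = NULL)
  class(out) <- c("MaTable", "data.frame")
  out
}

#' Exact Poisson rate test (conditional binomial)
#'
#' Tests equality of the rates of two Poisson counts `k1`, `k2` observed
#' at exposures `N1`, `N2`. Conditional on `k1 + k2`, `k2` is
#' `Binomial(k1 + k2, N2 / (N1 + N2))` under the null; the two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one (minimum-likelihood method). Vectorized over counts.
#'
#' @param k1,k2 Observed counts.
#' @param N1,N2 Library sizes / exposures.
#' @return Two-sided p-value(s); `k1 + k2 = 0` gives p = 1 by convention.
#' @export
poisson_rate_test <- function(k1, N1, k2, N2) {
  n <- k1 + k2
  pr <- N2 / (N1 + N2)
  mapply(function(ni, ki, pi) {
    if (ni == 0) return(1)
    probs <- stats::dbinom(0:ni, ni, pi)
    obs <- probs[ki + 1]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, n, k2, pr)
}

#' Mean normalized track value over intervals
#'
#' @param track Genome-normalized CoverageTrack (bin 1 recommended).
#' @param intervals Interval data.frame.
#' @return Per-interval mean value.
#' @export
track_score_intervals <- function(track, intervals) {
  genome <- attr(track, "genome")
  validate_intervals(intervals, genome, what = "intervals")
  bin <- attr(track, "bin")
  vapply(seq_len(nrow(intervals)), function(i) {
    v <- unclass(track)[[intervals$chrom[i]]]
    if (bin == 1) {
      mean(v[(intervals$start[i] + 1):intervals$end[i]])
    } else {
      # weighted mean over the bins the interval touches
      b0 <- floor(intervals$start[i] / bin) + 1
      b1 <- ceiling(intervals$end[i] / bin)
      bs <- (seq(b0, b1) - 1) * bin
      cover <- pmin(bs + bin, intervals$end[i]) - pmax(bs, intervals$start[i])
      sum(v[b0:b1] * cover) / sum(cover)
    }
  }, numeric(1))
}

#' Quartile ranking of promoter scores
#'
#' Descending-order quartiles (1 = top). Ties share the better quartile.
#'
#' @param scores Numeric scores (e.g. Pc promoter signal) for the chosen
#'   universe of promoters.
#' @return Integer quartile labels in 1..4.
#' @export
quartile_rank <- function(scores) {
  stopifnot(length(scores) > 0)
  r <- rank(-scores, ties.method = "min")
  as.integer(ceiling(r * 4 / length(scores)))
}
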