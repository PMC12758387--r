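# Cell-type composition per age and Monte Carlo permutation testing of
# composition shifts (e.g. the growth of the ISC/EB share with age).

#' Cross-tabulate cell-type composition per age
#'
#' @param cells CellTable of typed, QC-passing cells (rows with missing
#'   type or age are dropped).
#' @return `CompositionTable` data.frame: age, cell_type, n, proportion
#'   (summing to 1 within each age). Ages with zero cells are omitted with
#'   a warning.
#' @export
composition <- function(cells) {
  keep <- !is.na(cells$cell_type) & !is.na(cells$age)
  cells <- cells[keep, , drop = FALSE]
  ages <- unique(cells$age)
  if (!length(ages)) stop("no typed, aged cells")
  tab <- table(cells$age, cells$cell_type)
  empty <- rownames(tab)[rowSums(tab) == 0]
  if (length(empty)) warning("age(s) with zero cells omitted: ",
                             paste(empty, collapse = ", "))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("age", "cell_type", "n")
  out <- out[!out$age %in% empty, ]
  totals <- tapply(out$n, out$age, sum)
  out$proportion <- out$n / as.numeric(totals[out$age])
  rownames(out) <- NULL
  class(out) <- c("CompositionTable", "data.frame")
  out
}

#' Monte Carlo permutation test of a composition shift
#'
#' Statistic: `proportion(focal_type, ageB) - proportion(focal_type,
#' ageA)`. The null is built by shuffling age labels among the pooled
#' cells `n_perm` times; the two-sided p-value uses the add-one estimator
#' `p = (1 + #(|stat_perm| >= |stat_obs|)) / (1 + n_perm)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param cells CellTable with cell_type and age.
#' @param focal_type Cell type whose proportion shift is tested.
#' @param ageA,ageB The two ages compared.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed RNG seed.
#' @param statistic `"proportion_diff"` (default) or `"chisq"` (chi-square
#'   statistic over the full age x type table).
#' @return List with `statistic`, `p`, `n_perm`.
#' @export
permutation_test <- function(cells, focal_type, ageA, ageB, n_perm = 10000,
                             seed = 1L, statistic = c("proportion_diff", "chisq")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1")
  keep <- !is.na(cells$cell_type) & cells$age %in% c(ageA, ageB)
  cells <- cells[keep, , drop = FALSE]
  if (!all(c(ageA, ageB) %in% cells$age)) stop("both ages must be present")
  age <- cells$age
  focal <- cells$cell_type == focal_type
  nA <- sum(age == ageA); nB <- sum(age == ageB)
  stat_fun <- if (statistic == "proportion_diff") {
    function(is_B) sum(focal & is_B) / nB - sum(focal & !is_B) / nA
  } else {
    function(is_B) {
      tab <- table(ifelse(is_B, ageB, ageA), cells$cell_type)
      suppressWarnings(stats::chisq.test(tab)$statistic)
    }
  }
  obs <- stat_fun(age == ageB)
  set.seed(seed)
  n <- length(age)
  if (statistic == "proportion_diff") {
    # shuffling labels only moves focal cells between the two age groups,
    # so each permutation reduces to the focal count landing in ageB
    nf <- sum(focal)
    xB <- vapply(seq_len(n_perm),
                 function(i) sum(focal[sample.int(n, nB)]), numeric(1))
    perm_stats <- xB / nB - (nf - xB) / nA
    exceed <- sum(abs(perm_stats) >= abs(obs) - 1e-12)
  } else {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      perm_B <- logical(n)
      perm_B[sample.int(n, nB)] <- TRUE
      if (abs(stat_fun(perm_B)) >= abs(obs) - 1e-12) exceed <- exceed + 1L
    }
  }
  list(statistic = unname(obs), p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}
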