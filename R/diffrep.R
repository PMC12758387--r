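# Pseudobulk differential analysis of repressive signal. Counts are summed
# per (cell type, age, replicate chip), library-size normalized over the
# feature universe, and tested feature-by-feature with a negative-binomial
# Wald test using one common dispersion estimated by method of moments
# across all features' replicate variability.

#' Pseudobulk a cell x feature count matrix
#'
#' @param matrix Cells x features counts (rows named by barcode).
#' @param cells CellTable with barcode, cell_type, age and replicate
#'   columns (replicate = source chip).
#' @param group_by Metadata columns defining the pseudobulk groups.
#' @return `PseudobulkCounts`: features x samples integer matrix with a
#'   `meta` attribute (one row per sample). Groups with zero cells are
#'   omitted with a warning.
#' @export
pseudobulk <- function(matrix, cells, group_by = c("cell_type", "age", "replicate")) {
  stopifnot(all(group_by %in% names(cells)))
  idx <- match(cells$barcode, rownames(matrix))
  if (anyNA(idx)) stop("cells missing from the count matrix")
  key <- interaction(cells[group_by], drop = FALSE, sep = ".")
  empty <- setdiff(levels(key), unique(as.character(key)))
  if (length(empty)) {
    warning("group(s) with 0 cells omitted: ", paste(empty, collapse = ", "))
  }
  lev <- intersect(levels(key), unique(as.character(key)))
  counts <- vapply(lev, function(l)
    Matrix::colSums(matrix[idx[key == l], , drop = FALSE]),
    numeric(ncol(matrix)))
  meta <- unique(cells[group_by])
  meta <- meta[match(lev, do.call(paste, c(meta, sep = "."))), , drop = FALSE]
  rownames(meta) <- NULL
  structure(counts, meta = cbind(sample = lev, meta),
            class = c("PseudobulkCounts", class(counts)))
}

#' CPKM normalization (counts per kilobase per million)
#'
#' @param counts Features x samples count matrix.
#' @param lengths Feature lengths in bp.
#' @param log2 Return `log2(CPKM + 1)` (heatmap variant).
#' @return Normalized matrix.
#' @export
cpkm <- function(counts, lengths, log2 = FALSE) {
  if (any(lengths <= 0)) stop("zero-length feature")
  lib <- colSums(counts)
  out <- counts / (lengths / 1000) / rep(lib / 1e6, each = nrow(counts))
  if (log2) out <- base::log2(out + 1)
  out
}

# common NB dispersion phi (var = mu + phi mu^2) by method of moments:
# regression through the origin of (s^2 - mu) on mu^2 over all
# feature x condition cells with >= 2 replicates
.common_dispersion <- function(norm_counts, condition) {
  lev <- unique(condition)
  num <- 0; den <- 0
  for (l in lev) {
    sub <- norm_counts[, condition == l, drop = FALSE]
    if (ncol(sub) < 2) next
    mu <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    num <- num + sum((v - mu) * mu^2)
    den <- den + sum(mu^4)
  }
  if (den == 0) return(0)
  phi <- num / den
  if (phi < 0) {
    warning("common dispersion estimate < 0; clamped to 0 (Poisson)")
    phi <- 0
  }
  phi
}

#' Differential test between two conditions
#'
#' Library sizes are equalized by total counts over the feature universe;
#' a single common NB dispersion is estimated by method of moments across
#' all features; each feature gets a Wald test on the log fold change with
#' `Var(log mean) = (1/mu + phi) / n_reps`; BH correction across features.
#'
#' @param counts PseudobulkCounts (or plain features x samples matrix).
#' @param condition Factor/character of length ncol(counts) giving each
#'   sample's condition.
#' @param contrast Length-2 character: `c(conditionB, conditionA)`; the
#'   log2 fold change is B over A (B = contrast condition, A = reference).
#' @param alpha FDR threshold for calling direction (default 0.05).
#' @param lfc_min Minimum |log2FC| for calling direction (default 1).
#' @param lengths Optional feature lengths for the mean-CPKM columns.
#' @return `DifferentialTable` data.frame: feature, log2FC, p, fdr,
#'   direction (gain/loss/ns), normalized means per condition.
#' @export
differential <- function(counts, condition, contrast, alpha = 0.05,
                         lfc_min = 1, lengths = NULL) {
  stopifnot(length(contrast) == 2, all(contrast %in% condition))
  nB <- sum(condition == contrast[1]); nA <- sum(condition == contrast[2])
  if (nA < 2 || nB < 2) stop("need >= 2 replicates per condition")
  cmat <- unclass(counts)
  lib <- colSums(cmat)
  norm <- cmat / rep(lib / mean(lib), each = nrow(cmat))
  use <- condition %in% contrast
  phi <- .common_dispersion(norm[, use, drop = FALSE], condition[use])

  muA <- rowMeans(norm[, condition == contrast[2], drop = FALSE])
  muB <- rowMeans(norm[, condition == contrast[1], drop = FALSE])
  eps <- 0.5
  lfc <- base::log2((muB + eps) / (muA + eps))
  se2 <- (1 / (muA + eps) + phi) / nA + (1 / (muB + eps) + phi) / nB
  z <- (log(muB + eps) - log(muA + eps)) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  p[muA + muB == 0] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(fdr < alpha & abs(lfc) >= lfc_min,
                      ifelse(lfc > 0, "gain", "loss"), "ns")
  out <- data.frame(feature = rownames(cmat) %||% seq_len(nrow(cmat)),
                    log2FC = lfc, p = p, fdr = fdr, direction = direction,
                    mean_A = muA, mean_B = muB, row.names = NULL)
  if (!is.null(lengths)) {
    cp <- cpkm(cmat, lengths)
    out$cpkm_A <- rowMeans(cp[, condition == contrast[2], drop = FALSE])
    out$cpkm_B <- rowMeans(cp[, condition == contrast[1], drop = FALSE])
  }
  attr(out, "dispersion") <- phi
  class(out) <- c("DifferentialTable", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row z-score a matrix
#'
#' Per row: subtract the mean, divide by the population standard deviation
#' (denominator n), so every non-constant output row has mean 0 and SD
#' exactly 1. Constant rows map to all zeros and are flagged in the
#' `constant_rows` attribute.
#'
#' @param m Numeric matrix with >= 2 columns.
#' @return Z-scored matrix.
#' @export
zscore_rows <- function(m) {
  stopifnot(ncol(m) >= 2)
  mu <- rowMeans(m)
  sd <- sqrt(rowMeans((m - mu)^2))
  constant <- sd == 0
  sd[constant] <- 1
  out <- (m - mu) / sd
  structure(out, constant_rows = which(constant))
}
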