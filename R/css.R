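# Chromatin silencing scores: a gene-level, distance-weighted,
# depth-normalized aggregate of repressive-mark fragments. For H3K27me3 a
# high score means the gene sits in dense repressive signal ("repressed");
# a low score means the gene is free of it and potentially expressed, which
# is what makes marker-based cell typing work on a repressive mark.

#' CSS configuration
#'
#' @param tile Tile width in bp (default 500). Fragments are assigned to
#'   one tile by their midpoint.
#' @param window Window upstream/downstream of the gene span (default
#'   50,000 bp).
#' @param tau Exponential decay length in bp (default 5,000): a tile whose
#'   midpoint is `d` bp from the gene span gets weight `exp(-d / tau)`,
#'   with `d = 0` inside the span.
#' @param depth_scale Per-cell depth normalization target (default 10,000).
#' @return A `CssConfig` list.
#' @export
css_config <- function(tile = 500, window = 50000, tau = 5000,
                       depth_scale = 10000) {
  stopifnot(tile > 0, window >= tile, tau > 0, depth_scale > 0)
  structure(list(tile = tile, window = window, tau = tau,
                 depth_scale = depth_scale), class = "CssConfig")
}

#' Compute the chromatin silencing score matrix
#'
#' For each gene, tiles covering `[start - window, end + window)` are
#' weighted by `exp(-d / tau)` where `d` is the distance from the tile
#' midpoint to the nearest point of the gene span. The raw score of a cell
#' for a gene is the weighted sum of its fragment-midpoint counts over
#' those tiles; the CSS is the raw score times `depth_scale` divided by the
#' cell's total fragment count.
#'
#' @param frags Barcoded FragmentSet.
#' @param genes Gene interval data.frame with name and strand.
#' @param cfg [css_config()].
#' @param barcodes Row order (default all labels).
#' @return `CssMatrix`: cells x genes dense-ish Matrix, high = repressed.
#' @export
css_scores <- function(frags, genes, cfg = css_config(),
                       barcodes = sort(unique(frags$label))) {
  stopifnot(inherits(cfg, "CssConfig"))
  genome <- genome_of(frags)
  tile <- cfg$tile
  # global tile indexing across chromosomes
  n_tiles <- ceiling(genome / tile)
  offset <- stats::setNames(cumsum(c(0, n_tiles[-length(n_tiles)])), names(genome))
  total_tiles <- sum(n_tiles)

  mid <- floor((frags$start + frags$end) / 2)
  tile_idx <- offset[frags$chrom] + floor(mid / tile) + 1L
  cell_idx <- match(frags$label, barcodes)
  keep <- !is.na(cell_idx)
  cell_tile <- Matrix::sparseMatrix(i = cell_idx[keep], j = tile_idx[keep], x = 1,
                                    dims = c(length(barcodes), total_tiles))

  # gene x tile weight matrix
  wlist <- lapply(seq_len(nrow(genes)), function(g) {
    chrom <- genes$chrom[g]
    lo <- max(0, genes$start[g] - cfg$window)
    hi <- min(genome[[chrom]], genes$end[g] + cfg$window)
    t0 <- floor(lo / tile); t1 <- min(ceiling(hi / tile) - 1, n_tiles[[chrom]] - 1)
    tl <- t0:t1
    tm <- tl * tile + tile / 2
    d <- pmax(0, genes$start[g] - tm, tm - (genes$end[g] - 1))
    list(j = offset[[chrom]] + tl + 1L, w = exp(-d / cfg$tau))
  })
  gene_tile <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(genes)), vapply(wlist, function(x) length(x$j), integer(1))),
    j = unlist(lapply(wlist, `[[`, "j")),
    x = unlist(lapply(wlist, `[[`, "w")),
    dims = c(nrow(genes), total_tiles))

  depth <- table(factor(frags$label, levels = barcodes))
  depth <- pmax(as.numeric(depth), 1)
  raw <- as.matrix(Matrix::tcrossprod(cell_tile, gene_tile))
  css <- raw * (cfg$depth_scale / depth)
  dimnames(css) <- list(barcodes, genes$name)
  structure(css, orientation = "high_is_repressed")
}

#' Aggregate CSS per cluster
#'
#' Cluster-level CSS is the mean over member cells of per-cell CSS.
#'
#' @param css CssMatrix (cells x genes).
#' @param clusters Cluster labels in row order of `css`.
#' @return clusters x genes matrix of mean CSS.
#' @export
css_by_cluster <- function(css, clusters) {
  lev <- sort(unique(clusters))
  out <- t(vapply(lev, function(cl)
    Matrix::colMeans(css[clusters == cl, , drop = FALSE]),
    numeric(ncol(css))))
  rownames(out) <- as.character(lev)
  out
}

#' Assign cell types to clusters from marker-gene CSS
#'
#' Each marker gene's cluster-mean CSS is z-scored across clusters; a
#' cluster receives the type whose marker z-score is most negative there
#' (low CSS = unrepressed = expressed marker). Ties are broken by raw CSS.
#' If all marker z-scores are zero in a cluster the assignment is flagged
#' ambiguous.
#'
#' @param cluster_css clusters x genes matrix from [css_by_cluster()].
#' @param markers Named character vector: type -> marker gene.
#' @return data.frame with cluster, cell_type, ambiguous flag and the
#'   marker z-score matrix in attribute `z`.
#' @export
assign_types <- function(cluster_css, markers) {
  missing <- setdiff(unname(markers), colnames(cluster_css))
  if (length(missing)) {
    stop("marker gene(s) absent from annotation: ", paste(missing, collapse = ", "))
  }
  m <- cluster_css[, unname(markers), drop = FALSE]
  z <- scale(m)
  z[is.nan(z)] <- 0
  types <- names(markers)
  assign <- vapply(seq_len(nrow(m)), function(i) {
    zi <- z[i, ]
    best <- which(zi == min(zi))
    if (length(best) > 1) best <- best[which.min(m[i, best])]
    types[best]
  }, character(1))
  data.frame(cluster = rownames(cluster_css),
             cell_type = assign,
             ambiguous = apply(z, 1, function(zi) all(zi == 0)),
             row.names = NULL) |>
    structure(z = z)
}
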