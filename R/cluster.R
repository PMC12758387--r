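# Cell x domain counting, TF-IDF/LSI embedding, SNN-Leiden clustering and
# UMAP. LSI follows the standard scATAC/CUT&Tag recipe: term frequency =
# count / cell depth, inverse document frequency = log(1 + n_cells /
# (1 + feature cell count)), truncated SVD of TF*IDF, with components that
# track sequencing depth (|r| > 0.9 against log depth) dropped.

#' Build the cell x domain count matrix
#'
#' @param frags Barcoded FragmentSet.
#' @param features Interval data.frame (typically merged cross-age
#'   domains).
#' @param barcodes Cell barcodes defining row order (default: all labels).
#' @return Sparse `dgCMatrix` of fragment counts, rows = cells, columns =
#'   features (named `chrom:start-end`).
#' @export
feature_matrix <- function(frags, features, barcodes = sort(unique(frags$label))) {
  hits <- GenomicRanges::findOverlaps(.as_gr(frags), .as_gr(features))
  cell <- match(frags$label[S4Vectors::queryHits(hits)], barcodes)
  keep <- !is.na(cell)
  m <- Matrix::sparseMatrix(
    i = cell[keep],
    j = S4Vectors::subjectHits(hits)[keep],
    x = 1,
    dims = c(length(barcodes), nrow(features)),
    dimnames = list(barcodes,
                    sprintf("%s:%d-%d", features$chrom,
                            as.integer(features$start), as.integer(features$end)))
  )
  methods::as(m, "CsparseMatrix")
}

.tfidf <- function(matrix, idf = NULL) {
  depth <- Matrix::rowSums(matrix)
  depth[depth == 0] <- 1
  tf <- matrix / depth
  if (is.null(idf)) {
    idf <- log(1 + nrow(matrix) / (1 + Matrix::colSums(matrix > 0)))
  }
  list(x = tf %*% Matrix::Diagonal(x = idf), idf = idf)
}

#' LSI embedding of a cell x feature count matrix
#'
#' @param matrix Sparse count matrix (cells x features).
#' @param d Number of singular components (default 30).
#' @param depth_cor_max Components whose absolute Pearson correlation with
#'   log depth exceeds this are dropped (default 0.9) and reported in the
#'   `dropped` attribute.
#' @param seed RNG seed for the truncated SVD.
#' @return An `LsiEmbedding`: list with `coords` (cells x kept components),
#'   `v` (feature loadings), `idf`, `dropped`, `singular_values`.
#' @export
lsi_embed <- function(matrix, d = 30, depth_cor_max = 0.9, seed = 1L) {
  if (!nrow(matrix) || !ncol(matrix) || sum(matrix) == 0) stop("empty matrix")
  d <- min(d, nrow(matrix) - 1L, ncol(matrix))
  tf <- .tfidf(matrix)
  x <- tf$x
  set.seed(seed)
  if (d >= min(dim(x)) / 2) {
    s <- svd(as.matrix(x))
    s$u <- s$u[, seq_len(d), drop = FALSE]
    s$v <- s$v[, seq_len(d), drop = FALSE]
    s$d <- s$d[seq_len(d)]
  } else {
    s <- irlba::irlba(x, nv = d)
  }
  coords <- s$u %*% diag(s$d, nrow = d)
  logd <- log(Matrix::rowSums(matrix) + 1)
  cors <- suppressWarnings(apply(coords, 2, function(cc)
    if (stats::sd(cc) == 0) 0 else stats::cor(cc, logd)))
  cors[is.na(cors)] <- 0
  drop <- which(abs(cors) > depth_cor_max)
  keep <- setdiff(seq_len(d), drop)
  structure(list(coords = coords[, keep, drop = FALSE],
                 v = s$v, idf = tf$idf, singular_values = s$d,
                 kept = keep, dropped = drop, depth_cor = cors),
            class = "LsiEmbedding")
}

#' Project new count rows into a fitted LSI space
#' @param embedder LsiEmbedding from [lsi_embed()].
#' @param matrix New cells x features counts (same feature set).
#' @return Coordinates in the kept components.
#' @export
lsi_project <- function(embedder, matrix) {
  x <- .tfidf(matrix, idf = embedder$idf)$x
  as.matrix(x %*% embedder$v)[, embedder$kept, drop = FALSE]
}

# k nearest neighbours of `query` rows among `ref` rows, cosine distance,
# computed in blocks; returns index matrix (n_query x k) into ref rows
.knn_cosine <- function(query, ref, k) {
  qn <- query / sqrt(pmax(rowSums(query^2), 1e-12))
  rn <- ref / sqrt(pmax(rowSums(ref^2), 1e-12))
  n <- nrow(qn)
  out <- matrix(0L, n, k)
  block <- max(1L, floor(2e7 / nrow(rn)))
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    sim <- tcrossprod(qn[s:e, , drop = FALSE], rn)
    out[s:e, ] <- t(apply(sim, 1, function(v)
      order(v, decreasing = TRUE)[seq_len(k)]))
  }
  out
}

#' Shared-nearest-neighbour Leiden clustering
#'
#' Builds a kNN graph (cosine distance) on the embedding, reweights edges
#' by the Jaccard overlap of the endpoints' neighbourhoods, and partitions
#' the graph with the Leiden algorithm under the modularity objective.
#'
#' @param embedding LsiEmbedding or a plain coordinate matrix.
#' @param k Neighbours for the kNN graph (default 20).
#' @param resolution Leiden resolution (default 0.8).
#' @param seed RNG seed (labels are stable under a fixed seed).
#' @return Integer cluster labels (1 = largest cluster).
#' @export
snn_cluster <- function(embedding, k = 20, resolution = 0.8, seed = 1L) {
  coords <- if (inherits(embedding, "LsiEmbedding")) embedding$coords else embedding
  n <- nrow(coords)
  if (n <= k) stop("n_cells <= k; choose a smaller k")
  nn <- .knn_cosine(coords, coords, k + 1L)[, -1L, drop = FALSE]
  # SNN Jaccard weights on the union of directed kNN edges
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  edges <- Matrix::which(adj + Matrix::t(adj) > 0, arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  sh <- shared[edges]
  w <- sh / (2 * k - sh)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(comm)[as.character(seq_len(n))]
  # relabel by decreasing size for stable, readable labels
  sizes <- sort(table(memb), decreasing = TRUE)
  as.integer(factor(memb, levels = names(sizes)))
}

#' UMAP embedding for visualization
#'
#' Two-dimensional layout of the LSI space; plotting only, nothing
#' downstream depends on it.
#'
#' @param embedding LsiEmbedding or coordinate matrix.
#' @param seed RNG seed (deterministic under a fixed seed).
#' @param n_neighbors UMAP neighbourhood size.
#' @return n_cells x 2 coordinate matrix.
#' @export
umap_embed <- function(embedding, seed = 1L, n_neighbors = 15) {
  coords <- if (inherits(embedding, "LsiEmbedding")) embedding$coords else embedding
  set.seed(seed)
  uwot::umap(coords, n_neighbors = n_neighbors, metric = "cosine",
             n_threads = 1, n_sgd_threads = 1, batch = TRUE)
}

#' Adjusted Rand Index between two label vectors
#'
#' Hubert-Arabie adjusted-for-chance agreement between two partitions;
#' used to compare recovered clusters with planted labels.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
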