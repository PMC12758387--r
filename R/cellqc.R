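# Per-cell quality control. Metrics follow the standard single-cell
# CUT&Tag triage: total fragments, fraction of fragments in called domains
# (FRiP), fraction in the blacklist; then synthetic-doublet scoring on the
# survivors in LSI space.

#' Compute per-cell QC metrics
#'
#' @param frags Barcoded FragmentSet.
#' @param domains DomainSet (the merged cross-age set, i.e. the same peak
#'   universe used for the cell x domain matrix).
#' @param blacklist Blacklist interval data.frame.
#' @return A `CellTable` data.frame: barcode, n_fragments, frip,
#'   blacklist_fraction, plus placeholder columns (doublet_score, pass_qc,
#'   age, cluster, cell_type) filled by later stages.
#' @export
qc_metrics <- function(frags, domains, blacklist) {
  if (all(is.na(frags$label))) stop("fragments carry no barcodes")
  barcodes <- sort(unique(frags$label))
  n_frag <- table(factor(frags$label, levels = barcodes))
  in_dom <- table(factor(frags$label[.frags_overlapping(frags, domains)],
                         levels = barcodes))
  in_bl <- table(factor(frags$label[.frags_overlapping(frags, blacklist)],
                        levels = barcodes))
  out <- data.frame(
    barcode = barcodes,
    n_fragments = as.integer(n_frag),
    frip = as.numeric(in_dom) / as.integer(n_frag),
    blacklist_fraction = as.numeric(in_bl) / as.integer(n_frag),
    doublet_score = NA_real_,
    pass_qc = NA,
    age = NA_character_,
    cluster = NA_character_,
    cell_type = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("CellTable", "data.frame")
  out
}

#' Apply the hard QC filters
#'
#' `pass_qc` is the conjunction of: at least `min_frags` fragments, FRiP at
#' least `min_frip` (inclusive), blacklist fraction at most `max_bl`
#' (inclusive), and -- when doublet scores have been computed and flagged --
#' not a doublet. Idempotent.
#'
#' @param cells CellTable from [qc_metrics()].
#' @param min_frags Minimum fragments per cell (default 100).
#' @param min_frip Minimum fraction of fragments in domains (default 0.7).
#' @param max_bl Maximum blacklist fraction (default 0.2).
#' @return CellTable with `pass_qc` set.
#' @export
apply_filters <- function(cells, min_frags = 100, min_frip = 0.7, max_bl = 0.2) {
  doublet <- if ("is_doublet_call" %in% names(cells)) {
    !is.na(cells$is_doublet_call) & cells$is_doublet_call
  } else FALSE
  cells$pass_qc <- cells$n_fragments >= min_frags &
    cells$frip >= min_frip &
    cells$blacklist_fraction <= max_bl &
    !doublet
  cells
}

#' Score cells for doublets by synthetic-doublet kNN enrichment
#'
#' Synthesizes `n_synth` in-silico doublets by summing the feature count
#' vectors of random cell pairs, projects observed cells and synthetic
#' doublets into the fitted LSI space, and scores each observed cell by the
#' number of synthetic doublets among its `k` nearest neighbours divided by
#' the expected count `k * n_synth / (n_synth + n_cells)`. Cells whose
#' score falls in the top `flag_fraction` are flagged as doublets.
#'
#' @param matrix Cell x feature count matrix (rows = QC-passing cells).
#' @param embedder Fitted LSI model from [lsi_embed()] on the same matrix.
#' @param n_synth Number of synthetic doublets (default 5 per cell).
#' @param k Neighbours (default 10).
#' @param flag_fraction Fraction of cells flagged by score (default 0.01).
#' @param seed RNG seed for pair sampling.
#' @return data.frame with doublet_score and is_doublet_call per cell, in
#'   the row order of `matrix`. With fewer than `2 * k` cells a warning is
#'   raised and all scores are NA.
#' @export
doublet_scores <- function(matrix, embedder, n_synth = 5 * nrow(matrix),
                           k = 10, flag_fraction = 0.01, seed = 1L) {
  n <- nrow(matrix)
  if (n_synth < 1) stop("n_synth must be positive")
  if (n < 2 * k) {
    warning("fewer than 2*k cells: doublet scoring skipped")
    return(data.frame(doublet_score = rep(NA_real_, n),
                      is_doublet_call = rep(NA, n)))
  }
  set.seed(seed)
  i1 <- sample.int(n, n_synth, replace = TRUE)
  i2 <- sample.int(n, n_synth, replace = TRUE)
  synth <- matrix[i1, , drop = FALSE] + matrix[i2, , drop = FALSE]
  proj_obs <- lsi_project(embedder, matrix)
  proj_syn <- lsi_project(embedder, synth)
  all_coords <- rbind(proj_obs, proj_syn)
  nn <- .knn_cosine(proj_obs, all_coords, k = k + 1L)  # self is its own NN
  syn_hits <- rowSums(nn[, -1L, drop = FALSE] > n)
  expected <- k * n_synth / (n_synth + n)
  score <- syn_hits / expected
  n_flag <- ceiling(flag_fraction * n)
  cutoff <- sort(score, decreasing = TRUE)[n_flag]
  data.frame(doublet_score = score,
             is_doublet_call = rank(-score, ties.method = "first") <= n_flag)
}

#' QC summary per age
#'
#' Counts of cells retained at each successive filter.
#'
#' @param cells CellTable (after [apply_filters()]).
#' @param min_frags,min_frip,max_bl Thresholds used.
#' @return data.frame of per-age counts.
#' @export
qc_summary <- function(cells, min_frags = 100, min_frip = 0.7, max_bl = 0.2) {
  ages <- if (all(is.na(cells$age))) "all" else unique(cells$age)
  do.call(rbind, lapply(ages, function(a) {
    sub <- if (identical(a, "all")) cells else cells[cells$age %in% a, ]
    f1 <- sub$n_fragments >= min_frags
    f2 <- f1 & sub$frip >= min_frip
    f3 <- f2 & sub$blacklist_fraction <= max_bl
    data.frame(age = a, total = nrow(sub), min_frags = sum(f1),
               and_frip = sum(f2), and_blacklist = sum(f3),
               pass_qc = sum(sub$pass_qc, na.rm = TRUE))
  }))
}
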