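# Sparse-enrichment calling of broad repressive domains. The caller
# decomposes a coverage track into maximal runs of strictly positive signal
# ("signal blocks"), ranks blocks by their area under the curve (signal x
# width), and keeps the top fraction -- the numeric-threshold mode of
# SEACR-style peak calling, suited to broad H3K27me3 domains where no IgG
# control track exists for the single-cell pseudobulks.

#' Decompose a track into signal blocks
#'
#' A signal block is a maximal run of strictly positive signal. Each block
#' is annotated with its AUC (sum of signal times width), its maximum
#' signal, and the position of the maximum (leftmost bin on ties).
#'
#' @param track CoverageTrack (raw or normalized).
#' @return data.frame with chrom, start, end (bp, 0-based half-open), auc,
#'   max_signal, max_position.
#' @export
call_blocks <- function(track) {
  bin <- attr(track, "bin")
  genome <- attr(track, "genome")
  out <- lapply(names(track), function(chrom) {
    v <- unclass(track)[[chrom]]
    w <- .bin_widths(track, chrom)
    pos <- v > 0
    if (!any(pos)) return(NULL)
    r <- rle(pos)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1L
    runs <- which(r$values)
    blocks <- lapply(runs, function(i) {
      b0 <- starts_bin[i]; b1 <- ends_bin[i]
      vv <- v[b0:b1]; ww <- w[b0:b1]
      imax <- which.max(vv)
      data.frame(
        chrom = chrom,
        start = (b0 - 1L) * bin,
        end = min(b1 * bin, genome[[chrom]]),
        auc = sum(vv * ww),
        max_signal = vv[imax],
        max_position = (b0 - 1L + imax - 1L) * bin,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, blocks)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      auc = numeric(), max_signal = numeric(),
                      max_position = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Threshold signal blocks by AUC
#'
#' Retains the top `top_fraction` of blocks ranked by AUC: with `n` blocks,
#' the AUC of the `ceiling(top_fraction * n)`-th largest block becomes the
#' cutoff and every block with AUC greater than or equal to it is kept, so
#' ties at the cutoff are all retained.
#'
#' @param blocks data.frame from [call_blocks()].
#' @param top_fraction Proportion of blocks to keep (0 < f <= 1). The
#'   default 0.01 is the stringent cutoff used for H3K27me3 pseudobulks.
#' @return A `DomainSet`: the retained blocks, sorted, with the threshold
#'   recorded in attributes.
#' @export
threshold_blocks <- function(blocks, top_fraction = 0.01) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (!nrow(blocks)) {
    return(structure(blocks, threshold = top_fraction, class = c("DomainSet", "data.frame")))
  }
  k <- ceiling(top_fraction * nrow(blocks))
  cutoff <- sort(blocks$auc, decreasing = TRUE)[k]
  keep <- blocks$auc >= cutoff
  out <- blocks[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = top_fraction, auc_cutoff = cutoff,
            class = c("DomainSet", "data.frame"))
}

#' Call repressive domains from a fragment set
#'
#' Convenience wrapper: binned coverage, genome normalization (optional),
#' block decomposition and AUC thresholding.
#'
#' @param frags FragmentSet (e.g. one age's pseudobulk).
#' @param genome Chromosome sizes.
#' @param bin Bin width in bp (default 25).
#' @param top_fraction AUC threshold (default 0.01).
#' @param normalized Call on the genome-normalized track (default TRUE).
#' @return A `DomainSet`.
#' @export
call_domains <- function(frags, genome = genome_of(frags), bin = 25L,
                         top_fraction = 0.01, normalized = TRUE) {
  track <- coverage_track(frags, genome, bin = bin)
  if (normalized) track <- normalize_track(track, genome)
  threshold_blocks(call_blocks(track), top_fraction)
}

#' Merge per-age domain sets
#'
#' Cross-age union with bedtools-merge semantics. Provenance (the names of
#' the merged inputs) is recorded in an attribute.
#'
#' @param domain_sets Named list of DomainSets (or plain interval
#'   data.frames).
#' @return A merged `DomainSet` of plain intervals.
#' @export
merge_domain_sets <- function(domain_sets) {
  merged <- merge_intervals(domain_sets)
  structure(merged, provenance = names(domain_sets),
            class = c("DomainSet", "data.frame"))
}

#' Genes overlapping domains
#'
#' @param genes Gene interval data.frame (chrom/start/end, optional
#'   name/strand).
#' @param domains DomainSet or interval data.frame.
#' @return The subset of `genes` with at least 1 bp overlap with any domain.
#' @export
genes_in_domains <- function(genes, domains) {
  if (!nrow(genes) || !nrow(domains)) return(genes[integer(), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(.as_gr(genes), .as_gr(domains))
  out <- genes[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enhancers overlapping domains
#'
#' Identical overlap rule to [genes_in_domains()]; bookended intervals (zero
#' overlap under the half-open convention) are excluded.
#'
#' @param enhancers Enhancer interval data.frame.
#' @param domains DomainSet or interval data.frame.
#' @return Subset of `enhancers` within domains.
#' @export
enhancers_in_domains <- function(enhancers, domains) {
  genes_in_domains(enhancers, domains)
}

#' Base-pair Jaccard index between two interval sets
#'
#' Intersection over union of covered base pairs; used to compare called
#' domains with planted truth.
#'
#' @param a,b Interval data.frames.
#' @return Scalar in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  ga <- GenomicRanges::reduce(.as_gr(a))
  gb <- GenomicRanges::reduce(.as_gr(b))
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb, ignore.strand = TRUE)))
  if (uni == 0) return(1)
  inter / uni
}

#' Export a DomainSet as SEACR-style TSV
#' @param domains DomainSet.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_domains <- function(domains, path) {
  cols <- intersect(c("chrom", "start", "end", "auc", "max_signal", "max_position"),
                    names(domains))
  utils::write.table(as.data.frame(domains)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
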