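# ---- genome / interval helpers ------------------------------------------------

#' Read a chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length in bp.
#'
#' @param path Path to a chrom.sizes text file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$chrom)) stop("duplicated chromosome names in ", path)
  stats::setNames(tab$size, tab$chrom)
}

#' @keywords internal
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(names(genome), unname(genome)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# intervals are data.frames with chrom/start/end (0-based half-open) and
# optionally name/strand columns; converted to GRanges internally.
.as_gr <- function(x, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  sl <- if (!is.null(genome)) genome else NULL
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else rep("*", nrow(x)),
    seqlengths = sl
  )
  if ("name" %in% names(x)) names(gr) <- x$name
  gr
}

.from_gr <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(names(gr))) df$name <- names(gr)
  df
}

#' Read a BED file of intervals
#'
#' Columns beyond the first three are mapped to `name`, `score`, `strand`
#' when present (standard BED column order). Coordinates stay 0-based
#' half-open. Gzip-compressed files are read transparently.
#'
#' @param path BED(-like) file path.
#' @param genome Optional named vector of chromosome sizes used to validate
#'   interval bounds.
#' @return data.frame with chrom/start/end and any optional columns.
#' @export
read_bed <- function(path, genome = NULL) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns: ", path)
  names(tab) <- cols[seq_len(min(ncol(tab), 6))]
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if ("score" %in% names(tab)) tab$score <- suppressWarnings(as.numeric(tab$score))
  validate_intervals(tab, genome, what = path)
  tab
}

#' @keywords internal
write_bed <- function(x, path, columns = intersect(c("chrom", "start", "end",
                                                     "name", "score", "strand"),
                                                   names(x))) {
  df <- x[, columns, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_intervals <- function(x, genome = NULL, what = "intervals") {
  bad <- which(!(x$end > x$start))
  if (length(bad)) {
    stop(what, ": end <= start at line(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(genome)) {
    missing_chrom <- setdiff(unique(x$chrom), names(genome))
    if (length(missing_chrom)) {
      stop(what, ": chromosome(s) not in genome: ",
           paste(missing_chrom, collapse = ", "))
    }
    oob <- which(x$start < 0 | x$end > genome[x$chrom])
    if (length(oob)) {
      stop(what, ": interval outside chromosome bounds at line(s) ",
           paste(utils::head(oob, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

# ---- FragmentSet --------------------------------------------------------------

#' Construct a FragmentSet
#'
#' The universal input currency of the pipeline: genomic fragments with an
#' optional cell barcode or sample label. Coordinates are 0-based half-open,
#' as in fragment BED files. Records are sorted by (chrom, start, end).
#'
#' @param df data.frame with columns chrom, start, end and optionally label.
#' @param genome Named vector of chromosome sizes.
#' @return A `FragmentSet` (data.frame subclass with a `genome` attribute).
#' @export
fragment_set <- function(df, genome) {
  stopifnot(is.data.frame(df))
  if (!"label" %in% names(df)) df$label <- NA_character_
  df <- df[, c("chrom", "start", "end", "label")]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$label <- as.character(df$label)
  if (nrow(df)) validate_intervals(df, genome, what = "fragments")
  ord <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("FragmentSet", "data.frame"))
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet: %d fragments, %d labels, genome of %d chrom(s) (%s bp)\n",
              nrow(x), length(unique(x$label)), length(attr(x, "genome")),
              format(sum(attr(x, "genome")), big.mark = ",")))
  invisible(x)
}

#' Genome of a FragmentSet or CoverageTrack
#' @param x FragmentSet or CoverageTrack.
#' @return Named vector of chromosome sizes.
#' @export
genome_of <- function(x) attr(x, "genome")

#' Read a fragment BED file
#'
#' Expects 3 or 4 tab-separated columns (chrom, start, end, barcode/sample
#' label), 0-based half-open. Malformed records abort with their line
#' numbers; intervals outside the declared genome are rejected.
#'
#' @param path Fragment BED file (optionally gzipped).
#' @param genome Named vector of chromosome sizes.
#' @return Sorted, validated [fragment_set()].
#' @export
read_fragments <- function(path, genome) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (!length(first)) {
    return(fragment_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), label = character()),
                        genome))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 3) stop("fragment file needs >= 3 columns: ", path)
  df <- data.frame(chrom = tab[[1]],
                   start = suppressWarnings(as.numeric(tab[[2]])),
                   end = suppressWarnings(as.numeric(tab[[3]])),
                   label = if (ncol(tab) >= 4) tab[[4]] else NA_character_,
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad)) {
    stop(path, ": non-numeric coordinates at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  fragment_set(df, genome)
}

#' Write a FragmentSet as 4-column BED
#' @param frags FragmentSet.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments <- function(frags, path) {
  write_bed(cbind(frags[, c("chrom", "start", "end")], name = frags$label), path)
}

# ---- CoverageTrack ------------------------------------------------------------

#' Compute a coverage track from fragments
#'
#' Per-base fragment coverage, optionally averaged into fixed-width bins
#' (the bin value is the mean per-base coverage inside the bin; a final
#' partial bin is averaged over its actual width).
#'
#' @param frags FragmentSet.
#' @param genome Named vector of chromosome sizes (defaults to the
#'   FragmentSet's genome).
#' @param bin Bin width in bp (>= 1). `bin = 1` gives per-base values.
#' @return A `CoverageTrack`: per-chromosome numeric vectors plus `bin`,
#'   `normalization` and `genome` attributes.
#' @export
coverage_track <- function(frags, genome = genome_of(frags), bin = 1L) {
  stopifnot(bin >= 1)
  bin <- as.integer(bin)
  gr <- .as_gr(frags, genome)
  cov <- GenomicRanges::coverage(gr)
  values <- lapply(names(genome), function(chrom) {
    L <- as.integer(genome[[chrom]])
    rle <- if (chrom %in% names(cov)) cov[[chrom]] else
      S4Vectors::Rle(0L, L)
    if (bin == 1L) return(as.numeric(rle))
    starts <- seq.int(1L, L, by = bin)
    ends <- pmin(starts + bin - 1L, L)
    as.numeric(IRanges::viewMeans(IRanges::Views(rle, start = starts, end = ends)))
  })
  names(values) <- names(genome)
  structure(values, bin = bin, normalization = "raw", genome = genome,
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack (%s): bin %d bp, %d chrom(s), total signal %.4g\n",
              attr(x, "normalization"), attr(x, "bin"), length(x),
              track_total(x)))
  invisible(x)
}

# widths of the bins of a track on one chromosome (last bin may be partial)
.bin_widths <- function(track, chrom) {
  bin <- attr(track, "bin")
  L <- attr(track, "genome")[[chrom]]
  n <- length(track[[chrom]])
  w <- rep(bin, n)
  w[n] <- L - (n - 1L) * bin
  w
}

#' Total per-base signal of a track (sum of value x bin width)
#' @param track CoverageTrack.
#' @return Scalar total.
#' @export
track_total <- function(track) {
  sum(vapply(names(track), function(chrom) {
    sum(unclass(track)[[chrom]] * .bin_widths(track, chrom))
  }, numeric(1)))
}

#' Genome-normalize a coverage track
#'
#' Scales a raw track so that uniformly distributed counts would have value
#' one at every position: `out = cov * L / sum(cov)` with `L` the total
#' genome length and `sum(cov)` the total per-base coverage.
#'
#' @param track Raw CoverageTrack.
#' @param genome Named vector of chromosome sizes.
#' @return Genome-normalized CoverageTrack. An all-zero track is returned
#'   unchanged (tagged normalized) with a warning.
#' @export
normalize_track <- function(track, genome = attr(track, "genome")) {
  if (attr(track, "normalization") != "raw") {
    stop("normalize_track expects a raw track")
  }
  total <- track_total(track)
  L <- sum(genome)
  vals <- unclass(track)
  if (total == 0) {
    warning("all-zero track: returning zeros")
    scale <- 0
  } else {
    scale <- L / total
  }
  out <- lapply(vals[names(genome)], function(v) v * scale)
  structure(out, bin = attr(track, "bin"), normalization = "genome-normalized",
            genome = genome, class = "CoverageTrack")
}

#' Write a track as bedGraph
#'
#' Adjacent equal-valued bins are collapsed into runs; zero-valued runs are
#' omitted. Values are printed with 6 significant digits.
#'
#' @param track CoverageTrack.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  bin <- attr(track, "bin")
  genome <- attr(track, "genome")
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- unclass(track)[[chrom]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    starts <- starts_bin[keep] * bin
    ends <- pmin(ends_bin[keep] * bin, genome[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(starts),
                       as.integer(ends), signif(r$values[keep], 6)), con)
  }
  invisible(path)
}

# ---- interval arithmetic ------------------------------------------------------

#' Merge interval lists with bedtools-merge semantics
#'
#' Overlapping or bookended intervals (end of one equals start of the next)
#' coalesce into one.
#'
#' @param sets A list of interval data.frames (chrom/start/end), or a single
#'   data.frame.
#' @return data.frame of merged, sorted intervals.
#' @export
merge_intervals <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  all <- do.call(rbind, lapply(sets, function(s) s[, c("chrom", "start", "end")]))
  if (!nrow(all)) return(all)
  merged <- GenomicRanges::reduce(.as_gr(all))
  .from_gr(GenomicRanges::sort(merged))
}

#' Count fragments over intervals
#'
#' Per-interval number of fragments with at least 1 bp overlap. A fragment
#' overlapping two intervals is counted once in each (bedtools
#' `intersect -c` semantics).
#'
#' @param frags FragmentSet.
#' @param intervals Interval data.frame.
#' @return Integer vector, one count per interval row.
#' @export
count_over_intervals <- function(frags, intervals) {
  if (!nrow(intervals)) return(integer())
  if (!nrow(frags)) return(integer(nrow(intervals)))
  GenomicRanges::countOverlaps(.as_gr(intervals), .as_gr(frags))
}

# subset of fragment row indices overlapping any interval
.frags_overlapping <- function(frags, intervals) {
  if (!nrow(frags) || !nrow(intervals)) return(integer())
  S4Vectors::queryHits(GenomicRanges::findOverlaps(.as_gr(frags), .as_gr(intervals)))
}
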