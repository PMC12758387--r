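# FIMO-style position-weight-matrix scanning. Sites are scored in bits as
# sum_i log2(p_i(letter) / bg(letter)); per-site p-values are computed
# exactly by dynamic programming over finely discretized integer scores
# under the background model; both strands are scanned and sites with
# p below the threshold are reported.

.BASES <- c("A", "C", "G", "T")

#' Construct a PWM
#'
#' Count or probability matrices are normalized to probabilities after
#' adding a pseudocount to every cell (FIMO-like, default 0.1).
#'
#' @param matrix 4 x w numeric matrix, rows A, C, G, T.
#' @param name Motif identifier.
#' @param background Background distribution over ACGT (default uniform).
#' @param pseudocount Added to each cell before normalization.
#' @return A `Pwm` object.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.1) {
  stopifnot(nrow(matrix) == 4, all(matrix >= 0))
  rownames(matrix) <- .BASES
  background <- background / sum(background)
  prob <- apply(matrix + pseudocount, 2, function(col) col / sum(col))
  stopifnot(all(abs(colSums(prob) - 1) < 1e-9))
  structure(list(name = name, width = ncol(prob), prob = prob,
                 background = stats::setNames(background, .BASES),
                 score = base::log2(prob / background)),
            class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm '%s': width %d, consensus %s, max score %.3f bits\n",
              x$name, x$width, pwm_consensus(x), pwm_max_score(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (leftmost argmax per column)
#' @param p Pwm.
#' @return Character string of length w.
#' @export
pwm_consensus <- function(p) {
  paste(.BASES[apply(p$prob, 2, which.max)], collapse = "")
}

#' Maximum attainable log-odds score of a PWM
#' @param p Pwm.
#' @return Score in bits.
#' @export
pwm_max_score <- function(p) sum(apply(p$score, 2, max))

#' Score one site against a PWM
#'
#' @param p Pwm.
#' @param sequence Character w-mer over ACGT.
#' @return Log-odds score in bits; NA (with the site reported skipped) for
#'   ambiguous bases.
#' @export
score_site <- function(p, sequence) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters) != p$width) stop("sequence length must equal motif width")
  idx <- match(letters, .BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(p$score[cbind(idx, seq_len(p$width))])
}

.dp_cache <- new.env(parent = emptyenv())

# integer-discretized score matrix and its exact background distribution;
# memoized per (PWM, granularity) since scans and p-value queries hit the
# same PWM repeatedly
.pwm_dp <- function(p, granularity = 1e-4) {
  key <- paste(granularity, paste(signif(c(p$score, p$background), 12),
                                  collapse = ","), sep = "|")
  hit <- .dp_cache[[key]]
  if (!is.null(hit)) return(hit)
  s_int <- round(p$score / granularity)
  lo <- sum(apply(s_int, 2, min))
  hi <- sum(apply(s_int, 2, max))
  # dp[v] = P(total integer score == v + cur_lo - 1) under background,
  # grown column by column from a single mass at 0
  dp <- numeric(hi - lo + 1)
  cur <- 1
  dp[1] <- 1
  cur_lo <- 0
  for (j in seq_len(p$width)) {
    new_lo <- cur_lo + min(s_int[, j])
    new_hi <- cur_lo + (cur - 1) + max(s_int[, j])
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      sh <- cur_lo + s_int[b, j] - new_lo
      idx <- (sh + 1):(sh + cur)
      new[idx] <- new[idx] + p$background[b] * dp[seq_len(cur)]
    }
    dp <- new
    cur <- length(new)
    cur_lo <- new_lo
  }
  out <- list(probs = dp, lo = cur_lo, granularity = granularity,
              s_int = s_int)
  if (length(ls(.dp_cache)) > 64) rm(list = ls(.dp_cache), envir = .dp_cache)
  .dp_cache[[key]] <- out
  out
}

#' Exact p-value of a site score
#'
#' `P(random w-mer under the background scores >= score)`, computed by
#' dynamic programming over integer-discretized scores. The default
#' granularity of 1/10,000 bit keeps the discretization error well below
#' the spacing of attainable scores for typical PWMs; [scan_pwm()] scores
#' sites on the same discretized matrix, so its p-value lookups are exact.
#'
#' @param p Pwm.
#' @param score Score in bits.
#' @return p-value in (0, 1].
#' @export
site_pvalue <- function(p, score) {
  if (!is.finite(score)) return(if (score < 0) 1 else .Machine$double.xmin)
  # up to width 8 the full outcome distribution (4^w terms) is cheap, so
  # the tail is computed exactly on real-valued scores
  if (p$width <= 8) {
    s <- 0; pr <- 1
    for (j in seq_len(p$width)) {
      s <- as.vector(outer(s, p$score[, j], "+"))
      pr <- as.vector(outer(pr, p$background, "*"))
    }
    return(max(sum(pr[s >= score - 1e-9]), .Machine$double.xmin))
  }
  # wider motifs: per-column rounding displaces a score's own mass point
  # by at most ceiling(w/2) grid units, so the true tail lies between the
  # tail sums just outside that window; refine the grid when the bracket
  # is loose
  upper <- 1
  for (g in c(1e-4, 4e-6)) {
    dp <- .pwm_dp(p, g)
    guard <- ceiling(p$width / 2)
    sf <- rev(cumsum(rev(dp$probs)))
    at <- function(target) {
      pos <- target - dp$lo + 1
      if (pos <= 1) 1 else if (pos > length(sf)) 0 else sf[pos]
    }
    tgt <- round(score / g)
    upper <- at(tgt - guard)
    lower <- at(tgt + guard + 1)
    if (upper - lower <= 5e-4 * upper) break
  }
  max(upper, .Machine$double.xmin)
}

#' Scan sequences with a PWM
#'
#' Both strands are scanned (reverse-strand sites are scored on the
#' reverse complement); sites with p-value below `p_threshold` are
#' reported. Windows containing ambiguous bases are skipped.
#'
#' @param p Pwm.
#' @param sequences Named character vector or `DNAStringSet`.
#' @param p_threshold Site p-value threshold (default 1e-4, the FIMO
#'   default).
#' @return data.frame of `MotifHit`s: sequence name, motif, strand,
#'   offset (0-based, forward-strand coordinates of the site start),
#'   score (bits), p.
#' @export
scan_pwm <- function(p, sequences, p_threshold = 1e-4) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) names(sequences) <- sprintf("seq%d", seq_along(sequences))
  dp <- .pwm_dp(p)
  sf <- rev(cumsum(rev(dp$probs)))
  # sites are scored on the same integer-discretized matrix the DP uses,
  # so the p-value lookup is exact
  pval_of <- function(s_int_total) {
    pos <- s_int_total - dp$lo + 1
    out <- numeric(length(pos))
    out[pos <= 1] <- 1
    inside <- pos > 1 & pos <= length(sf)
    out[inside] <- sf[pos[inside]]
    out[pos > length(sf)] <- .Machine$double.xmin
    out
  }
  w <- p$width
  scan_one_strand <- function(seqchars, strand, L) {
    n <- length(seqchars) - w + 1
    if (n < 1) return(NULL)
    code <- match(seqchars, .BASES)
    s <- integer(n)
    valid <- rep(TRUE, n)
    for (j in seq_len(w)) {
      cj <- code[j:(j + n - 1)]
      bad <- is.na(cj)
      valid <- valid & !bad
      cj[bad] <- 1L
      s <- s + dp$s_int[cbind(cj, j)]
    }
    pv <- pval_of(s)
    keep <- valid & pv < p_threshold
    if (!any(keep)) return(NULL)
    off <- which(keep) - 1L
    if (strand == "-") off <- L - w - off
    data.frame(strand = strand, offset = off,
               score = s[keep] * dp$granularity, p = pv[keep])
  }
  out <- lapply(names(sequences), function(nm) {
    fw <- strsplit(toupper(sequences[[nm]]), "")[[1]]
    L <- length(fw)
    rc <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[fw])
    rc[is.na(rc)] <- "N"
    hits <- rbind(scan_one_strand(fw, "+", L), scan_one_strand(rc, "-", L))
    if (is.null(hits) || !nrow(hits)) return(NULL)
    cbind(sequence = nm, motif = p$name, hits)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(sequence = character(), motif = character(),
                      strand = character(), offset = integer(),
                      score = numeric(), p = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Motif enrichment in foreground vs background enhancers
#'
#' Per motif, a 2x2 table of enhancers with/without at least one hit in
#' foreground (age-changing) vs background (stable in-domain) sets, tested
#' with a two-sided Fisher exact test, BH-corrected across motifs.
#'
#' @param hits data.frame of hits from [scan_pwm()] (multiple motifs can
#'   be row-bound).
#' @param fg,bg Character vectors of foreground and background enhancer
#'   (sequence) names.
#' @return data.frame: motif, hit counts, odds ratio, p, q (BH).
#' @export
motif_enrichment <- function(hits, fg, bg) {
  if (!length(fg) || !length(bg)) stop("empty foreground or background set")
  motifs <- unique(hits$motif)
  out <- do.call(rbind, lapply(motifs, function(m) {
    with_hit <- unique(hits$sequence[hits$motif == m])
    a <- sum(fg %in% with_hit); b <- length(fg) - a
    c <- sum(bg %in% with_hit); d <- length(bg) - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    data.frame(motif = m, fg_with = a, fg_total = length(fg),
               bg_with = c, bg_total = length(bg),
               odds_ratio = (a * d) / max(1e-12, b * c),
               p = ft$p.value)
  }))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p), ]
}

# ---- MEME format I/O ----------------------------------------------------

#' Write PWMs in MEME motif format
#' @param pwms Named list of 4 x w probability (or count) matrices or Pwm
#'   objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (nm in names(pwms)) {
    m <- if (inherits(pwms[[nm]], "Pwm")) pwms[[nm]]$prob else pwms[[nm]]
    m <- apply(m, 2, function(col) col / sum(col))
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m)), con)
    writeLines(apply(t(m), 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME motif file
#' @param path MEME-format motif file.
#' @param background,pseudocount Passed to [pwm()].
#' @return Named list of Pwm objects.
#' @export
read_meme <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  out <- lapply(starts, function(s) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + 1
    while (h <= length(lines) && !grepl("letter-probability matrix", lines[h])) h <- h + 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4)))
    pwm(t(m), name = name, background = background, pseudocount = pseudocount)
  })
  stats::setNames(out, vapply(out, function(p) p$name, character(1)))
}

#' Extract interval sequences from a genome
#' @param sequences Named DNAStringSet (one per chromosome).
#' @param intervals Interval data.frame with optional `name`.
#' @return Named character vector of sequences.
#' @export
interval_sequences <- function(sequences, intervals) {
  out <- vapply(seq_len(nrow(intervals)), function(i) {
    as.character(Biostrings::subseq(sequences[[intervals$chrom[i]]],
                                    start = intervals$start[i] + 1L,
                                    end = intervals$end[i]))
  }, character(1))
  names(out) <- if ("name" %in% names(intervals)) intervals$name else
    sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  out
}
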