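# Shared fixtures. The default synthetic dataset and the full pipeline run
# are expensive (~1 min together), so they are built once per test session
# and cached in this environment.

.cache <- new.env(parent = emptyenv())

tiny_genome <- c(chrA = 1000, chrB = 500)

make_frags <- function(chrom, start, end, label = NA_character_,
                       genome = tiny_genome) {
  n <- max(length(chrom), length(start))
  fragment_set(data.frame(chrom = rep(chrom, length.out = n),
                          start = start, end = end,
                          label = rep(label, length.out = n)),
               genome)
}

# a CoverageTrack built directly from bin values (internal layout)
make_track <- function(values, bin, genome,
                       normalization = "genome-normalized") {
  structure(values, bin = as.integer(bin), normalization = normalization,
            genome = genome, class = "CoverageTrack")
}

# default synthetic single-cell dataset (seed 1)
default_synth <- function() {
  if (is.null(.cache$synth)) {
    .cache$synth <- generate_single_cell(synth_config(seed = 1L))
  }
  .cache$synth
}

# full default pipeline run (seed 1); returns outdir and elapsed seconds
default_run <- function() {
  if (is.null(.cache$run)) {
    od <- file.path(tempdir(), "guttag_default_run")
    unlink(od, recursive = TRUE)
    t0 <- Sys.time()
    suppressWarnings(suppressMessages(
      run_pipeline("all", pipeline_config(seed = 1L), od)))
    .cache$run <- list(outdir = od,
                       elapsed = as.numeric(Sys.time() - t0, units = "secs"))
  }
  .cache$run
}

read_run_tsv <- function(run, name) {
  utils::read.table(file.path(run$outdir, name), header = TRUE, sep = "\t")
}

# truth-joined cell table from the default run
default_celltable <- function() {
  run <- default_run()
  tr <- default_synth()$truth
  cells <- read_run_tsv(run, "celltable.tsv")
  merge(cells, tr$cells[c("barcode", "type", "is_doublet", "is_artifact",
                          "planted_bl_fraction", "doublet_types")],
        by = "barcode")
}

# rank-based AUROC (oracle-style, independent of pROC)
auroc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
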