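# Pipeline orchestration: a single config object carrying every module's
# parameters, step functions that read their inputs from the output
# directory (so steps can be run separately), and a JSON manifest recording
# parameters, seed and input hashes for every step. All randomness derives
# from the config seed; a rerun with the same config produces identical
# outputs.

.STEPS <- c("simulate", "domains", "qc", "cluster", "css", "diff",
            "enhancers", "motifs", "bulk", "proportions")

.validation_error <- function(msg) {
  stop(structure(class = c("guttag_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.missing_artifact <- function(path, producer) {
  stop(structure(class = c("guttag_missing_artifact", "error", "condition"),
                 list(message = sprintf(
                   "missing artifact '%s': run the '%s' step first", path, producer),
                   call = sys.call(-1))))
}

#' Pipeline configuration
#'
#' Defaults are the thresholds of the published analysis: 100 fragments
#' per cell, FRiP >= 0.7, blacklist fraction <= 0.2, domain-calling top
#' fraction 0.01, 10,000 permutations, CSS decay 5,000 bp, alpha = 0.05.
#'
#' @param seed Master seed.
#' @param synth [synth_config()] for the simulate step (seeded from
#'   `seed` unless given).
#' @param qc,domains,cluster,css,diff,motifs,bulk,proportions Named lists
#'   overriding individual parameters of each block.
#' @return A validated `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, synth = NULL, qc = list(),
                            domains = list(), cluster = list(), css = list(),
                            diff = list(), motifs = list(), bulk = list(),
                            proportions = list()) {
  merge_block <- function(defaults, user, block) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      .validation_error(sprintf("unknown key(s) in '%s' block: %s", block,
                                paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    synth = if (is.null(synth)) synth_config(seed = as.integer(seed)) else synth,
    qc = merge_block(list(min_frags = 100, min_frip = 0.7, max_bl = 0.2,
                          doublet_k = 50, doublet_n_synth_per_cell = 5,
                          doublet_flag_fraction = 0.05), qc, "qc"),
    domains = merge_block(list(bin = 25, top_fraction = 0.01,
                               normalized = TRUE), domains, "domains"),
    cluster = merge_block(list(d = 30, k = 20, resolution = 0.8), cluster,
                          "cluster"),
    css = merge_block(list(tile = 500, window = 50000, tau = 5000,
                           depth_scale = 10000), css, "css"),
    diff = merge_block(list(alpha = 0.05, lfc_min = 1), diff, "diff"),
    motifs = merge_block(list(p_threshold = 1e-4), motifs, "motifs"),
    bulk = merge_block(list(corr_threshold = 0.8), bulk, "bulk"),
    proportions = merge_block(list(n_perm = 10000, focal_type = "ISC/EB",
                                   ageA = "young", ageB = "old"),
                              proportions, "proportions")
  )
  with(cfg$qc, {
    if (min_frip < 0 || min_frip > 1) .validation_error("min_frip must be in [0, 1]")
    if (max_bl < 0 || max_bl > 1) .validation_error("max_bl must be in [0, 1]")
    if (min_frags < 0) .validation_error("min_frags must be >= 0")
  })
  if (cfg$domains$top_fraction <= 0 || cfg$domains$top_fraction > 1)
    .validation_error("domains top_fraction must be in (0, 1]")
  if (cfg$proportions$n_perm < 1) .validation_error("n_perm must be >= 1")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline config from YAML
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return PipelineConfig.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "synth")
  unknown <- setdiff(names(y), c(known, "synth"))
  if (length(unknown)) {
    .validation_error(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  if (!is.null(y$synth)) {
    y$synth <- do.call(synth_config, utils::modifyList(
      list(seed = as.integer(y$seed %||% 1L)), y$synth))
  }
  do.call(pipeline_config, y)
}

.art <- function(outdir, name) file.path(outdir, name)

.require_artifact <- function(outdir, name, producer) {
  p <- .art(outdir, name)
  if (!file.exists(p)) .missing_artifact(name, producer)
  p
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.manifest_add <- function(outdir, step, params, inputs = character()) {
  mf <- .art(outdir, "manifest.json")
  man <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
  hashes <- as.list(tools::md5sum(inputs[file.exists(inputs)]))
  names(hashes) <- basename(names(hashes))
  man[[step]] <- list(parameters = params, input_hashes = hashes)
  jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mf)
}

# ---- steps --------------------------------------------------------------

.step_simulate <- function(cfg, outdir) {
  sc <- generate_single_cell(cfg$synth)
  tr <- sc$truth
  write_fragments(sc$fragments, .art(outdir, "fragments.bed"))
  write_chrom_sizes(tr$genome, .art(outdir, "chrom.sizes"))
  write_bed(cbind(tr$genes[c("chrom", "start", "end", "name")], score = 0,
                  strand = tr$genes$strand), .art(outdir, "genes.bed"))
  .write_tsv(tr$promoters, .art(outdir, "promoters.tsv"))
  write_bed(tr$enhancers[c("chrom", "start", "end", "name")],
            .art(outdir, "enhancers.bed"))
  write_bed(tr$blacklist, .art(outdir, "blacklist.bed"))
  write_meme(tr$motifs, .art(outdir, "motifs.meme"))
  Biostrings::writeXStringSet(tr$sequences, .art(outdir, "genome.fa"))
  # observable per-cell metadata (age, chip); the hidden truth goes to JSON
  .write_tsv(tr$cells[c("barcode", "age", "replicate")], .art(outdir, "cells.tsv"))
  truth_json <- list(
    cells = tr$cells,
    domains = tr$domains,
    all_domains = tr$all_domains,
    diff_genes = tr$diff_genes,
    enhancers = tr$enhancers[, setdiff(names(tr$enhancers), "sequence")],
    marker_genes = as.list(tr$marker_genes),
    motif_consensus = tr$motif_consensus,
    pc_bound = tr$pc_bound,
    promoter_rates = as.data.frame(tr$promoter_rates)
  )
  jsonlite::write_json(truth_json, .art(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  for (ab in c("RNAPIIS5P", "Pc", "IgG")) {
    bdir <- .art(outdir, "bulk")
    dir.create(bdir, showWarnings = FALSE)
    bl <- generate_bulk(cfg$synth, ab)
    for (nm in names(bl)) {
      write_fragments(bl[[nm]], file.path(bdir, sprintf("%s_%s.bed", ab, nm)))
    }
  }
  .manifest_add(outdir, "simulate",
                list(seed = cfg$synth$seed, snr = cfg$synth$snr,
                     doublet_rate = cfg$synth$doublet_rate,
                     cell_counts = as.data.frame(cfg$synth$cell_counts)))
  invisible(TRUE)
}

.load_core <- function(outdir) {
  genome <- read_chrom_sizes(.require_artifact(outdir, "chrom.sizes", "simulate"))
  frags <- read_fragments(.require_artifact(outdir, "fragments.bed", "simulate"), genome)
  cells_meta <- utils::read.table(.require_artifact(outdir, "cells.tsv", "simulate"),
                                  header = TRUE, sep = "\t")
  list(genome = genome, frags = frags, cells_meta = cells_meta)
}

.step_domains <- function(cfg, outdir) {
  core <- .load_core(outdir)
  ages <- unique(core$cells_meta$age)
  per_age <- lapply(ages, function(a) {
    bc <- core$cells_meta$barcode[core$cells_meta$age == a]
    sub <- core$frags[core$frags$label %in% bc, , drop = FALSE]
    sub <- fragment_set(sub, core$genome)
    dom <- call_domains(sub, core$genome, bin = cfg$domains$bin,
                        top_fraction = cfg$domains$top_fraction,
                        normalized = cfg$domains$normalized)
    write_domains(dom, .art(outdir, sprintf("domains_%s.tsv", a)))
    dom
  })
  names(per_age) <- ages
  merged <- merge_domain_sets(per_age)
  write_bed(merged, .art(outdir, "domains_merged.bed"))
  .manifest_add(outdir, "domains", cfg$domains,
                inputs = .art(outdir, "fragments.bed"))
  invisible(merged)
}

.step_qc <- function(cfg, outdir) {
  core <- .load_core(outdir)
  merged <- read_bed(.require_artifact(outdir, "domains_merged.bed", "domains"))
  blacklist <- read_bed(.require_artifact(outdir, "blacklist.bed", "simulate"))
  cells <- qc_metrics(core$frags, merged, blacklist)
  cells$age <- core$cells_meta$age[match(cells$barcode, core$cells_meta$barcode)]
  cells$replicate <- core$cells_meta$replicate[match(cells$barcode,
                                                     core$cells_meta$barcode)]
  cells <- apply_filters(cells, cfg$qc$min_frags, cfg$qc$min_frip, cfg$qc$max_bl)
  surv <- cells$barcode[cells$pass_qc]
  fm <- feature_matrix(core$frags, merged, barcodes = surv)
  emb <- lsi_embed(fm, d = cfg$cluster$d, seed = cfg$seed)
  ds <- doublet_scores(fm, emb,
                       n_synth = cfg$qc$doublet_n_synth_per_cell * length(surv),
                       k = cfg$qc$doublet_k,
                       flag_fraction = cfg$qc$doublet_flag_fraction,
                       seed = cfg$seed)
  cells$doublet_score <- ds$doublet_score[match(cells$barcode, surv)]
  cells$is_doublet_call <- ds$is_doublet_call[match(cells$barcode, surv)]
  cells <- apply_filters(cells, cfg$qc$min_frags, cfg$qc$min_frip, cfg$qc$max_bl)
  .write_tsv(cells, .art(outdir, "celltable.tsv"))
  .write_tsv(qc_summary(cells, cfg$qc$min_frags, cfg$qc$min_frip, cfg$qc$max_bl),
             .art(outdir, "qc_summary.tsv"))
  .manifest_add(outdir, "qc", cfg$qc,
                inputs = c(.art(outdir, "fragments.bed"),
                           .art(outdir, "domains_merged.bed")))
  invisible(cells)
}

.read_celltable <- function(outdir, producer = "qc") {
  utils::read.table(.require_artifact(outdir, "celltable.tsv", producer),
                    header = TRUE, sep = "\t",
                    colClasses = c(cluster = "character"))
}

.step_cluster <- function(cfg, outdir) {
  core <- .load_core(outdir)
  merged <- read_bed(.require_artifact(outdir, "domains_merged.bed", "domains"))
  cells <- .read_celltable(outdir)
  keep <- cells$pass_qc
  fm <- feature_matrix(core$frags, merged, barcodes = cells$barcode[keep])
  emb <- lsi_embed(fm, d = cfg$cluster$d, seed = cfg$seed)
  cl <- snn_cluster(emb, k = cfg$cluster$k, resolution = cfg$cluster$resolution,
                    seed = cfg$seed)
  um <- umap_embed(emb, seed = cfg$seed)
  cells$cluster[keep] <- as.character(cl)
  .write_tsv(cells, .art(outdir, "celltable.tsv"))
  .write_tsv(data.frame(barcode = cells$barcode[keep], umap1 = um[, 1],
                        umap2 = um[, 2]), .art(outdir, "umap.tsv"))
  Matrix::writeMM(fm, .art(outdir, "feature_matrix.mtx"))
  writeLines(rownames(fm), .art(outdir, "feature_matrix_rows.txt"))
  writeLines(colnames(fm), .art(outdir, "feature_matrix_cols.txt"))
  .manifest_add(outdir, "cluster", cfg$cluster,
                inputs = .art(outdir, "celltable.tsv"))
  invisible(cells)
}

.step_css <- function(cfg, outdir) {
  core <- .load_core(outdir)
  genes <- read_bed(.require_artifact(outdir, "genes.bed", "simulate"))
  cells <- .read_celltable(outdir, "cluster")
  if (all(is.na(cells$cluster))) .missing_artifact("cluster labels", "cluster")
  keep <- cells$pass_qc
  ccfg <- css_config(tile = cfg$css$tile, window = cfg$css$window,
                     tau = cfg$css$tau, depth_scale = cfg$css$depth_scale)
  css <- css_scores(core$frags, genes, ccfg, barcodes = cells$barcode[keep])
  by_cl <- css_by_cluster(css, cells$cluster[keep])
  markers <- unlist(jsonlite::read_json(
    .require_artifact(outdir, "truth.json", "simulate"))$marker_genes)
  assign <- assign_types(by_cl, markers)
  cells$cell_type[keep] <- assign$cell_type[match(cells$cluster[keep],
                                                  assign$cluster)]
  .write_tsv(cells, .art(outdir, "celltable.tsv"))
  .write_tsv(assign, .art(outdir, "cluster_types.tsv"))
  .write_tsv(cbind(cluster = rownames(by_cl), as.data.frame(by_cl)),
             .art(outdir, "css_by_cluster.tsv"))
  .manifest_add(outdir, "css", cfg$css, inputs = .art(outdir, "celltable.tsv"))
  invisible(cells)
}

# shared helper for the gene- and enhancer-universe differentials
.run_differential <- function(cfg, outdir, features, tag) {
  core <- .load_core(outdir)
  cells <- .read_celltable(outdir, "css")
  if (all(is.na(cells$cell_type))) .missing_artifact("cell types", "css")
  cells <- cells[cells$pass_qc & !is.na(cells$cell_type), ]
  fm <- feature_matrix(core$frags, features, barcodes = cells$barcode)
  colnames(fm) <- features$name
  pb <- pseudobulk(fm, cells)
  meta <- attr(pb, "meta")
  out <- list()
  for (type in unique(cells$cell_type)) {
    sel <- meta$cell_type == type & meta$age %in% c("young", "old")
    if (sum(meta$age[sel] == "young") < 2 || sum(meta$age[sel] == "old") < 2) next
    dt <- differential(pb[, sel, drop = FALSE], meta$age[sel],
                       contrast = c("old", "young"),
                       alpha = cfg$diff$alpha, lfc_min = cfg$diff$lfc_min,
                       lengths = features$end - features$start)
    fn <- sprintf("%s_%s.tsv", tag, gsub("[^A-Za-z0-9]", "-", type))
    .write_tsv(dt, .art(outdir, fn))
    out[[type]] <- dt
  }
  out
}

.step_diff <- function(cfg, outdir) {
  genes <- read_bed(.require_artifact(outdir, "genes.bed", "simulate"))
  merged <- read_bed(.require_artifact(outdir, "domains_merged.bed", "domains"))
  gid <- genes_in_domains(genes, merged)
  out <- .run_differential(cfg, outdir, gid, "diff_genes")
  .manifest_add(outdir, "diff", cfg$diff, inputs = .art(outdir, "celltable.tsv"))
  invisible(out)
}

.step_enhancers <- function(cfg, outdir) {
  enh <- read_bed(.require_artifact(outdir, "enhancers.bed", "simulate"))
  merged <- read_bed(.require_artifact(outdir, "domains_merged.bed", "domains"))
  eid <- enhancers_in_domains(enh, merged)
  out <- .run_differential(cfg, outdir, eid, "diff_enhancers")
  .manifest_add(outdir, "enhancers", cfg$diff,
                inputs = .art(outdir, "enhancers.bed"))
  invisible(out)
}

.step_motifs <- function(cfg, outdir) {
  enh <- read_bed(.require_artifact(outdir, "enhancers.bed", "simulate"))
  merged <- read_bed(.require_artifact(outdir, "domains_merged.bed", "domains"))
  seqs <- Biostrings::readDNAStringSet(.require_artifact(outdir, "genome.fa", "simulate"))
  motifs <- read_meme(.require_artifact(outdir, "motifs.meme", "simulate"))
  eid <- enhancers_in_domains(enh, merged)
  # foreground: enhancers called differential in any cell type
  diff_files <- list.files(outdir, pattern = "^diff_enhancers_.*\\.tsv$",
                           full.names = TRUE)
  if (!length(diff_files)) .missing_artifact("diff_enhancers_*.tsv", "enhancers")
  fg <- unique(unlist(lapply(diff_files, function(f) {
    dt <- utils::read.table(f, header = TRUE, sep = "\t")
    dt$feature[dt$direction != "ns"]
  })))
  bg <- setdiff(eid$name, fg)
  enh_seqs <- interval_sequences(seqs, eid)
  hits <- do.call(rbind, lapply(motifs, function(p)
    scan_pwm(p, enh_seqs, p_threshold = cfg$motifs$p_threshold)))
  .write_tsv(hits, .art(outdir, "motif_hits.tsv"))
  enr <- motif_enrichment(hits, fg = fg, bg = bg)
  .write_tsv(enr, .art(outdir, "motif_enrichment.tsv"))
  .manifest_add(outdir, "motifs", cfg$motifs,
                inputs = .art(outdir, "motifs.meme"))
  invisible(enr)
}

.step_bulk <- function(cfg, outdir) {
  genome <- read_chrom_sizes(.require_artifact(outdir, "chrom.sizes", "simulate"))
  prom <- utils::read.table(.require_artifact(outdir, "promoters.tsv", "simulate"),
                            header = TRUE, sep = "\t")
  bdir <- .art(outdir, "bulk")
  load_ab <- function(ab) {
    files <- list.files(bdir, pattern = sprintf("^%s_", ab), full.names = TRUE)
    if (!length(files)) .missing_artifact(sprintf("bulk/%s_*", ab), "simulate")
    fl <- lapply(files, read_fragments, genome = genome)
    names(fl) <- sub("\\.bed$", "", sub(sprintf("^%s_", ab), "", basename(files)))
    fl
  }
  rnap <- load_ab("RNAPIIS5P")
  counts <- promoter_counts(rnap, prom)
  age_of <- sub("_rep\\d+$", "", colnames(counts))
  cors <- lapply(unique(age_of), function(a)
    replicate_correlation(counts[, age_of == a, drop = FALSE],
                          threshold = cfg$bulk$corr_threshold))
  names(cors) <- unique(age_of)
  cor_df <- do.call(rbind, lapply(names(cors), function(a)
    data.frame(age = a, min_r = min(cors[[a]][upper.tri(cors[[a]])]),
               merge_ok = attr(cors[[a]], "merge_ok"))))
  .write_tsv(cor_df, .art(outdir, "bulk_replicate_correlation.tsv"))
  merged <- merge_replicates(counts, age_of)
  ma <- ma_stat(merged, "mid", "old")
  mcpm <- cpm(merged)
  ma$rate_p <- poisson_rate_test(merged[, "mid"], sum(merged[, "mid"]),
                                 merged[, "old"], sum(merged[, "old"]))
  ma$rate_q <- stats::p.adjust(ma$rate_p, method = "BH")
  .write_tsv(ma, .art(outdir, "bulk_ma_old_vs_mid.tsv"))
  # Pc vs IgG promoter scoring on genome-normalized tracks
  pc_pool <- do.call(rbind, lapply(load_ab("Pc"), as.data.frame))
  igg_pool <- do.call(rbind, lapply(load_ab("IgG"), as.data.frame))
  score_of <- function(pool) {
    tr <- normalize_track(coverage_track(fragment_set(pool, genome), genome, bin = 1))
    track_score_intervals(tr, prom)
  }
  pc_scores <- score_of(pc_pool)
  igg_scores <- score_of(igg_pool)
  pc_tab <- data.frame(promoter = prom$name, pc = pc_scores, igg = igg_scores,
                       quartile = quartile_rank(pc_scores))
  .write_tsv(pc_tab, .art(outdir, "bulk_pc_promoters.tsv"))
  .manifest_add(outdir, "bulk", cfg$bulk, inputs = .art(outdir, "promoters.tsv"))
  invisible(list(ma = ma, correlations = cor_df, pc = pc_tab))
}

.step_proportions <- function(cfg, outdir) {
  cells <- .read_celltable(outdir, "css")
  if (all(is.na(cells$cell_type))) .missing_artifact("cell types", "css")
  cells <- cells[cells$pass_qc & !is.na(cells$cell_type), ]
  comp <- composition(cells)
  .write_tsv(comp, .art(outdir, "composition.tsv"))
  pt <- permutation_test(cells, cfg$proportions$focal_type,
                         cfg$proportions$ageA, cfg$proportions$ageB,
                         n_perm = cfg$proportions$n_perm, seed = cfg$seed)
  jsonlite::write_json(pt, .art(outdir, "composition_test.json"),
                       auto_unbox = TRUE, digits = NA)
  .manifest_add(outdir, "proportions", cfg$proportions,
                inputs = .art(outdir, "celltable.tsv"))
  invisible(list(composition = comp, test = pt))
}

#' Run the pipeline
#'
#' Subcommands: simulate, domains, qc, cluster, css, diff, enhancers,
#' motifs, bulk, proportions, or `all` (the full sequence). Each step
#' writes its outputs and a manifest entry to `outdir`; a step whose
#' upstream artifact is missing fails with an error naming the producing
#' subcommand.
#'
#' @param step Subcommand name (or "all").
#' @param config [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the last step's value.
#' @export
run_pipeline <- function(step = "all", config = pipeline_config(),
                         outdir = "guttag_out") {
  stopifnot(inherits(config, "PipelineConfig"))
  steps <- if (identical(step, "all")) .STEPS else match.arg(step, .STEPS)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- NULL
  for (s in steps) {
    message("[guttag] step: ", s)
    out <- switch(s,
      simulate = .step_simulate(config, outdir),
      domains = .step_domains(config, outdir),
      qc = .step_qc(config, outdir),
      cluster = .step_cluster(config, outdir),
      css = .step_css(config, outdir),
      diff = .step_diff(config, outdir),
      enhancers = .step_enhancers(config, outdir),
      motifs = .step_motifs(config, outdir),
      bulk = .step_bulk(config, outdir),
      proportions = .step_proportions(config, outdir))
  }
  invisible(out)
}
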