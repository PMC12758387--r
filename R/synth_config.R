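# Configuration for the synthetic gut CUT&Tag world. Defaults emulate the
# statistical structure of the real experiment: three epithelial cell types
# whose H3K27me3 landscapes share canonical domains but differ in
# type-specific ones, polyploid enterocytes carrying ~3x more fragments per
# cell, a progenitor (ISC/EB) share that grows from ~22% of cells in young
# guts to ~52% in old guts, age-dependent domain gains and losses
# concentrated in enterocytes (enterocyte counts >> enteroendocrine >>
# ISC/EB), doublets, a blacklist artifact region, four bulk replicates per
# age with promoter-localized RNAPII-S5P signal, and an S-phase histone
# gene array whose promoters gain signal in the oldest age.

#' Configuration for the synthetic dataset generator
#'
#' All sizes are in bp and all per-cell parameters describe singlet cells;
#' doublets and blacklist-artifact cells are generated on top. See the
#' methods vignette for the rationale behind each default.
#'
#' @param seed Integer seed; the same config and seed give byte-identical
#'   outputs.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_genes Number of ordinary genes (markers included).
#' @param gene_length_range Min/max gene length.
#' @param histone_units Number of tandem histone repeat units; each unit
#'   carries one His1, His2A, His2B, His3 and His4 promoter.
#' @param n_enhancers Number of enhancers (500 bp each by default).
#' @param enhancer_width Enhancer width.
#' @param blacklist_width Width of the single blacklist artifact region.
#' @param cell_counts Matrix of singlet cell counts, rows = cell types
#'   (`ISC/EB`, `EE`, `EC`), columns = ages (`young`, `mid`, `old`).
#' @param depth_meanlog,depth_sdlog Lognormal fragment-count model for
#'   ISC/EB and EE singlets.
#' @param ec_depth_mult Depth multiplier for enterocytes (polyploidy).
#' @param fragment_length Fixed fragment length.
#' @param snr Fraction of a singlet's fragments drawn from its (type, age)
#'   domain set; the remainder is uniform over the genome.
#' @param doublet_rate Doublets emitted per singlet (0 <= r < 1).
#' @param artifact_rate Blacklist-artifact cells emitted per singlet.
#' @param artifact_bl_range Range of the planted blacklist fraction for
#'   artifact cells (all above the 0.2 QC cutoff).
#' @param shared_domains Number of domains shared by all three types.
#' @param type_domains Named vector: type-specific domain counts.
#' @param age_gain_genes,age_loss_genes Named vectors: number of genes per
#'   type that gain/lose repression with age (grouped into 1-2 gene
#'   domains). Defaults preserve the enterocyte >> enteroendocrine >>
#'   ISC/EB ordering of the real tissue.
#' @param weak_weight Named vector: relative sampling weight of a domain in
#'   its weak state (a gain domain before its onset age, a loss domain
#'   after its offset age). Age changes are graded, not on/off: gains are
#'   weak domains in young cells. Enterocytes change strongly enough to
#'   separate by age in clustering; the other types do not.
#' @param weight_jitter_shape Shape of the per-cell, per-domain Gamma
#'   weight jitter (mean 1) modelling variegated silencing; larger = less
#'   cell-to-cell variability. 0 disables jitter.
#' @param domain_pad Padding added around a domain's gene group.
#' @param bulk_reps Bulk replicates per age per antibody.
#' @param rnapii_base_meanlog,rnapii_base_sdlog Lognormal model for
#'   per-promoter RNAPII-S5P Poisson rates (identical across ages).
#' @param histone_rates Per-replicate Poisson rates for the five histone
#'   promoter classes (His2A/His2B highest, His1 lowest).
#' @param histone_fold Multiplicative old-age gain at histone promoters.
#' @param bulk_bg_frac Fraction of each bulk library drawn uniformly from
#'   the genome.
#' @param bulk_overdispersion Gamma overdispersion of bulk replicate rates
#'   (0 = pure Poisson).
#' @param pc_frac Fraction of promoters bound by Pc (age-constant rates).
#' @param pc_rate,pc_bg_rate Per-replicate Poisson rates at Pc-bound and
#'   unbound promoters.
#' @param igg_depth IgG fragments per replicate (uniform background).
#' @param promoter_halfwidth Promoters are TSS +/- this many bp.
#' @param motif_width,motif_consensus_prob Planted PWM shape.
#' @param motif_plant_fg,motif_plant_bg Fraction of age-changing (fg) and
#'   stable in-domain (bg) enhancers carrying the planted motif.
#' @param n_decoy_motifs Decoy PWMs written alongside the planted one.
#' @return A validated `SynthConfig` list.
#' @export
synth_config <- function(seed = 1L,
                         chrom_sizes = c(chr2L = 2e6, chr2R = 2e6),
                         n_genes = 400L,
                         gene_length_range = c(2000, 10000),
                         histone_units = 10L,
                         n_enhancers = 300L,
                         enhancer_width = 500L,
                         blacklist_width = 10000L,
                         cell_counts = rbind(
                           `ISC/EB` = c(young = 55L, mid = 75L, old = 130L),
                           EE       = c(young = 45L, mid = 45L, old = 45L),
                           EC       = c(young = 150L, mid = 130L, old = 75L)),
                         depth_meanlog = log(250),
                         depth_sdlog = 0.25,
                         ec_depth_mult = 3,
                         fragment_length = 150L,
                         snr = 0.8,
                         doublet_rate = 0.05,
                         artifact_rate = 0.02,
                         artifact_bl_range = c(0.3, 0.5),
                         shared_domains = 22L,
                         type_domains = c(`ISC/EB` = 6L, EE = 8L, EC = 12L),
                         age_gain_genes = c(`ISC/EB` = 1L, EE = 1L, EC = 12L),
                         age_loss_genes = c(`ISC/EB` = 1L, EE = 3L, EC = 9L),
                         weak_weight = c(`ISC/EB` = 0.35, EE = 0.35, EC = 0.1),
                         weight_jitter_shape = 4,
                         domain_pad = 400L,
                         bulk_reps = 4L,
                         rnapii_base_meanlog = log(20),
                         rnapii_base_sdlog = 1,
                         histone_rates = c(His1 = 8, His2A = 60, His2B = 60,
                                           His3 = 25, His4 = 25),
                         histone_fold = 10,
                         bulk_bg_frac = 0.1,
                         bulk_overdispersion = 0,
                         pc_frac = 0.2,
                         pc_rate = 40,
                         pc_bg_rate = 1,
                         igg_depth = 20000L,
                         promoter_halfwidth = 500L,
                         motif_width = 8L,
                         motif_consensus_prob = 0.85,
                         motif_plant_fg = 0.8,
                         motif_plant_bg = 0.05,
                         n_decoy_motifs = 4L) {
  cfg <- mget(names(formals()))
  class(cfg) <- "SynthConfig"
  validate_synth_config(cfg)
  cfg
}

#' Validate a SynthConfig
#' @param cfg SynthConfig.
#' @return TRUE invisibly; stops with an explanatory message otherwise.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  with(cfg, {
    if (!length(chrom_sizes) || is.null(names(chrom_sizes)) || any(chrom_sizes <= 0))
      stop("chrom_sizes must be a named vector of positive lengths")
    if (snr < 0 || snr > 1) stop("snr must be in [0, 1]")
    if (doublet_rate < 0 || doublet_rate >= 1) stop("doublet_rate must be in [0, 1)")
    if (artifact_rate < 0 || artifact_rate >= 1) stop("artifact_rate must be in [0, 1)")
    if (any(artifact_bl_range <= 0.2) || any(artifact_bl_range > 1))
      stop("artifact_bl_range must lie in (0.2, 1] so planted artifacts exceed the QC cutoff")
    types <- c("ISC/EB", "EE", "EC")
    if (!all(rownames(cell_counts) == types))
      stop("cell_counts rows must be ISC/EB, EE, EC")
    if (!all(colnames(cell_counts) == c("young", "mid", "old")))
      stop("cell_counts columns must be young, mid, old")
    if (any(cell_counts <= 0)) stop("cell_counts must be positive")
    for (t in types) {
      if (shared_domains + type_domains[[t]] <= 0)
        stop("empty domain set for type ", t,
             ": shared_domains + type_domains must be positive")
    }
    if (any(gene_length_range < 100) || gene_length_range[1] > gene_length_range[2])
      stop("bad gene_length_range")
    if (any(weak_weight <= 0) || any(weak_weight >= 1))
      stop("weak_weight must be in (0, 1)")
    if (weight_jitter_shape < 0) stop("weight_jitter_shape must be >= 0")
    if (histone_fold <= 0) stop("histone_fold must be positive")
    if (fragment_length < 1) stop("fragment_length must be >= 1")
  })
  invisible(TRUE)
}
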