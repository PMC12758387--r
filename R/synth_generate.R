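# Synthetic single-cell and bulk fragment data with planted ground truth.
# The layout (genes, domains, enhancers, promoters, sequence, rates) is a
# deterministic function of the config seed; fragment sampling uses derived
# seeds so single-cell and bulk draws are independent streams.

.TYPES <- c("ISC/EB", "EE", "EC")
.AGES <- c("young", "mid", "old")
.HIS_CLASSES <- c("His1", "His2A", "His2B", "His3", "His4")

# chunk a gene budget into domain group sizes of 1-2 genes
.chunk_sizes <- function(budget) {
  if (budget <= 0) return(integer())
  sizes <- rep(2L, budget %/% 2L)
  if (budget %% 2L) sizes <- c(sizes, 1L)
  sizes
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.consensus_pwm <- function(consensus, p) {
  bases <- c("A", "C", "G", "T")
  letters <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(letters),
              dimnames = list(bases, NULL))
  for (j in seq_along(letters)) m[letters[j], j] <- p
  m
}

# deterministic genome layout: everything except the fragment draws
.synth_layout <- function(cfg) {
  set.seed(cfg$seed)
  genome <- cfg$chrom_sizes
  flen <- cfg$fragment_length

  # reserved regions on the last chromosome: histone array and blacklist
  res_chrom <- names(genome)[length(genome)]
  slot <- 1200L
  his_start <- 40000L
  his_len <- cfg$histone_units * 5L * slot
  his_region <- data.frame(chrom = res_chrom, start = his_start,
                           end = his_start + his_len)
  bl_start <- as.integer(genome[[res_chrom]] - 50000L)
  blacklist <- data.frame(chrom = res_chrom, start = bl_start,
                          end = bl_start + cfg$blacklist_width)
  reserved <- rbind(his_region, blacklist)
  reserved$start <- reserved$start - 2000L
  reserved$end <- reserved$end + 2000L

  # ordinary genes: sequential placement with random lengths and gaps
  quota <- round(cfg$n_genes * genome / sum(genome))
  quota[length(quota)] <- cfg$n_genes - sum(quota[-length(quota)])
  genes <- list()
  gi <- 0L
  for (chrom in names(genome)) {
    pos <- 5000
    L <- genome[[chrom]]
    placed <- 0L
    res_here <- reserved[reserved$chrom == chrom, , drop = FALSE]
    while (placed < quota[[chrom]]) {
      len <- round(stats::runif(1, cfg$gene_length_range[1], cfg$gene_length_range[2]))
      hit <- which(res_here$start < pos + len & res_here$end > pos)
      if (length(hit)) {
        pos <- max(res_here$end[hit])
        next
      }
      if (pos + len > L - 5000) break
      gi <- gi + 1L
      placed <- placed + 1L
      genes[[gi]] <- data.frame(chrom = chrom, start = pos, end = pos + len,
                                name = sprintf("g%04d", gi),
                                strand = sample(c("+", "-"), 1))
      pos <- pos + len + round(stats::runif(1, 500, 4000))
    }
  }
  genes <- do.call(rbind, genes)

  # ---- domain groups over consecutive genes -----------------------------
  n_loss_dom <- vapply(.TYPES, function(t) length(.chunk_sizes(cfg$age_loss_genes[[t]])), integer(1))
  n_gain_dom <- vapply(.TYPES, function(t) length(.chunk_sizes(cfg$age_gain_genes[[t]])), integer(1))
  for (t in .TYPES) {
    if (cfg$type_domains[[t]] < n_loss_dom[[t]])
      stop("type_domains[", t, "] must be >= number of loss domains")
  }
  roles <- c(rep("shared", cfg$shared_domains),
             paste0("marker:", .TYPES),
             unlist(lapply(.TYPES, function(t)
               rep(paste0("stable:", t), cfg$type_domains[[t]] - n_loss_dom[[t]]))),
             unlist(lapply(.TYPES, function(t)
               rep(paste0("loss:", t), n_loss_dom[[t]]))),
             unlist(lapply(.TYPES, function(t)
               rep(paste0("gain:", t), n_gain_dom[[t]]))))
  sizes <- integer(length(roles))
  free_roles <- !grepl("^(loss|gain)", roles)
  sizes[grepl("^marker", roles)] <- 1L
  sizes[roles == "shared" | grepl("^stable", roles)] <-
    sample(1:2, sum(roles == "shared" | grepl("^stable", roles)), replace = TRUE)
  for (t in .TYPES) {
    sizes[roles == paste0("loss:", t)] <- .chunk_sizes(cfg$age_loss_genes[[t]])
    sizes[roles == paste0("gain:", t)] <- .chunk_sizes(cfg$age_gain_genes[[t]])
  }
  ord <- sample(seq_along(roles))
  roles <- roles[ord]; sizes <- sizes[ord]

  n_groups <- length(roles)
  if (sum(sizes) + n_groups > nrow(genes))
    stop("not enough genes to host the requested domains; increase n_genes")
  # walk the gene list, taking groups of consecutive same-chromosome genes
  group_genes <- vector("list", n_groups)
  i <- 1L
  for (g in seq_len(n_groups)) {
    s <- sizes[g]
    repeat {
      if (i + s - 1L > nrow(genes)) stop("ran out of genes while placing domains")
      if (length(unique(genes$chrom[i:(i + s - 1L)])) == 1L) break
      i <- i + 1L
    }
    group_genes[[g]] <- i:(i + s - 1L)
    i <- i + s + 1L + stats::rbinom(1, 2, 0.5)  # >=1 free separator gene
  }

  pad <- cfg$domain_pad
  domains <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    idx <- group_genes[[g]]
    data.frame(chrom = genes$chrom[idx[1]],
               start = max(0, min(genes$start[idx]) - pad),
               end = min(genome[[genes$chrom[idx[1]]]], max(genes$end[idx]) + pad),
               domain_id = sprintf("dom%03d", g),
               role = roles[g])
  }))

  # marker genes get their field names; low CSS in their own type is the
  # typing signal, so each marker domain is planted in the other two types
  marker_genes <- c(`ISC/EB` = "esg", EE = "Piezo", EC = "nub")
  for (t in .TYPES) {
    g <- which(domains$role == paste0("marker:", t))
    genes$name[group_genes[[g]]] <- marker_genes[[t]]
  }

  # onset/offset of age-dependent domains (enterocytes change at mid and
  # old; the other types change only in old age)
  domains$onset <- "young"
  domains$offset <- NA_character_
  for (t in .TYPES) {
    gains <- which(domains$role == paste0("gain:", t))
    losses <- which(domains$role == paste0("loss:", t))
    if (t == "EC") {
      half_g <- seq_len(ceiling(length(gains) / 2))
      domains$onset[gains[half_g]] <- "mid"
      domains$onset[gains[-half_g]] <- "old"
      half_l <- seq_len(ceiling(length(losses) / 2))
      domains$offset[losses[half_l]] <- "mid"
      domains$offset[losses[-half_l]] <- "old"
    } else {
      domains$onset[gains] <- "old"
      domains$offset[losses] <- "old"
    }
  }

  # planted per-(type, age) interval sets
  age_rank <- stats::setNames(seq_along(.AGES), .AGES)
  domain_sets <- lapply(.TYPES, function(t) {
    others <- setdiff(.TYPES, t)
    base <- domains$role %in% c("shared",
                                paste0("stable:", t), paste0("loss:", t),
                                paste0("gain:", t),
                                paste0("marker:", others))
    stats::setNames(lapply(.AGES, function(a) {
      # age changes are graded: a gain domain is weak before its onset age
      # and a loss domain is weak from its offset age on; within base only
      # gain:t / loss:t carry a non-young onset / non-NA offset
      weak <- (age_rank[domains$onset] > age_rank[[a]]) |
        (!is.na(domains$offset) & age_rank[domains$offset] <= age_rank[[a]])
      out <- domains[base, c("chrom", "start", "end", "domain_id", "role")]
      out$weight <- ifelse(weak[base], cfg$weak_weight[[t]], 1)
      out
    }), .AGES)
  })
  names(domain_sets) <- .TYPES

  # planted differential gene sets (signed)
  diff_genes <- do.call(rbind, lapply(.TYPES, function(t) {
    rows <- lapply(c("gain", "loss"), function(dir) {
      gs <- which(domains$role == paste0(dir, ":", t))
      if (!length(gs)) return(NULL)
      data.frame(type = t,
                 gene = genes$name[unlist(group_genes[gs])],
                 direction = dir)
    })
    do.call(rbind, rows)
  }))

  # ---- histone array ----------------------------------------------------
  his <- do.call(rbind, lapply(seq_len(cfg$histone_units), function(u) {
    base <- his_start + (u - 1L) * 5L * slot
    data.frame(chrom = res_chrom,
               start = base + (seq_len(5L) - 1L) * slot + 100L,
               end = base + (seq_len(5L) - 1L) * slot + 100L + 1000L,
               name = sprintf("%s_u%02d", .HIS_CLASSES, u),
               class = .HIS_CLASSES)
  }))

  # ---- promoters (TSS +/- halfwidth) ------------------------------------
  hw <- cfg$promoter_halfwidth
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  promoters <- data.frame(chrom = genes$chrom,
                          start = pmax(0, tss - hw),
                          end = pmin(genome[genes$chrom], tss + hw),
                          name = genes$name,
                          class = "gene")
  promoters <- rbind(promoters, his[, c("chrom", "start", "end", "name", "class")])
  rownames(promoters) <- NULL

  # per-promoter RNAPII-S5P Poisson rates (per replicate); identical across
  # ages except the histone_fold gain at histone promoters in old age
  base_rate <- stats::rlnorm(nrow(promoters), cfg$rnapii_base_meanlog,
                             cfg$rnapii_base_sdlog)
  is_his <- promoters$class != "gene"
  base_rate[is_his] <- cfg$histone_rates[promoters$class[is_his]]
  rates <- matrix(base_rate, nrow = nrow(promoters), ncol = 3,
                  dimnames = list(promoters$name, .AGES))
  rates[is_his, "old"] <- rates[is_his, "old"] * cfg$histone_fold

  pc_bound <- stats::rbinom(nrow(promoters), 1, cfg$pc_frac) == 1

  # ---- enhancers --------------------------------------------------------
  ew <- cfg$enhancer_width
  place_in <- function(iv, k) {
    off <- floor(stats::runif(k, 0, pmax(1, iv$end - iv$start - ew)))
    data.frame(chrom = iv$chrom, start = iv$start + off,
               end = iv$start + off + ew)
  }
  chg_rows <- which(grepl("^(gain|loss):", domains$role))
  chg <- do.call(rbind, lapply(chg_rows, function(r) {
    t <- sub("^(gain|loss):", "", domains$role[r])
    k <- if (t == "EC") 2L else 1L
    cbind(place_in(domains[r, ], k),
          status = paste0("changing_", sub(":.*", "", domains$role[r])),
          type = t)
  }))
  stable_rows <- which(domains$role == "shared" | grepl("^stable:", domains$role))
  n_stable_enh <- min(60L, cfg$n_enhancers - nrow(chg))
  pick <- sample(stable_rows, n_stable_enh, replace = TRUE)
  stab <- cbind(place_in(domains[pick, ], n_stable_enh),
                status = "stable_domain", type = NA_character_)
  n_bg <- cfg$n_enhancers - nrow(chg) - n_stable_enh
  avoid <- rbind(his_region, blacklist)
  bg_list <- list()
  while (length(bg_list) < n_bg) {
    chrom <- sample(names(genome), 1, prob = genome)
    s <- floor(stats::runif(1, 0, genome[[chrom]] - ew))
    if (any(avoid$chrom == chrom & avoid$start < s + ew & avoid$end > s)) next
    bg_list[[length(bg_list) + 1L]] <-
      data.frame(chrom = chrom, start = s, end = s + ew,
                 status = "background", type = NA_character_)
  }
  enhancers <- rbind(chg, stab, do.call(rbind, bg_list))
  enhancers$name <- sprintf("enh%04d", seq_len(nrow(enhancers)))
  rownames(enhancers) <- NULL

  # ---- motif planting ---------------------------------------------------
  w <- cfg$motif_width
  bases <- c("A", "C", "G", "T")
  consensus <- paste(sample(bases, w, replace = TRUE), collapse = "")
  planted_pwm <- .consensus_pwm(consensus, cfg$motif_consensus_prob)
  decoys <- lapply(seq_len(cfg$n_decoy_motifs), function(i)
    .consensus_pwm(paste(sample(bases, w, replace = TRUE), collapse = ""),
                   cfg$motif_consensus_prob))
  motifs <- c(list(planted_pwm), decoys)
  names(motifs) <- c("planted_TF", sprintf("decoy_TF%d", seq_len(cfg$n_decoy_motifs)))

  is_fg <- grepl("^changing", enhancers$status)
  plant <- logical(nrow(enhancers))
  plant[is_fg] <- stats::runif(sum(is_fg)) < cfg$motif_plant_fg
  is_bg_dom <- enhancers$status == "stable_domain"
  plant[is_bg_dom] <- stats::runif(sum(is_bg_dom)) < cfg$motif_plant_bg
  enhancers$motif_planted <- plant
  enhancers$motif_offset <- NA_integer_
  enhancers$motif_strand <- NA_character_
  enhancers$motif_offset[plant] <- as.integer((ew - w) %/% 2)
  enhancers$motif_strand[plant] <- sample(c("+", "-"), sum(plant), replace = TRUE)

  # ---- genome sequence with planted sites -------------------------------
  seqs <- lapply(genome, function(L) .rand_dna(L))
  for (i in which(plant)) {
    site <- if (enhancers$motif_strand[i] == "+") consensus else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
    p0 <- enhancers$start[i] + enhancers$motif_offset[i]
    chrom <- enhancers$chrom[i]
    substr(seqs[[chrom]], p0 + 1L, p0 + w) <- site
  }
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- names(genome)

  list(genome = genome, genes = genes, domains = domains,
       domain_sets = domain_sets, diff_genes = diff_genes,
       promoters = promoters, promoter_rates = rates, pc_bound = pc_bound,
       histone = his, enhancers = enhancers, blacklist = blacklist,
       motifs = motifs, motif_consensus = consensus,
       marker_genes = marker_genes, sequences = sequences)
}

# sample n fragment intervals from an interval set, by width times an
# optional per-interval weight
.sample_in_intervals <- function(iv, n, flen, genome, weight = NULL) {
  if (n <= 0) return(NULL)
  wd <- iv$end - iv$start
  pr <- if (is.null(weight)) wd else wd * weight
  k <- sample.int(nrow(iv), n, replace = TRUE, prob = pr)
  s <- iv$start[k] + floor(stats::runif(n) * wd[k])
  e <- pmin(s + flen, genome[iv$chrom[k]])
  data.frame(chrom = iv$chrom[k], start = s, end = e)
}

.sample_uniform <- function(n, flen, genome) {
  if (n <= 0) return(NULL)
  chrom <- sample(names(genome), n, replace = TRUE, prob = genome)
  s <- floor(stats::runif(n) * (genome[chrom] - flen))
  data.frame(chrom = chrom, start = s, end = s + flen)
}

# fragments of one singlet-style draw
.draw_cell <- function(type, age, layout, cfg, depth = NULL) {
  meanlog <- cfg$depth_meanlog + if (type == "EC") log(cfg$ec_depth_mult) else 0
  if (is.null(depth)) depth <- max(10L, round(stats::rlnorm(1, meanlog, cfg$depth_sdlog)))
  n_in <- round(cfg$snr * depth)
  iv <- layout$domain_sets[[type]][[age]]
  w <- iv$weight
  if (cfg$weight_jitter_shape > 0) {
    # variegated silencing: per-cell, per-domain intensity jitter (mean 1)
    sh <- cfg$weight_jitter_shape
    w <- w * stats::rgamma(nrow(iv), shape = sh, scale = 1 / sh)
  }
  frag <- rbind(.sample_in_intervals(iv, n_in, cfg$fragment_length, layout$genome, w),
                .sample_uniform(depth - n_in, cfg$fragment_length, layout$genome))
  list(frag = frag, depth = depth)
}

#' Generate the synthetic single-cell dataset
#'
#' Singlet counts per (type, age) are taken verbatim from
#' `cfg$cell_counts`; doublets (merged draws of two random cells of the
#' same age, pair types proportional to type frequencies) and
#' blacklist-artifact cells are emitted on top and flagged in the truth.
#'
#' @param cfg A [synth_config()].
#' @return List with `fragments` (a [fragment_set()] labelled by cell
#'   barcode) and `truth` (a `SynthTruth` list: per-cell truth table,
#'   planted domains and per-(type, age) interval sets, differential gene
#'   sets, enhancer/motif truth, promoter rates, annotations).
#' @export
generate_single_cell <- function(cfg) {
  validate_synth_config(cfg)
  layout <- .synth_layout(cfg)
  set.seed(cfg$seed + 1L)
  cells <- list(); frags <- list(); ci <- 0L

  for (age in .AGES) {
    counts <- cfg$cell_counts[, age]
    freq <- counts / sum(counts)
    for (type in .TYPES) {
      for (j in seq_len(counts[[type]])) {
        d <- .draw_cell(type, age, layout, cfg)
        ci <- ci + 1L
        frags[[ci]] <- d$frag
        cells[[ci]] <- data.frame(type = type, age = age, is_doublet = FALSE,
                                  is_artifact = FALSE, depth = d$depth,
                                  planted_bl_fraction = 0,
                                  doublet_types = NA_character_)
      }
    }
    n_singlets <- sum(counts)
    # doublets: two independent draws merged under one barcode
    for (j in seq_len(round(cfg$doublet_rate * n_singlets))) {
      pair <- sample(.TYPES, 2L, replace = TRUE, prob = freq)
      d1 <- .draw_cell(pair[1], age, layout, cfg)
      d2 <- .draw_cell(pair[2], age, layout, cfg)
      ci <- ci + 1L
      frags[[ci]] <- rbind(d1$frag, d2$frag)
      cells[[ci]] <- data.frame(type = NA_character_, age = age,
                                is_doublet = TRUE, is_artifact = FALSE,
                                depth = d1$depth + d2$depth,
                                planted_bl_fraction = 0,
                                doublet_types = paste(sort(pair), collapse = "+"))
    }
    # blacklist-artifact cells: a planted fraction of fragments from the
    # blacklist region, always above the 0.2 QC cutoff
    for (j in seq_len(round(cfg$artifact_rate * n_singlets))) {
      type <- sample(.TYPES, 1L, prob = freq)
      meanlog <- cfg$depth_meanlog + if (type == "EC") log(cfg$ec_depth_mult) else 0
      depth <- max(10L, round(stats::rlnorm(1, meanlog, cfg$depth_sdlog)))
      blf <- stats::runif(1, cfg$artifact_bl_range[1], cfg$artifact_bl_range[2])
      n_bl <- max(ceiling(0.21 * depth), round(blf * depth))
      d <- .draw_cell(type, age, layout, cfg, depth = depth - n_bl)
      ci <- ci + 1L
      frags[[ci]] <- rbind(d$frag,
                           .sample_in_intervals(layout$blacklist, n_bl,
                                                cfg$fragment_length, layout$genome))
      cells[[ci]] <- data.frame(type = type, age = age, is_doublet = FALSE,
                                is_artifact = TRUE, depth = depth,
                                planted_bl_fraction = n_bl / depth,
                                doublet_types = NA_character_)
    }
  }

  # opaque barcodes in shuffled order; replicate = source chip (2 chips)
  perm <- sample(ci)
  barcodes <- sprintf("bc%05d", seq_len(ci))
  cell_df <- do.call(rbind, cells)[perm, , drop = FALSE]
  cell_df <- cbind(barcode = barcodes, cell_df)
  cell_df$replicate <- sample(c("chip1", "chip2"), ci, replace = TRUE)
  rownames(cell_df) <- NULL

  frag_df <- do.call(rbind, frags[perm])
  frag_df$label <- rep(barcodes, vapply(frags[perm], nrow, integer(1)))
  fragments <- fragment_set(frag_df, layout$genome)

  truth <- structure(list(
    cells = cell_df,
    domains = layout$domains,
    domain_sets = layout$domain_sets,
    all_domains = merge_intervals(list(do.call(
      rbind, lapply(.TYPES, function(t) do.call(
        rbind, lapply(layout$domain_sets[[t]], function(d)
          d[, c("chrom", "start", "end")])))))),
    diff_genes = layout$diff_genes,
    genes = layout$genes,
    promoters = layout$promoters,
    promoter_rates = layout$promoter_rates,
    pc_bound = layout$pc_bound,
    histone = layout$histone,
    enhancers = layout$enhancers,
    blacklist = layout$blacklist,
    motifs = layout$motifs,
    motif_consensus = layout$motif_consensus,
    marker_genes = layout$marker_genes,
    sequences = layout$sequences,
    genome = layout$genome
  ), class = "SynthTruth")

  list(fragments = fragments, truth = truth)
}

#' Generate synthetic bulk fragment replicates
#'
#' One FragmentSet per replicate per age. `RNAPIIS5P` draws Poisson counts
#' per promoter from the age's rate vector (histone promoters multiplied by
#' `histone_fold` in old age); `Pc` puts age-constant peaks on the
#' Pc-bound promoter subset; `IgG` is uniform background.
#'
#' @param cfg A [synth_config()].
#' @param antibody One of "RNAPIIS5P", "Pc", "IgG".
#' @return Named list of [fragment_set()]s (`<age>_rep<k>`), with a `meta`
#'   attribute (age, replicate per element).
#' @export
generate_bulk <- function(cfg, antibody = c("RNAPIIS5P", "Pc", "IgG")) {
  antibody <- match.arg(antibody)
  validate_synth_config(cfg)
  layout <- .synth_layout(cfg)
  set.seed(cfg$seed + 1L + match(antibody, c("RNAPIIS5P", "Pc", "IgG")))
  genome <- layout$genome
  prom <- layout$promoters
  flen <- cfg$fragment_length
  out <- list(); meta <- list()
  for (age in .AGES) {
    for (r in seq_len(cfg$bulk_reps)) {
      if (antibody == "IgG") {
        frag <- .sample_uniform(stats::rpois(1, cfg$igg_depth), flen, genome)
      } else {
        rates <- if (antibody == "RNAPIIS5P") layout$promoter_rates[, age] else
          ifelse(layout$pc_bound, cfg$pc_rate, cfg$pc_bg_rate)
        if (cfg$bulk_overdispersion > 0) {
          od <- cfg$bulk_overdispersion
          rates <- rates * stats::rgamma(length(rates), shape = 1 / od, scale = od)
        }
        k <- stats::rpois(length(rates), rates)
        idx <- rep(seq_along(k), k)
        wd <- prom$end[idx] - prom$start[idx]
        s <- prom$start[idx] + floor(stats::runif(length(idx)) * wd)
        frag <- data.frame(chrom = prom$chrom[idx], start = s,
                           end = pmin(s + flen, genome[prom$chrom[idx]]))
        n_bg <- round(cfg$bulk_bg_frac * sum(k))
        frag <- rbind(frag, .sample_uniform(n_bg, flen, genome))
      }
      nm <- sprintf("%s_rep%d", age, r)
      frag$label <- nm
      out[[nm]] <- fragment_set(frag, genome)
      meta[[nm]] <- data.frame(sample = nm, age = age, replicate = r)
    }
  }
  structure(out, meta = do.call(rbind, meta), antibody = antibody)
}
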