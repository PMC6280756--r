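# Seeded generator for a complete toy regeneration study: genome and gene
# models, FPKM tables with planted fold changes and genomic clustering of
# up-regulated genes, replicate ATAC peak sets with planted emerging and
# increasing regions, reference open-region collections, ChIP features,
# conservation tracks and species alignment masks, ortholog maps with a
# planted cross-species core, a zebrafish arm, and qPCR tables -- together
# with the truth bundle that every pipeline stage can be scored against.
#
# Planted effect sizes deliberately clear the calling thresholds with
# margin (DE fold >= 2 vs the 1.7 rule; accessibility fold >= 2 vs 1.5)
# so that recovery of the planted labels is deterministic.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the statistical structure of a damage-response
#' regeneration study at desk scale: two chromosomes, two replicates,
#' three timepoints, mostly up-regulated DE genes, a small emerging
#' fraction among damage-responsive regions, and a planted cross-species
#' regeneration core.
#'
#' @param seed master seed; each data layer derives its own stream from it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes total fly genes (split evenly across chromosomes).
#' @param de_fraction fraction of genes differentially expressed at early.
#' @param up_fraction fraction of DE genes that are up-regulated.
#' @param de_fold_meanlog,de_fold_sdlog,de_fold_min log-normal planted DE
#'   fold distribution, floored at `de_fold_min`.
#' @param rep_noise_sdlog replicate-level multiplicative noise (log sd).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline FPKM.
#' @param n_planted_clusters,genes_per_cluster,cluster_gene_spacing
#'   chromosomal clusters of up-regulated genes (all members fit in one
#'   30-kb window at the default spacing).
#' @param n_background_peaks,n_increasing,n_emerging planted ATAC regions.
#' @param peak_width peak width in bp.
#' @param increasing_fold_min,increasing_fold_max planted accessibility
#'   fold for increasing regions.
#' @param background_jitter per-replicate multiplicative height jitter for
#'   background peaks (keeps cross-condition folds below 1.2).
#' @param reused_fraction fraction of emerging regions copied into the
#'   reference open sets.
#' @param chip_marked_fraction_increasing,chip_marked_fraction_emerging
#'   fractions of each DRRE class carrying active-enhancer features.
#' @param n_species alignment masks / species count.
#' @param ortholog_density fraction of non-core fly genes with orthologs.
#' @param n_core_genes planted regeneration-core size.
#' @param starr_fraction fraction of DRREs overlapping activity regions.
#' @param zf_chrom_length,n_zf_genes,n_zf_emerging,n_zf_increasing,
#'   zf_reused_fraction zebrafish arm shape.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 2e6,
                       n_genes = 400,
                       de_fraction = 0.08, up_fraction = 0.9,
                       de_fold_meanlog = log(2.5), de_fold_sdlog = 0.2,
                       de_fold_min = 2,
                       rep_noise_sdlog = 0.05,
                       baseline_meanlog = log(10), baseline_sdlog = 1,
                       n_planted_clusters = 3, genes_per_cluster = 5,
                       cluster_gene_spacing = 3000,
                       n_background_peaks = 120, n_increasing = 360,
                       n_emerging = 24,
                       peak_width = 400,
                       increasing_fold_min = 2, increasing_fold_max = 3,
                       background_jitter = 0.08,
                       reused_fraction = 0.58,
                       chip_marked_fraction_increasing = 0.8,
                       chip_marked_fraction_emerging = 0.63,
                       n_species = 10,
                       ortholog_density = 0.5,
                       n_core_genes = 12,
                       starr_fraction = 0.4,
                       zf_chrom_length = 1e6, n_zf_genes = 40,
                       n_zf_emerging = 30, n_zf_increasing = 20,
                       zf_reused_fraction = 0.8) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_genes > 0,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$reused_fraction >= 0, cfg$reused_fraction <= 1,
            cfg$n_emerging >= 0, cfg$n_increasing >= 0,
            cfg$n_background_peaks >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# layer-specific RNG stream derived from the master seed
layer_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 20011 + k * 7919) %% 2147483647)
}

with_layer_seed <- function(seed, k, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(layer_seed(seed, k))
  force(code)
}

CELL <- 10000L  # genome layout grid in bp

# -- genome / gene layer -----------------------------------------------------

sim_genome <- function(cfg) {
  data.frame(chrom = sprintf("chr%d", seq_len(cfg$n_chroms)),
             length = rep(cfg$chrom_length, cfg$n_chroms),
             stringsAsFactors = FALSE)
}

# one gene with 1-3 transcripts inside [pos, pos + body) on a random strand
make_gene <- function(gene_id, chrom, pos, body, strand, n_tx) {
  # split the body into 2 exons with an intron in the middle third
  e1_len <- max(200L, as.integer(body * 0.3))
  intron_len <- max(150L, as.integer(body * 0.3))
  e2_start <- pos + e1_len + intron_len
  e2_end <- pos + body
  exons <- data.frame(start = c(pos, e2_start), end = c(pos + e1_len, e2_end))
  txs <- list(t1 = exons)
  if (n_tx >= 2) txs$t2 <- exons  # same structure, annotated isoform
  if (n_tx >= 3) txs$t3 <- data.frame(start = exons$start[1],
                                      end = exons$end[1])  # short isoform
  gene_model(gene_id, chrom, strand, txs)
}

sim_genes <- function(cfg) {
  with_layer_seed(cfg$seed, 1, {
    genome <- sim_genome(cfg)
    per_chrom <- cfg$n_genes %/% cfg$n_chroms
    n_cells <- as.integer(cfg$chrom_length %/% CELL)
    genes <- list()
    cluster_truth <- list()
    cluster_cells <- list()
    for (ci in seq_len(cfg$n_chroms)) {
      ch <- genome$chrom[ci]
      # planted cluster anchor cells on chromosome 1 only, well separated
      anchors <- integer(0)
      if (ci == 1 && cfg$n_planted_clusters > 0) {
        cand <- seq(10, n_cells - 10, by = max(12, (n_cells - 20) %/%
                                                 max(1, cfg$n_planted_clusters)))
        anchors <- cand[seq_len(min(cfg$n_planted_clusters, length(cand)))]
      }
      occupied <- unlist(lapply(anchors, function(a) a + 0:1))
      cluster_cells[[ch]] <- occupied
      gi <- 0L
      for (a in anchors) {
        base <- (a - 1L) * CELL
        mem <- character(0)
        for (k in seq_len(cfg$genes_per_cluster)) {
          gi <- gi + 1L
          id <- sprintf("%s_g%03d", ch, gi)
          pos <- base + (k - 1L) * cfg$cluster_gene_spacing
          genes[[id]] <- make_gene(id, ch, pos, 1500L, "+", 1L)
          mem <- c(mem, id)
        }
        cluster_truth[[length(cluster_truth) + 1L]] <-
          list(chrom = ch, anchor_cell = a, members = mem)
      }
      free_cells <- setdiff(seq_len(n_cells), occupied)
      n_more <- per_chrom - gi
      for (cell in free_cells[seq_len(max(0, n_more))]) {
        gi <- gi + 1L
        id <- sprintf("%s_g%03d", ch, gi)
        pos <- (cell - 1L) * CELL + sample.int(2000L, 1)
        body <- sample(1500:3500, 1)
        strand <- sample(c("+", "-"), 1)
        genes[[id]] <- make_gene(id, ch, pos, body, strand, sample(1:3, 1))
      }
    }
    list(genes = genes, clusters = cluster_truth, cluster_cells = cluster_cells)
  })
}

# -- expression layer --------------------------------------------------------

sim_expression <- function(cfg, gene_layer) {
  with_layer_seed(cfg$seed, 2, {
    ids <- names(gene_layer$genes)
    n <- length(ids)
    cluster_members <- unlist(lapply(gene_layer$clusters, `[[`, "members"))
    tssd <- gene_tss(gene_layer$genes)

    # scattered DE genes stay >= 40 kb away from planted cluster spans so
    # that cluster-member recovery is unambiguous
    spans <- lapply(gene_layer$clusters, function(cl) {
      m <- tssd[tssd$gene_id %in% cl$members, ]
      list(chrom = cl$chrom, lo = min(m$tss) - 40000, hi = max(m$tss) + 40000)
    })
    far_from_clusters <- vapply(seq_len(n), function(i) {
      for (sp in spans)
        if (tssd$chrom[i] == sp$chrom && tssd$tss[i] >= sp$lo &&
            tssd$tss[i] <= sp$hi) return(FALSE)
      TRUE
    }, logical(1))

    n_de <- max(0L, round(cfg$de_fraction * n) - length(cluster_members))
    pool <- setdiff(ids[far_from_clusters], cluster_members)
    scattered <- sample(pool, min(n_de, length(pool)))
    n_up_scatter <- round(cfg$up_fraction * length(scattered))
    scatter_dir <- c(rep("up", n_up_scatter),
                     rep("down", length(scattered) - n_up_scatter))

    de_early <- data.frame(gene_id = c(cluster_members, scattered),
                           direction = c(rep("up", length(cluster_members)),
                                         scatter_dir),
                           stringsAsFactors = FALSE)
    de_early$timepoint <- "early"
    up_early <- de_early$gene_id[de_early$direction == "up"]
    mid_ids <- sample(up_early, round(0.3 * length(up_early)))
    late_ids <- sample(mid_ids, max(0, round(0.3 * length(mid_ids))))
    de <- rbind(de_early,
                data.frame(gene_id = mid_ids, direction = "up",
                           timepoint = "mid", stringsAsFactors = FALSE),
                data.frame(gene_id = late_ids, direction = "up",
                           timepoint = "late", stringsAsFactors = FALSE))
    fold <- pmax(cfg$de_fold_min,
                 stats::rlnorm(nrow(de), cfg$de_fold_meanlog, cfg$de_fold_sdlog))
    de$fold <- fold

    baseline <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    names(baseline) <- ids
    expr <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
    for (cond in CONDITIONS) for (tp in TIMEPOINTS) for (r in 1:2) {
      eff <- rep(1, n)
      if (cond == "regeneration") {
        d <- de[de$timepoint == tp, , drop = FALSE]
        idx <- match(d$gene_id, ids)
        eff[idx] <- ifelse(d$direction == "up", d$fold, 1 / d$fold)
      }
      noise <- exp(stats::rnorm(n, 0, cfg$rep_noise_sdlog))
      expr[[paste(cond, tp, r, sep = "_")]] <-
        round(baseline * eff * noise, 4)
    }
    list(expression = expr, de = de)
  })
}

# -- peak / track layer ------------------------------------------------------

# free peak slots: two per grid cell, avoiding cluster cells
peak_slots <- function(cfg, gene_layer) {
  genome <- sim_genome(cfg)
  n_cells <- as.integer(cfg$chrom_length %/% CELL)
  slots <- NULL
  for (ch in genome$chrom) {
    skip <- gene_layer$cluster_cells[[ch]]
    cells <- setdiff(seq_len(n_cells), skip)
    slots <- rbind(slots,
                   data.frame(chrom = ch,
                              start = rep((cells - 1L) * CELL, each = 2) +
                                c(6000L, 8000L),
                              stringsAsFactors = FALSE))
  }
  slots$end <- slots$start + cfg$peak_width
  slots
}

peak_df <- function(chrom, start, end, name, summit, height) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, score = 0, strand = ".",
             summit = as.integer(summit), height = height,
             stringsAsFactors = FALSE)
}

track_from_steps <- function(steps) {
  validate_track(steps)
}

# fill the gaps of `elevated` with `base_value` across each chromosome
fill_track <- function(elevated, genome, base_value) {
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    len <- as.integer(genome$length[i])
    e <- elevated[elevated$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    gap_start <- c(0L, e$end)
    gap_end <- c(e$start, len)
    ok <- gap_end > gap_start
    rbind(data.frame(chrom = ch, start = gap_start[ok], end = gap_end[ok],
                     value = base_value, stringsAsFactors = FALSE),
          e[, c("chrom", "start", "end", "value"), drop = FALSE])
  })
  validate_track(do.call(rbind, rows))
}

sim_peaks <- function(cfg, gene_layer) {
  with_layer_seed(cfg$seed, 3, {
    genome <- sim_genome(cfg)
    slots <- peak_slots(cfg, gene_layer)
    need <- cfg$n_background_peaks + cfg$n_increasing + cfg$n_emerging
    if (need > nrow(slots))
      stop("cannot place ", need, " non-overlapping peaks: only ",
           nrow(slots), " slots available; reduce counts or enlarge the genome",
           call. = FALSE)
    idx <- sample.int(nrow(slots), need)
    take <- slots[idx, , drop = FALSE]
    kind <- rep(c("background", "increasing", "emerging"),
                c(cfg$n_background_peaks, cfg$n_increasing, cfg$n_emerging))
    take$kind <- kind
    take$name <- sprintf("%s_%03d", c(background = "bg", increasing = "inc",
                                      emerging = "emg")[kind],
                         stats::ave(seq_len(need), kind, FUN = seq_along))
    take$summit <- as.integer(take$start + cfg$peak_width %/% 2)
    base_h <- stats::rlnorm(need, log(20), 0.3)
    inc_fold <- stats::runif(need, cfg$increasing_fold_min, cfg$increasing_fold_max)
    jit <- function() stats::runif(need, 1 - cfg$background_jitter,
                                   1 + cfg$background_jitter)

    mk <- function(sel, heights) {
      peak_df(take$chrom[sel], take$start[sel], take$end[sel], take$name[sel],
              take$summit[sel], heights[sel])
    }
    in_ctl <- take$kind != "emerging"
    in_reg <- rep(TRUE, need)
    ctl_h <- base_h
    reg_h <- ifelse(take$kind == "increasing", base_h * inc_fold, base_h)

    atac <- list(
      control = list(rep1 = mk(in_ctl, ctl_h * jit()),
                     rep2 = mk(in_ctl, ctl_h * jit())),
      regeneration = list(rep1 = mk(in_reg, reg_h * jit()),
                          rep2 = mk(in_reg, reg_h * jit())),
      l3 = list(rep1 = mk(in_ctl, ctl_h * jit()),
                rep2 = mk(in_ctl, ctl_h * jit())))
    atac <- lapply(atac, function(s) lapply(s, sort_regions))

    tracks <- list(
      control = fill_track(
        {e <- mk(in_ctl, ctl_h); data.frame(chrom = e$chrom, start = e$start,
                                            end = e$end, value = e$height)},
        genome, 0),
      regeneration = fill_track(
        {e <- mk(in_reg, reg_h); data.frame(chrom = e$chrom, start = e$start,
                                            end = e$end, value = e$height)},
        genome, 0))
    tracks <- lapply(tracks, function(t) t[t$value > 0, , drop = FALSE])

    drre_truth <- take[take$kind != "background",
                       c("name", "chrom", "start", "end", "summit", "kind")]
    names(drre_truth)[6] <- "drre_class"
    drre_truth$drre_class <- ifelse(drre_truth$drre_class == "emerging",
                                    "emerging", "increasing")
    rownames(drre_truth) <- NULL
    list(atac = atac, tracks = lapply(tracks, validate_track),
         drre = drre_truth, slots_used = take,
         slots_free = slots[-idx, , drop = FALSE])
  })
}

# -- reference open sets, ChIP, conservation, masks, activity ----------------

REF_LABELS <- data.frame(
  label = c("embryo_2_4h", "embryo_6_8h", "embryo_16_18h",
            "L3_cns", "L3_eye_antenna", "L3_haltere", "L3_leg",
            "pharate_haltere", "pharate_leg", "pharate_wing"),
  stage = c("embryo", "embryo", "embryo", "L3", "L3", "L3", "L3",
            "pharate", "pharate", "pharate"),
  tissue = c("whole", "whole", "whole", "cns", "eye_antenna", "haltere",
             "leg", "haltere", "leg", "wing"),
  stringsAsFactors = FALSE)

sim_refs <- function(cfg, peak_layer) {
  with_layer_seed(cfg$seed, 4, {
    emg <- peak_layer$drre[peak_layer$drre$drre_class == "emerging", , drop = FALSE]
    n_reused <- round(cfg$reused_fraction * nrow(emg))
    reused <- if (nrow(emg)) emg[sample.int(nrow(emg), n_reused), , drop = FALSE]
              else emg
    free <- peak_layer$slots_free
    refs <- list()
    for (lab in REF_LABELS$label) refs[[lab]] <- empty_regions()
    # each reused emerging region is copied into 1-3 reference sets
    if (nrow(reused)) for (i in seq_len(nrow(reused))) {
      labs <- sample(REF_LABELS$label, sample(1:3, 1))
      for (lab in labs)
        refs[[lab]] <- rbind(refs[[lab]],
                             data.frame(chrom = reused$chrom[i],
                                        start = reused$start[i],
                                        end = reused$end[i]))
    }
    # filler intervals from unused slots (never overlap planted regions)
    for (lab in REF_LABELS$label) {
      k <- min(10, nrow(free))
      if (k > 0) {
        pick <- free[sample.int(nrow(free), k), , drop = FALSE]
        refs[[lab]] <- rbind(refs[[lab]],
                             pick[, c("chrom", "start", "end"), drop = FALSE])
      }
      refs[[lab]] <- merge_intervals(refs[[lab]])
    }
    list(refs = refs,
         reused = sort(reused$name),
         usage = data.frame(name = emg$name,
                            usage = ifelse(emg$name %in% reused$name,
                                           "reused", "novel"),
                            stringsAsFactors = FALSE))
  })
}

CHIP_FEATURES <- c("H3K4me1", "H3K27ac", "PolII")

sim_chip <- function(cfg, peak_layer) {
  with_layer_seed(cfg$seed, 5, {
    genome <- sim_genome(cfg)
    drre <- peak_layer$drre
    flat <- data.frame(chrom = genome$chrom, start = 0L,
                       end = as.integer(genome$length), value = 1)
    marked <- character(0)
    for (cls in c("increasing", "emerging")) {
      d <- drre[drre$drre_class == cls, , drop = FALSE]
      frac <- if (cls == "increasing") cfg$chip_marked_fraction_increasing
              else cfg$chip_marked_fraction_emerging
      k <- round(frac * nrow(d))
      if (k > 0) marked <- c(marked, d$name[sample.int(nrow(d), k)])
    }
    feats <- stats::setNames(vector("list", length(CHIP_FEATURES)), CHIP_FEATURES)
    feature_of <- list()
    for (nm in marked) {
      chosen <- sample(CHIP_FEATURES, sample(1:3, 1))
      feature_of[[nm]] <- chosen
    }
    for (f in CHIP_FEATURES) {
      rows <- drre[drre$name %in% names(feature_of)[vapply(
        feature_of, function(ch) f %in% ch, logical(1))], , drop = FALSE]
      feats[[f]] <- list(
        reg_peaks = if (nrow(rows))
          rows[order(rows$chrom, rows$start), c("chrom", "start", "end")]
          else empty_regions(),
        reg_track = flat, ctl_track = flat)
    }
    list(chip = feats, marked = sort(marked),
         activity = data.frame(
           name = drre$name,
           activity = ifelse(drre$name %in% marked, "presence", "absence"),
           stringsAsFactors = FALSE))
  })
}

sim_conservation <- function(cfg, peak_layer) {
  with_layer_seed(cfg$seed, 6, {
    genome <- sim_genome(cfg)
    drre <- peak_layer$drre
    elevated <- data.frame(chrom = drre$chrom,
                           start = pmax(0L, drre$summit - 100L),
                           end = drre$summit + 100L, value = 0.8)
    track <- fill_track(sort_regions(elevated), genome, 0.1)
    # species alignment masks: emerging regions align in more species
    k_aligned <- ifelse(drre$drre_class == "emerging",
                        sample(6:cfg$n_species, nrow(drre), replace = TRUE),
                        sample(1:8, nrow(drre), replace = TRUE))
    k_aligned <- pmin(k_aligned, cfg$n_species)
    species <- sprintf("species_%02d", seq_len(cfg$n_species))
    masks <- stats::setNames(lapply(seq_len(cfg$n_species), function(s) {
      rows <- drre[k_aligned >= s, c("chrom", "start", "end"), drop = FALSE]
      merge_intervals(rows)
    }), species)
    # activity (STARR-like) regions overlap a planted fraction of DRREs
    n_act <- round(cfg$starr_fraction * nrow(drre))
    act <- drre[sample.int(nrow(drre), n_act), c("chrom", "start", "end")]
    list(conservation = track, masks = masks,
         starr = merge_intervals(act),
         species_truth = data.frame(name = drre$name, n_species = k_aligned,
                                    stringsAsFactors = FALSE))
  })
}

# -- ortholog / species layer ------------------------------------------------

sim_orthologs <- function(cfg, expr_layer) {
  with_layer_seed(cfg$seed, 7, {
    de <- expr_layer$de
    up_early <- de$gene_id[de$timepoint == "early" & de$direction == "up"]
    core <- sort(sample(up_early, min(cfg$n_core_genes, length(up_early))))
    ids <- expr_layer$expression$gene_id
    is_core <- ids %in% core
    map_rows <- list()
    sp_rows <- list(zebrafish = list(), mouse = list())
    for (species in c("zebrafish", "mouse")) {
      # core genes get 1-2 up-regulated orthologs; a random ortholog_density
      # fraction of the rest get one ortholog whose fold stays below 1.5
      k <- ifelse(is_core, sample(1:2, length(ids), replace = TRUE),
                  ifelse(stats::runif(length(ids)) < cfg$ortholog_density, 1L, 0L))
      fly <- rep(ids, k)
      up <- rep(is_core, k)
      idx <- unlist(lapply(k, seq_len))
      og <- sprintf("%s_%s_o%d", substr(species, 1, 1), fly, idx)
      map_rows[[species]] <- data.frame(fly_gene = fly, species = species,
                                        ortholog = og, stringsAsFactors = FALSE)
      uninjured <- stats::rlnorm(length(og), log(10), 0.5)
      fold <- ifelse(up, stats::runif(length(og), 1.8, 3),
                     stats::runif(length(og), 0.75, 1.3))
      sp_rows[[species]] <- data.frame(gene_id = og,
                                       uninjured = round(uninjured, 4),
                                       injured = round(uninjured * fold, 4),
                                       stringsAsFactors = FALSE)
    }
    list(map = do.call(rbind, map_rows), species_expression = sp_rows,
         core = core)
  })
}

# -- zebrafish accessibility arm ---------------------------------------------

sim_zebrafish <- function(cfg) {
  with_layer_seed(cfg$seed, 8, {
    genome <- data.frame(chrom = "zchr1", length = cfg$zf_chrom_length,
                         stringsAsFactors = FALSE)
    grid <- 20000L
    n_cells <- as.integer(cfg$zf_chrom_length %/% grid)
    genes <- list()
    for (i in seq_len(min(cfg$n_zf_genes, n_cells))) {
      id <- sprintf("zf_g%03d", i)
      pos <- (i - 1L) * grid + sample.int(2000L, 1)
      genes[[id]] <- make_gene(id, "zchr1", pos, sample(1500:3500, 1),
                               sample(c("+", "-"), 1), 1L)
    }
    need <- cfg$n_zf_emerging + cfg$n_zf_increasing
    slots <- data.frame(chrom = "zchr1",
                        start = rep((seq_len(n_cells) - 1L) * grid,
                                    each = 2) + c(8000L, 14000L),
                        stringsAsFactors = FALSE)
    slots$end <- slots$start + cfg$peak_width
    idx <- sample.int(nrow(slots), need)
    take <- slots[idx, , drop = FALSE]
    take$kind <- rep(c("emerging", "increasing"),
                     c(cfg$n_zf_emerging, cfg$n_zf_increasing))
    take$name <- sprintf("zf_%s_%03d",
                         ifelse(take$kind == "emerging", "emg", "inc"),
                         stats::ave(seq_len(need), take$kind, FUN = seq_along))
    take$summit <- as.integer(take$start + cfg$peak_width %/% 2)
    base_h <- stats::rlnorm(need, log(20), 0.3)
    fold <- stats::runif(need, cfg$increasing_fold_min, cfg$increasing_fold_max)
    jit <- function(n) stats::runif(n, 0.95, 1.05)
    in_uninj <- take$kind == "increasing"
    mk <- function(sel, h) peak_df(take$chrom[sel], take$start[sel],
                                   take$end[sel], take$name[sel],
                                   take$summit[sel], h[sel])
    uninj_h <- base_h
    inj_h <- ifelse(take$kind == "increasing", base_h * fold, base_h)
    uninjured <- list(rep1 = mk(in_uninj, uninj_h * jit(need)),
                      rep2 = mk(in_uninj, uninj_h * jit(need)))
    injured <- list(rep1 = mk(rep(TRUE, need), inj_h * jit(need)),
                    rep2 = mk(rep(TRUE, need), inj_h * jit(need)))
    emg <- take[take$kind == "emerging", , drop = FALSE]
    n_reused <- round(cfg$zf_reused_fraction * nrow(emg))
    reused <- emg[sample.int(nrow(emg), n_reused), , drop = FALSE]
    free <- slots[-idx, , drop = FALSE]
    filler <- free[sample.int(nrow(free), min(8, nrow(free))), , drop = FALSE]
    embryo_open <- merge_intervals(rbind(
      reused[, c("chrom", "start", "end")],
      filler[, c("chrom", "start", "end")]))
    truth <- data.frame(name = take$name,
                        drre_class = take$kind,
                        usage = ifelse(take$name %in% reused$name,
                                       "reused", "novel"),
                        stringsAsFactors = FALSE)
    truth$usage[truth$drre_class == "increasing"] <- NA
    list(genome = genome, genes = genes,
         uninjured = lapply(uninjured, sort_regions),
         injured = lapply(injured, sort_regions),
         embryo_open = embryo_open, truth = truth)
  })
}

# -- qPCR layer --------------------------------------------------------------

sim_qpcr <- function(cfg) {
  with_layer_seed(cfg$seed, 9, {
    regions <- c(WNT_iDRRE = 2.5, proximal_eDRRE = 4, distal_eDRRE = 3)
    rows <- NULL
    for (rid in names(regions)) {
      fold <- regions[[rid]]
      for (cond in CONDITIONS) for (role in c("target", "reference")) {
        base_ct <- if (role == "reference") 20 else
          if (cond == "control") 25 else 25 - log2(fold)
        ct <- round(base_ct + stats::rnorm(3, 0, 0.03), 3)
        rows <- rbind(rows, data.frame(region_id = rid, condition = cond,
                                       role = role, replicate = 1:3,
                                       ct = ct, stringsAsFactors = FALSE))
      }
    }
    list(qpcr = rows,
         folds = data.frame(region_id = names(regions),
                            fold = unname(regions), stringsAsFactors = FALSE))
  })
}

# -- top-level generators ----------------------------------------------------

#' Simulate a complete toy regeneration study with planted truth
#'
#' Generates, deterministically for a given seed, every input the pipeline
#' consumes plus a `truth` element with the planted labels: DE genes per
#' timepoint, cluster memberships, per-region DRRE classes, the reused
#' set, active (feature-marked) regions, per-region species counts, the
#' cross-species core genes, the zebrafish classes, and the planted qPCR
#' folds.
#'
#' @param config a [sim_config()].
#' @return a `sim_bundle` list; see the package vignette for the layout.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gene_layer <- sim_genes(config)
  expr_layer <- sim_expression(config, gene_layer)
  peak_layer <- sim_peaks(config, gene_layer)
  ref_layer <- sim_refs(config, peak_layer)
  chip_layer <- sim_chip(config, peak_layer)
  cons_layer <- sim_conservation(config, peak_layer)
  orth_layer <- sim_orthologs(config, expr_layer)
  zf_layer <- sim_zebrafish(config)
  qpcr_layer <- sim_qpcr(config)

  tssd <- gene_tss(gene_layer$genes)
  cluster_truth <- do.call(rbind, lapply(seq_along(gene_layer$clusters),
    function(i) {
      cl <- gene_layer$clusters[[i]]
      m <- tssd[tssd$gene_id %in% cl$members, ]
      out <- data.frame(cluster_id = sprintf("planted_%02d", i),
                        chrom = cl$chrom, start = min(m$tss),
                        end = max(m$tss) + 1L, stringsAsFactors = FALSE)
      out$members <- list(sort(cl$members))
      out
    }))

  structure(list(
    config = config,
    genome = sim_genome(config),
    genes = gene_layer$genes,
    expression = expr_layer$expression,
    atac = peak_layer$atac,
    tracks = peak_layer$tracks,
    refs = ref_layer$refs,
    ref_labels = REF_LABELS,
    chip = chip_layer$chip,
    conservation = cons_layer$conservation,
    masks = cons_layer$masks,
    starr = cons_layer$starr,
    orthologs = orth_layer$map,
    species_expression = orth_layer$species_expression,
    zf = zf_layer,
    qpcr = qpcr_layer$qpcr,
    truth = list(
      de = expr_layer$de,
      clusters = cluster_truth,
      drre = peak_layer$drre,
      usage = ref_layer$usage,
      reused = ref_layer$reused,
      activity = chip_layer$activity,
      marked = chip_layer$marked,
      species = cons_layer$species_truth,
      core = orth_layer$core,
      zf = zf_layer$truth,
      qpcr_folds = qpcr_layer$folds)
  ), class = "sim_bundle")
}

#' Simulate a null study with no planted structure
#'
#' DE labels are assigned uniformly at random (expression itself carries
#' no planted fold change) and the peak landscape is identical across
#' conditions up to symmetric replicate noise, so differential calls and
#' cluster discoveries on this bundle are false positives by construction.
#'
#' @param config a [sim_config()]; planted counts are ignored.
#' @return a `sim_bundle` with `truth$de_labels` holding the random label
#'   assignment and all-background region truth.
#' @export
null_study <- function(config = sim_config()) {
  cfg <- config
  cfg$n_planted_clusters <- 0L
  cfg$n_emerging <- 0L
  cfg$n_increasing <- 0L
  gene_layer <- sim_genes(cfg)
  peak_layer <- sim_peaks(cfg, gene_layer)
  bundle <- with_layer_seed(cfg$seed, 10, {
    ids <- names(gene_layer$genes)
    n <- length(ids)
    baseline <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    expr <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
    for (cond in CONDITIONS) for (tp in TIMEPOINTS) for (r in 1:2)
      expr[[paste(cond, tp, r, sep = "_")]] <-
        round(baseline * exp(stats::rnorm(n, 0, cfg$rep_noise_sdlog)), 4)
    de_labels <- sample(ids, round(cfg$de_fraction * n))
    list(expression = expr, de_labels = sort(de_labels))
  })
  structure(list(
    config = cfg,
    genome = sim_genome(cfg),
    genes = gene_layer$genes,
    expression = bundle$expression,
    atac = peak_layer$atac,
    tracks = peak_layer$tracks,
    truth = list(de_labels = bundle$de_labels,
                 drre = peak_layer$drre)
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  seed <- if (!is.null(x$config)) x$config$seed else NA
  cat(sprintf("<sim_bundle> seed %s: %d genes on %d chromosome(s)",
              seed, length(x$genes), nrow(x$genome)))
  if (!is.null(x$truth$drre))
    cat(sprintf(", %d planted DRRE(s)", nrow(x$truth$drre)))
  cat("\n")
  invisible(x)
}

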