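# End-to-end orchestration of the discovery pipeline over a study bundle,
# with fail-fast validation, per-stage logging and an output manifest.

PIPELINE_STAGES <- c("de", "clusters", "atac_diff", "classify", "annotate",
                     "usage", "features", "conserve", "core_genes")

# bundle elements each stage needs
stage_requirements <- list(
  de = "expression",
  clusters = c("expression", "genes", "genome"),
  atac_diff = c("atac", "tracks"),
  classify = c("atac", "tracks"),
  annotate = c("atac", "tracks", "genes"),
  usage = c("atac", "tracks", "refs"),
  features = c("atac", "tracks", "chip"),
  conserve = c("atac", "tracks", "conservation", "masks", "starr"),
  core_genes = c("expression", "orthologs", "species_expression"))

#' Run the discovery pipeline over a study bundle
#'
#' Stages run in dependency order (differential expression, chromosomal
#' clusters, differential accessibility, DRRE classification, genomic
#' annotation, usage, enhancer features, conservation, cross-species
#' core). Inputs for every requested stage are validated before any stage
#' runs; a missing input fails fast naming the stage. Upstream results a
#' requested stage depends on are computed in memory, but only the
#' requested stages write outputs and appear in the manifest.
#'
#' @param bundle a `sim_bundle` (from [simulate_study()] or
#'   [read_bundle()]).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to emit (default: all).
#' @param fc_de expression fold-change threshold (default 1.7).
#' @param fc_acc accessibility height fold threshold (default 1.5).
#' @param pseudocount pseudocount for all ratio rules (default 0.01).
#' @param cluster_window,cluster_offset,min_genes,alpha cluster-detection
#'   parameters (defaults 30 kb, 10 kb, 3, 0.05).
#' @param hotspot_window,min_clusters hotspot parameters (1 Mb, 2).
#' @param cp_window,prox_window annotation windows in bp (100, 2000).
#' @param feature_window ChIP feature window in bp (500).
#' @param profile_flank conservation profile half-width in bp (500).
#' @param tau species-presence threshold on aligned fraction (0.5).
#' @param timepoint timepoint for the accessibility arm (default early).
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a manifest data frame (stage, output, n_records,
#'   md5, timestamp) with the parameter set attached as
#'   `attr(, "params")`; results are also returned in
#'   `attr(, "results")`.
#' @export
run_drre_pipeline <- function(bundle, out_dir,
                              stages = PIPELINE_STAGES,
                              fc_de = 1.7, fc_acc = 1.5, pseudocount = 0.01,
                              cluster_window = 30000, cluster_offset = 10000,
                              min_genes = 3, alpha = 0.05,
                              hotspot_window = 1e6, min_clusters = 2,
                              cp_window = 100, prox_window = 2000,
                              feature_window = 500, profile_flank = 500,
                              tau = 0.5, timepoint = "early",
                              quiet = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  params <- list(fc_de = fc_de, fc_acc = fc_acc, pseudocount = pseudocount,
                 cluster_window = cluster_window, cluster_offset = cluster_offset,
                 min_genes = min_genes, alpha = alpha,
                 hotspot_window = hotspot_window, min_clusters = min_clusters,
                 cp_window = cp_window, prox_window = prox_window,
                 feature_window = feature_window, profile_flank = profile_flank,
                 tau = tau, timepoint = timepoint)
  if (fc_de <= 1 || fc_acc <= 1)
    stop("fold-change thresholds must exceed 1", call. = FALSE)
  if (cluster_offset <= 0) stop("cluster_offset must be positive", call. = FALSE)

  # fail-fast: validate all needed inputs before any stage runs
  for (st in stages) {
    for (el in stage_requirements[[st]]) {
      if (is.null(bundle[[el]]))
        stop("stage '", st, "': bundle lacks required input '", el, "'",
             call. = FALSE)
    }
  }
  if (any(stages %in% c("classify", "annotate", "usage", "features",
                        "conserve")) && is.null(bundle$atac$l3))
    stop("stage 'classify': bundle lacks required input 'atac$l3' ",
         "(basal-stage open set)", call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message("[drrekit] ", sprintf(...))
  manifest <- NULL
  results <- list()
  emit <- function(stage, file, obj, writer = write_tsv) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    n <- if (is.data.frame(obj)) nrow(obj) else length(obj)
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, output = file,
                                  n_records = n,
                                  md5 = unname(tools::md5sum(path)),
                                  stringsAsFactors = FALSE))
    log_msg("%s: wrote %s (%d records)", stage, file, n)
  }
  flatten_members <- function(cl) {
    cl$members <- vapply(cl$members, paste, character(1), collapse = ",")
    cl
  }

  ## differential expression (needed by clusters and core_genes too)
  de_all <- NULL
  if (any(stages %in% c("de", "clusters", "core_genes"))) {
    de_all <- do.call(rbind, lapply(TIMEPOINTS, function(tp)
      call_de(bundle$expression, tp, fc = fc_de, pseudocount = pseudocount)))
    if ("de" %in% stages) {
      for (tp in TIMEPOINTS)
        emit("de", sprintf("de_%s.tsv", tp),
             de_all[de_all$timepoint == tp, , drop = FALSE])
      n_de <- sum(de_all$direction != "nde")
      log_msg("de: %d DE calls across timepoints (dropped %d nde)",
              n_de, nrow(de_all) - n_de)
    }
  }

  if ("clusters" %in% stages) {
    tssd <- gene_tss(bundle$genes)
    lens <- stats::setNames(bundle$genome$length, bundle$genome$chrom)
    for (tp in TIMEPOINTS) for (dir in c("up", "down")) {
      de_set <- de_all$gene_id[de_all$timepoint == tp & de_all$direction == dir]
      cl <- find_clusters(tssd, de_set, lens, window = cluster_window,
                          offset = cluster_offset, min_genes = min_genes,
                          alpha = alpha, direction = dir)
      emit("clusters", sprintf("clusters_%s_%s.tsv", tp, dir),
           flatten_members(cl))
      if (tp == timepoint && dir == "up") {
        results$clusters <- cl
        hs <- find_hotspots(cl, window = hotspot_window,
                            min_clusters = min_clusters)
        hs$cluster_ids <- vapply(hs$cluster_ids, paste, character(1),
                                 collapse = ",")
        emit("clusters", sprintf("hotspots_%s_%s.tsv", tp, dir), hs)
      }
    }
  }

  ## accessibility chain (computed when any downstream stage needs it)
  acc_needed <- any(stages %in% c("atac_diff", "classify", "annotate",
                                  "usage", "features", "conserve"))
  drre <- NULL
  if (acc_needed) {
    conc <- list(
      control = concordant_peaks(bundle$atac$control$rep1,
                                 bundle$atac$control$rep2),
      regeneration = concordant_peaks(bundle$atac$regeneration$rep1,
                                      bundle$atac$regeneration$rep2))
    diff <- differential_accessibility(conc$control, conc$regeneration,
                                       bundle$tracks$control,
                                       bundle$tracks$regeneration,
                                       fc = fc_acc, pseudocount = pseudocount,
                                       timepoint = timepoint)
    if ("atac_diff" %in% stages) emit("atac_diff", "diff_regions.tsv", diff)
    if (!is.null(bundle$atac$l3)) {
      l3_open <- consensus_regions(list(
        concordant_peaks(bundle$atac$l3$rep1, bundle$atac$l3$rep2)))
      ctl_open <- consensus_regions(list(conc$control))
      drre <- classify_drre(diff, ctl_open, l3_open)
      if ("classify" %in% stages) emit("classify", "drre.tsv", drre)
    }
  }

  if ("annotate" %in% stages) {
    ann <- annotate_peaks(drre, bundle$genes, cp_window = cp_window,
                          prox_window = prox_window)
    emit("annotate", "drre_annotated.tsv", ann)
    emit("annotate", "annotation_spectrum.tsv", annotation_spectrum(ann))
    results$annotated <- ann
  }
  if ("usage" %in% stages) {
    emg <- drre[drre$drre_class == "emerging", , drop = FALSE]
    usage <- classify_usage(emg, bundle$refs, bundle$ref_labels)
    emit("usage", "usage.tsv", usage)
    results$usage <- usage
  }
  if ("features" %in% stages) {
    statuses <- feature_status_table(drre, bundle$chip,
                                     window = feature_window)
    act <- activity_call(statuses)
    emit("features", "features.tsv", act)
    results$activity <- act
  }
  if ("conserve" %in% stages) {
    prof <- anchor_profile(drre, bundle$conservation, flank = profile_flank)
    emit("conserve", "conservation_profile.tsv", prof)
    sc <- species_conservation(drre, bundle$masks, tau = tau)
    emit("conserve", "species_conservation.tsv", sc)
    ao <- activity_overlap(drre, bundle$starr)
    emit("conserve", "activity_overlap.tsv",
         data.frame(percent_active = ao))
    results$species_conservation <- sc
  }
  if ("core_genes" %in% stages) {
    up <- function(tp) de_all$gene_id[de_all$timepoint == tp &
                                        de_all$direction == "up"]
    fish_up <- call_up_species(bundle$species_expression$zebrafish,
                               fc = 1.5, pseudocount = pseudocount)
    mouse_up <- call_up_species(bundle$species_expression$mouse,
                                fc = 1.5, pseudocount = pseudocount)
    core <- core_genes(up("early"), up("mid"), fish_up, mouse_up,
                       bundle$orthologs)
    emit("core_genes", "core_genes.tsv", core)
    results$core <- core
  }

  manifest <- if (is.null(manifest))
    data.frame(stage = character(), output = character(),
               n_records = integer(), md5 = character(),
               stringsAsFactors = FALSE) else manifest
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  attr(manifest, "params") <- params
  attr(manifest, "results") <- results
  results$drre <- drre
  attr(manifest, "results") <- results
  invisible(manifest)
}
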