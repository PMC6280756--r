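# Fly-oriented ortholog mapping, cross-species up-regulation calls, the
# regeneration-core intersection, a permutation null for ortholog
# enrichment, and the zebrafish DRRE arm.

#' Read an ortholog map
#'
#' @param path tab-delimited file with header columns `fly_gene`,
#'   `species`, `ortholog` (one row per ortholog pair).
#' @return ortholog map data frame.
#' @export
read_ortholog_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("fly_gene", "species", "ortholog")
  if (!all(need %in% names(x)))
    stop("ortholog map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

# orthologs of one fly gene in one species
orthologs_of <- function(map, gene, species) {
  unique(map$ortholog[map$fly_gene == gene & map$species == species])
}

#' Ortholog class of fly genes
#'
#' Classifies each fly gene by which vertebrate species it has at least
#' one ortholog in.
#'
#' @param genes character vector of fly gene ids.
#' @param map ortholog map data frame ([read_ortholog_map()]).
#' @return character vector in `{none, zebrafish_only, mouse_only, both}`.
#' @export
ortholog_class <- function(genes, map) {
  has_z <- genes %in% map$fly_gene[map$species == "zebrafish"]
  has_m <- genes %in% map$fly_gene[map$species == "mouse"]
  ifelse(has_z & has_m, "both",
         ifelse(has_z, "zebrafish_only",
                ifelse(has_m, "mouse_only", "none")))
}

#' Up-regulated genes in a species regeneration comparison
#'
#' A gene is up-regulated when its pseudocounted injured/uninjured
#' expression ratio reaches `fc` (default 1.5).
#'
#' @param expr data frame with `gene_id`, `uninjured`, `injured` columns
#'   (replicate-averaged expression values).
#' @param fc fold-change threshold (default 1.5).
#' @param pseudocount added to both values (default 0.01).
#' @return character vector of up-regulated gene ids.
#' @export
call_up_species <- function(expr, fc = 1.5, pseudocount = 0.01) {
  fold <- (expr$injured + pseudocount) / (expr$uninjured + pseudocount)
  expr$gene_id[fold >= fc]
}

#' Regeneration-core genes across fly, zebrafish and mouse
#'
#' Fly genes up-regulated after damage (early and/or mid) that map to at
#' least one up-regulated ortholog in zebrafish AND at least one in mouse.
#' Counting is fly-oriented: a fly gene with several up orthologs counts
#' once.
#'
#' @param fly_up_early,fly_up_mid character vectors of up-regulated fly
#'   gene ids at the early and mid timepoints.
#' @param fish_up,mouse_up character vectors of up-regulated ortholog ids.
#' @param map ortholog map data frame.
#' @return data frame with `gene_id`, `fish_support`, `mouse_support`
#'   (comma-separated supporting ortholog ids).
#' @export
core_genes <- function(fly_up_early, fly_up_mid, fish_up, mouse_up, map) {
  fly_up <- sort(union(fly_up_early, fly_up_mid))
  rows <- lapply(fly_up, function(g) {
    fs <- intersect(orthologs_of(map, g, "zebrafish"), fish_up)
    ms <- intersect(orthologs_of(map, g, "mouse"), mouse_up)
    if (length(fs) && length(ms))
      data.frame(gene_id = g,
                 fish_support = paste(sort(fs), collapse = ","),
                 mouse_support = paste(sort(ms), collapse = ","),
                 stringsAsFactors = FALSE)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene_id = character(), fish_support = character(),
                      mouse_support = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Permutation test for ortholog enrichment of regeneration genes
#'
#' Tests whether up-regulated fly genes carry up-regulated vertebrate
#' orthologs more often than same-size random gene sets drawn from the
#' background. The p-value is `(1 + #{draws with count >= observed}) /
#' (B + 1)`.
#'
#' @param fly_up character vector of up-regulated fly genes (subset of
#'   `background`).
#' @param background character vector of all eligible fly genes.
#' @param has_up_ortholog logical vector aligned with `background`
#'   (or named by it): does the gene have at least one up-regulated
#'   ortholog.
#' @param B number of permutations (default 10000).
#' @param seed optional integer seed for the draws.
#' @return list with `p_value`, `observed`, `expected` (null mean), `B`.
#' @export
ortholog_enrichment_test <- function(fly_up, background, has_up_ortholog,
                                     B = 10000, seed = NULL) {
  if (length(fly_up) > length(background))
    stop("fly_up larger than background", call. = FALSE)
  if (!all(fly_up %in% background))
    stop("fly_up must be a subset of background", call. = FALSE)
  if (!is.null(names(has_up_ortholog)))
    has_up_ortholog <- has_up_ortholog[background]
  if (length(has_up_ortholog) != length(background))
    stop("has_up_ortholog must align with background", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  m <- length(fly_up)
  observed <- sum(has_up_ortholog[match(fly_up, background)])
  null <- vapply(seq_len(B), function(i) sum(sample(has_up_ortholog, m)),
                 numeric(1))
  list(p_value = (1 + sum(null >= observed)) / (B + 1),
       observed = observed, expected = mean(null), B = B)
}

#' Zebrafish damage-responsive regulatory elements
#'
#' Mirrors the fly procedure for a system without a separate basal-stage
#' open set: concordant injured peaks exclusively called in regeneration
#' are `emerging`; peaks called in both samples with at least `fc`-fold
#' higher height after injury are `increasing`. Usage is classified
#' against embryonic open chromatin, and annotation uses a 500-bp core
#' promoter window.
#'
#' @param uninjured_peaks,injured_peaks concordant peak data frames.
#' @param uninjured_track,injured_track optional signal tracks for height.
#' @param embryo_open embryonic open-region data frame.
#' @param genes optional list of [gene_model()] objects for annotation.
#' @param fc height fold threshold (default 1.5).
#' @param cp_window core-promoter half-width for annotation (default 500).
#' @return DRRE data frame with `drre_class`, `usage` and (when `genes`
#'   given) annotation columns.
#' @export
zebrafish_drre <- function(uninjured_peaks, injured_peaks,
                           uninjured_track = NULL, injured_track = NULL,
                           embryo_open, genes = NULL,
                           fc = 1.5, cp_window = 500) {
  diff <- differential_accessibility(uninjured_peaks, injured_peaks,
                                     uninjured_track, injured_track, fc = fc)
  out <- classify_drre(diff, ctl_open = consensus_regions(list(uninjured_peaks)),
                       l3_open = empty_regions())
  usage <- classify_usage(out, refs = list(embryo = embryo_open))
  out$usage <- usage$usage
  if (!is.null(genes))
    out <- annotate_peaks(out, genes, cp_window = cp_window)
  out
}
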