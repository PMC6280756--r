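# Fragment-size partitioning, concordant/consensus peaks, differential
# accessibility, and the emerging/increasing DRRE classifier.

#' Classify ATAC fragment lengths
#'
#' Fragments shorter than 100 bp are nucleosome-free (`NF`); fragments of
#' 180-247 bp are mononucleosomal (`MN`); everything else is `other`.
#'
#' @param length positive integer vector of fragment lengths (bp).
#' @return character vector of classes.
#' @export
classify_fragment <- function(length) {
  if (any(is.na(length)) || any(length <= 0))
    stop("fragment lengths must be positive", call. = FALSE)
  ifelse(length < 100, "NF",
         ifelse(length >= 180 & length <= 247, "MN", "other"))
}

#' Replicate-concordant peaks
#'
#' Retains each `rep1` peak that overlaps at least one `rep2` peak
#' (>= 1 bp, half-open). Retained peaks keep their `rep1` coordinates and
#' summit; the height becomes the mean of the peak's own height and the
#' heights of its overlapping partners.
#'
#' @param rep1,rep2 peak data frames (see [read_peaks()]).
#' @return peak data frame (subset of `rep1` with updated heights).
#' @export
concordant_peaks <- function(rep1, rep2) {
  assert_regions(rep1, "rep1")
  assert_regions(rep2, "rep2")
  hits <- overlap_pairs(rep1, rep2)
  if (!nrow(hits)) return(rep1[integer(0), , drop = FALSE])
  keep <- sort(unique(hits$query))
  out <- rep1[keep, , drop = FALSE]
  newh <- vapply(keep, function(i) {
    partners <- rep2$height[hits$subject[hits$query == i]]
    mean(c(rep1$height[i], partners))
  }, numeric(1))
  out$height <- newh
  rownames(out) <- NULL
  out
}

#' Consensus open regions across samples
#'
#' Union-merges the concordant peaks of all samples into a disjoint set of
#' consensus regions.
#'
#' @param peak_sets list of peak data frames.
#' @return region data frame (disjoint, sorted).
#' @export
consensus_regions <- function(peak_sets) {
  if (!length(peak_sets)) return(empty_regions())
  all <- do.call(rbind, lapply(peak_sets, function(p)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               stringsAsFactors = FALSE)))
  merge_intervals(all)
}

#' Regions more accessible after damage
#'
#' Compares regeneration peaks against control peaks at one timepoint.
#' A regeneration peak overlapping no control peak is reported with
#' `mode = "presence_only"`. A regeneration peak overlapping control
#' peak(s) is reported with `mode = "height_fold"` when its pseudocounted
#' height ratio against the tallest overlapping control peak reaches `fc`
#' (default 1.5); other peaks are dropped. Heights are taken from the
#' signal tracks (maximum per-base value over the peak) when tracks are
#' supplied, otherwise from the peak `height` column.
#'
#' @param ctl_peaks,reg_peaks concordant peak data frames.
#' @param ctl_track,reg_track optional signal tracks.
#' @param fc height fold-change threshold (default 1.5).
#' @param pseudocount added to both heights (default 0.01).
#' @param timepoint label stored on the output.
#' @return data frame of differential regions: coordinates, `name`,
#'   `summit`, `height_reg`, `height_ctl`, `mode`, `fold` (NA for
#'   presence-only regions), `timepoint`.
#' @export
differential_accessibility <- function(ctl_peaks, reg_peaks,
                                       ctl_track = NULL, reg_track = NULL,
                                       fc = 1.5, pseudocount = 0.01,
                                       timepoint = NA_character_) {
  assert_regions(reg_peaks, "reg_peaks")
  assert_regions(ctl_peaks, "ctl_peaks")
  n <- nrow(reg_peaks)
  if (!n) {
    out <- reg_peaks[integer(0), c("chrom", "start", "end"), drop = FALSE]
    out$name <- character(0); out$summit <- integer(0)
    out$height_reg <- numeric(0); out$height_ctl <- numeric(0)
    out$mode <- character(0); out$fold <- numeric(0)
    out$timepoint <- character(0)
    return(out)
  }
  h_reg <- if (is.null(reg_track)) reg_peaks$height else
    region_signal(reg_track, reg_peaks, "max")
  h_ctl_each <- if (is.null(ctl_track)) ctl_peaks$height else
    region_signal(ctl_track, ctl_peaks, "max")
  hits <- overlap_pairs(reg_peaks, ctl_peaks)
  ctl_max <- rep(NA_real_, n)
  if (nrow(hits)) {
    agg <- tapply(h_ctl_each[hits$subject], hits$query, max)
    ctl_max[as.integer(names(agg))] <- as.numeric(agg)
  }
  mode <- ifelse(is.na(ctl_max), "presence_only", "height_fold")
  fold <- ifelse(is.na(ctl_max), NA_real_,
                 (h_reg + pseudocount) / (ctl_max + pseudocount))
  keep <- mode == "presence_only" | (!is.na(fold) & fold >= fc)
  out <- data.frame(chrom = reg_peaks$chrom, start = reg_peaks$start,
                    end = reg_peaks$end,
                    name = if ("name" %in% names(reg_peaks)) reg_peaks$name
                           else sprintf("region_%d", seq_len(n)),
                    summit = if ("summit" %in% names(reg_peaks)) reg_peaks$summit
                             else as.integer((reg_peaks$start + reg_peaks$end) %/% 2),
                    height_reg = h_reg, height_ctl = ctl_max,
                    mode = mode, fold = fold, timepoint = timepoint,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  sort_regions(out)
}

#' Classify differential regions as emerging or increasing DRREs
#'
#' A region is `emerging` when it overlaps neither the same-timepoint
#' control open set nor the basal (L3) open set, i.e. it is open only after
#' damage; any prior openness makes it `increasing`. Provenance columns
#' record which set(s) were overlapped.
#'
#' @param diff differential regions from [differential_accessibility()].
#' @param ctl_open merged control open regions (same timepoint).
#' @param l3_open merged basal-stage open regions (may have zero rows, e.g.
#'   for systems without a basal reference).
#' @return `diff` with added columns `overlaps_ctl`, `overlaps_l3`,
#'   `drre_class`.
#' @export
classify_drre <- function(diff, ctl_open, l3_open) {
  assert_regions(diff, "diff")
  out <- diff
  out$overlaps_ctl <- region_overlaps(diff, ctl_open)
  out$overlaps_l3 <- region_overlaps(diff, l3_open)
  out$drre_class <- ifelse(out$overlaps_ctl | out$overlaps_l3,
                           "increasing", "emerging")
  out
}
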