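# Reused/novel usage against reference open-region collections,
# summit-anchored signal/conservation profiles, per-species alignment
# conservation, and activity-region overlap.

#' Classify DRRE usage against reference open-region sets
#'
#' A DRRE is `reused` when it overlaps (>= 1 bp) open chromatin in at
#' least one reference dataset from another developmental stage or tissue;
#' otherwise it is `novel`. Reference sets must not include the assayed
#' stage/tissue itself (L3 wing disc): labels are validated when supplied.
#'
#' @param drres DRRE data frame with a `name` column.
#' @param refs named list of region data frames, one per reference dataset.
#' @param ref_labels optional data frame with `label`, `stage`, `tissue`
#'   describing each reference; a row with stage "L3" and tissue "wing"
#'   is a configuration error.
#' @return data frame with `name`, `usage`, `n_supporting`,
#'   `supporting_datasets` (comma-separated labels).
#' @export
classify_usage <- function(drres, refs, ref_labels = NULL) {
  assert_regions(drres, "drres")
  if (!length(refs) || is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("refs must be a non-empty named list", call. = FALSE)
  if (anyDuplicated(names(refs)))
    stop("reference labels must be unique", call. = FALSE)
  if (!is.null(ref_labels)) {
    bad <- ref_labels$stage == "L3" & ref_labels$tissue == "wing"
    if (any(bad))
      stop("reference set(s) labeled (L3, wing) are the assayed sample: ",
           paste(ref_labels$label[bad], collapse = ", "), call. = FALSE)
  }
  hit <- vapply(refs, function(r) region_overlaps(drres, r),
                logical(nrow(drres)))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = nrow(drres))
  supporting <- apply(hit, 1, function(h) paste(names(refs)[h], collapse = ","))
  data.frame(name = if ("name" %in% names(drres)) drres$name
                    else sprintf("region_%d", seq_len(nrow(drres))),
             usage = ifelse(rowSums(hit) >= 1, "reused", "novel"),
             n_supporting = rowSums(hit),
             supporting_datasets = supporting,
             stringsAsFactors = FALSE)
}

#' Summit-anchored mean signal profile
#'
#' For each offset o in `-flank..flank`, the profile value is the mean over
#' regions of the track value at (summit + o). Used for conservation-score
#' profiles around the nucleosome-free summit of DRREs, and equally for
#' TSS-anchored signal aggregation when `summit` holds TSS positions.
#'
#' @param regions data frame with `chrom` and `summit` columns.
#' @param track signal track data frame.
#' @param flank half-width in bp (default 500).
#' @return data frame with `offset`, `mean`, `n` (regions averaged); empty
#'   when `regions` has no rows.
#' @export
anchor_profile <- function(regions, track, flank = 500) {
  if (!"summit" %in% names(regions))
    stop("regions need a summit column", call. = FALSE)
  offsets <- seq.int(-flank, flank)
  if (!nrow(regions))
    return(data.frame(offset = integer(), mean = numeric(), n = integer()))
  acc <- numeric(length(offsets))
  for (ch in unique(regions$chrom)) {
    s <- regions$summit[regions$chrom == ch]
    pos <- as.vector(outer(s, offsets, `+`))
    vals <- matrix(track_values_at(track, ch, pos), nrow = length(s))
    acc <- acc + colSums(vals)
  }
  data.frame(offset = offsets, mean = acc / nrow(regions), n = nrow(regions))
}

#' Per-species alignment conservation of DRREs
#'
#' For each region and species, the aligned fraction is the number of
#' region bases covered by that species' alignment mask divided by region
#' length. A species "presents" the enhancer when its aligned fraction is
#' at least `tau` (default 0.5). `percent_aligned` is 100 times the mean
#' aligned fraction over all species, giving one summary per enhancer.
#'
#' @param drres DRRE data frame.
#' @param masks named list of region data frames, one per species, in the
#'   same coordinate system as `drres`.
#' @param tau presence threshold on the aligned fraction (default 0.5).
#' @return data frame with `name`, `n_species`, `percent_aligned`.
#' @export
species_conservation <- function(drres, masks, tau = 0.5) {
  assert_regions(drres, "drres")
  if (!length(masks) || is.null(names(masks)))
    stop("masks must be a non-empty named list", call. = FALSE)
  if (anyDuplicated(names(masks)))
    stop("species names must be unique", call. = FALSE)
  width <- drres$end - drres$start
  frac <- vapply(masks, function(m) {
    m <- merge_intervals(m)
    cov <- numeric(nrow(drres))
    hits <- overlap_pairs(drres, m)
    if (nrow(hits)) {
      w <- pmin(drres$end[hits$query], m$end[hits$subject]) -
        pmax(drres$start[hits$query], m$start[hits$subject])
      agg <- tapply(w, hits$query, sum)
      cov[as.integer(names(agg))] <- as.numeric(agg)
    }
    cov / width
  }, numeric(nrow(drres)))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = nrow(drres))
  data.frame(name = if ("name" %in% names(drres)) drres$name
                    else sprintf("region_%d", seq_len(nrow(drres))),
             n_species = as.integer(rowSums(frac >= tau)),
             percent_aligned = 100 * rowMeans(frac),
             stringsAsFactors = FALSE)
}

#' Fraction of DRREs overlapping activity regions
#'
#' Percentage of DRREs overlapping at least one region with demonstrated
#' enhancer activity (e.g. episomal reporter-assay intervals).
#'
#' @param drres DRRE data frame.
#' @param activity_regions region data frame.
#' @return percentage in `[0, 100]`; `NA` (with a warning) when `drres` is
#'   empty.
#' @export
activity_overlap <- function(drres, activity_regions) {
  assert_regions(drres, "drres")
  if (!nrow(drres)) {
    warning("no DRREs; activity overlap undefined")
    return(NA_real_)
  }
  100 * mean(region_overlaps(drres, activity_regions))
}
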