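# Active-enhancer feature marking from ChIP peaks/signal and
# delta-delta-Ct fold enrichment for ChIP-qPCR / 3C-qPCR tables.

#' Feature status of DRREs for one chromatin feature
#'
#' For each DRRE: `marked` when at least one regeneration ChIP peak
#' overlaps the DRRE extended by `window` bp on each side; otherwise
#' `higher_signal` when the mean regeneration signal over the DRRE
#' interval strictly exceeds the mean control signal; otherwise
#' `not_marked`.
#'
#' @param drres DRRE data frame.
#' @param reg_peaks ChIP peak regions called in regeneration samples.
#' @param reg_track,ctl_track ChIP signal tracks, pre-normalized to a
#'   common scale.
#' @param window extension in bp on each side for the peak test
#'   (default 500).
#' @return character vector of statuses, one per DRRE.
#' @export
feature_status <- function(drres, reg_peaks, reg_track, ctl_track,
                           window = 500) {
  assert_regions(drres, "drres")
  ext <- data.frame(chrom = drres$chrom,
                    start = pmax(0L, drres$start - window),
                    end = drres$end + window, stringsAsFactors = FALSE)
  marked <- region_overlaps(ext, reg_peaks)
  status <- rep("not_marked", nrow(drres))
  status[marked] <- "marked"
  if (any(!marked)) {
    sub <- drres[!marked, , drop = FALSE]
    m_reg <- region_signal(reg_track, sub, "mean")
    m_ctl <- region_signal(ctl_track, sub, "mean")
    status[!marked][m_reg > m_ctl] <- "higher_signal"
  }
  status
}

#' Feature statuses for all active-enhancer features
#'
#' @param drres DRRE data frame with a `name` column.
#' @param chip named list with one element per feature (conventionally
#'   H3K4me1, H3K27ac, PolII); each element a list with `reg_peaks`,
#'   `reg_track`, `ctl_track`.
#' @param window see [feature_status()].
#' @return data frame with `name` plus one status column per feature.
#' @export
feature_status_table <- function(drres, chip, window = 500) {
  if (!length(chip) || is.null(names(chip)))
    stop("chip must be a non-empty named list", call. = FALSE)
  out <- data.frame(name = if ("name" %in% names(drres)) drres$name
                           else sprintf("region_%d", seq_len(nrow(drres))),
                    stringsAsFactors = FALSE)
  for (f in names(chip)) {
    out[[f]] <- feature_status(drres, chip[[f]]$reg_peaks,
                               chip[[f]]$reg_track, chip[[f]]$ctl_track,
                               window = window)
  }
  out
}

#' Active-enhancer activity call from per-feature statuses
#'
#' A DRRE has activity `presence` when at least one feature is `marked` or
#' `higher_signal`, and `absence` when all features are `not_marked`.
#'
#' @param statuses data frame from [feature_status_table()] (a `name`
#'   column plus one status column per feature; all features required for
#'   every row).
#' @return `statuses` with added `n_features_present` and `activity`.
#' @export
activity_call <- function(statuses) {
  feat <- setdiff(names(statuses), "name")
  if (!length(feat)) stop("no feature columns", call. = FALSE)
  mat <- as.matrix(statuses[, feat, drop = FALSE])
  if (anyNA(mat)) stop("missing feature status", call. = FALSE)
  present <- mat == "marked" | mat == "higher_signal"
  out <- statuses
  out$n_features_present <- as.integer(rowSums(present))
  out$activity <- ifelse(out$n_features_present >= 1, "presence", "absence")
  out
}

#' Delta-delta-Ct fold enrichment from a qPCR table
#'
#' For each condition, delta-Ct is the mean target Ct minus the mean
#' reference (input or known-interaction) Ct over technical replicates;
#' delta-delta-Ct is delta-Ct(regeneration) minus delta-Ct(control); the
#' fold enrichment of regeneration over control is `2^(-ddCt)`. The SEM is
#' propagated from the technical-replicate spread of each of the four
#' means and reported on the fold scale.
#'
#' @param qpcr data frame with columns `region_id`, `condition`
#'   (control/regeneration), `role` (target/reference), `replicate`, `ct`.
#' @param region_id region to quantify.
#' @return list with `fold`, `ddct`, `sem` (SEM of the fold).
#' @export
ddct_fold_enrichment <- function(qpcr, region_id) {
  x <- qpcr[qpcr$region_id == region_id, , drop = FALSE]
  if (!nrow(x)) stop("no rows for region ", region_id, call. = FALSE)
  if (any(x$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  cell <- function(cond, role) {
    v <- x$ct[x$condition == cond & x$role == role]
    if (!length(v))
      stop("missing ", role, " Ct for condition ", cond, call. = FALSE)
    list(mean = mean(v),
         sem2 = if (length(v) > 1) stats::var(v) / length(v) else 0)
  }
  tc <- cell("control", "target");       rc <- cell("control", "reference")
  tr <- cell("regeneration", "target");  rr <- cell("regeneration", "reference")
  ddct <- (tr$mean - rr$mean) - (tc$mean - rc$mean)
  fold <- 2^(-ddct)
  se_ddct <- sqrt(tc$sem2 + rc$sem2 + tr$sem2 + rr$sem2)
  list(fold = fold, ddct = ddct, sem = fold * log(2) * se_ddct)
}
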