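# Unique TSS-relative genomic annotation of peaks/DRREs with precedence:
# core promoter (CP) > first intron (FI) > proximal > distal.

#' Annotate peaks with a unique genomic category
#'
#' Each peak's summit (or interval midpoint when no summit column is
#' present) is tested in order: within `cp_window` bp of any gene's TSS ->
#' `CP`; inside any gene's first intron -> `FI`; within `prox_window` bp of
#' any TSS -> `proximal`; otherwise `distal`. TSS windows are unstranded.
#' The assigned gene is the qualifying gene with the nearest TSS (nearest
#' TSS on the chromosome for distal peaks); residual ties break to the
#' lexicographically smallest gene id. The reported distance is signed
#' strand-aware: negative means the summit lies 5' of the assigned gene's
#' TSS.
#'
#' @param peaks peak or DRRE data frame (`chrom`, `start`, `end`, and
#'   optionally `summit`).
#' @param genes list of [gene_model()] objects.
#' @param cp_window core-promoter half-width in bp (default 100; the
#'   zebrafish analyses use 500).
#' @param prox_window proximal half-width in bp (default 2000).
#' @return `peaks` with added columns `category`, `gene_id` (NA when no
#'   gene shares the chromosome), `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, genes, cp_window = 100, prox_window = 2000) {
  assert_regions(peaks, "peaks")
  tss <- gene_tss(genes)
  fi <- first_introns(genes)
  n <- nrow(peaks)
  anchor <- if ("summit" %in% names(peaks)) peaks$summit
            else as.integer((peaks$start + peaks$end) %/% 2)
  category <- character(n)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)

  pick_nearest <- function(cand_tss, a) {
    d <- abs(a - cand_tss$tss)
    cand <- cand_tss[d == min(d), , drop = FALSE]
    cand$gene_id[order(cand$gene_id)][1]
  }
  for (i in seq_len(n)) {
    a <- anchor[i]
    ch <- peaks$chrom[i]
    t <- tss[tss$chrom == ch, , drop = FALSE]
    if (!nrow(t)) {
      category[i] <- "distal"
      next
    }
    d_un <- abs(a - t$tss)
    if (any(d_un <= cp_window)) {
      category[i] <- "CP"
      gene_id[i] <- pick_nearest(t[d_un <= cp_window, , drop = FALSE], a)
    } else {
      f <- fi[fi$chrom == ch & fi$start <= a & a < fi$end, , drop = FALSE]
      if (nrow(f)) {
        category[i] <- "FI"
        gene_id[i] <- pick_nearest(t[t$gene_id %in% f$gene_id, , drop = FALSE], a)
      } else if (any(d_un <= prox_window)) {
        category[i] <- "proximal"
        gene_id[i] <- pick_nearest(t[d_un <= prox_window, , drop = FALSE], a)
      } else {
        category[i] <- "distal"
        gene_id[i] <- pick_nearest(t, a)
      }
    }
    g <- t[t$gene_id == gene_id[i], , drop = FALSE]
    distance[i] <- if (g$strand[1] == "+") a - g$tss[1] else g$tss[1] - a
  }
  out <- peaks
  out$category <- category
  out$gene_id <- gene_id
  out$distance_to_tss <- distance
  out
}

#' Contingency spectrum of annotation categories
#'
#' Counts and fractions of annotated regions per category, optionally
#' split by DRRE class, optionally excluding core-promoter regions (the
#' enhancer-only spectrum).
#'
#' @param annotated output of [annotate_peaks()], optionally with a
#'   `drre_class` column.
#' @param exclude_cp drop CP regions before counting (default FALSE).
#' @return data frame with `drre_class` (`"all"` when absent), `category`,
#'   `count`, `fraction` (within class).
#' @export
annotation_spectrum <- function(annotated, exclude_cp = FALSE) {
  x <- annotated
  if (exclude_cp) x <- x[x$category != "CP", , drop = FALSE]
  cls <- if ("drre_class" %in% names(x)) x$drre_class else rep("all", nrow(x))
  if (!nrow(x))
    return(data.frame(drre_class = character(), category = character(),
                      count = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  tab <- as.data.frame(table(drre_class = cls, category = x$category),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  totals <- tapply(tab$count, tab$drre_class, sum)
  tab$fraction <- tab$count / as.numeric(totals[tab$drre_class])
  rownames(tab) <- NULL
  tab[order(tab$drre_class, tab$category), , drop = FALSE]
}
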