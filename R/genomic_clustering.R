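# Sliding-window hypergeometric detection of chromosomal clusters of
# differentially expressed genes, cluster hotspots, and coregulation
# summaries for cluster members.

#' Find chromosomal clusters of differentially expressed genes
#'
#' Each chromosome is tiled with windows of length `window` advanced by
#' `offset`; a gene belongs to a window when its TSS lies inside it. For a
#' window holding n genes of which k are in `de_set`, the enrichment
#' p-value is the hypergeometric upper tail P(X >= k) with population size
#' N (all genes) and K DE genes genome-wide. Benjamini-Hochberg correction
#' is applied across all windows containing at least one gene; windows with
#' k >= `min_genes` and q <= `alpha` survive, and overlapping surviving
#' windows are merged into clusters whose interval spans their member DE
#' genes. Defaults (30-kb window, 10-kb offset, 3 genes, alpha 0.05, BH)
#' follow the CROC parameterization.
#'
#' @param genes data frame with `gene_id`, `chrom`, `tss` (see [gene_tss()]).
#' @param de_set character vector of DE gene ids (must be a subset of
#'   `genes$gene_id`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window window length in bp (default 30000).
#' @param offset window step in bp (default 10000); must be positive.
#' @param min_genes minimum DE genes per window (default 3).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param direction label stored on the output (`"up"` or `"down"`).
#' @return data frame of clusters: `cluster_id`, `chrom`, `start`, `end`
#'   (span of member DE gene TSSs), `n_members`, `members` (list column of
#'   gene ids sorted by position), `p_value`, `q_value`, `direction`.
#' @export
find_clusters <- function(genes, de_set, chrom_lengths,
                          window = 30000, offset = 10000,
                          min_genes = 3, alpha = 0.05, direction = "up") {
  if (offset <= 0) stop("offset must be positive", call. = FALSE)
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), p_value = numeric(),
                      q_value = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (!nrow(genes) || !length(de_set)) return(empty)
  if (!all(de_set %in% genes$gene_id))
    stop("de_set contains ids absent from genes", call. = FALSE)
  N <- nrow(genes)
  is_de <- genes$gene_id %in% de_set
  K <- sum(is_de)

  win <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, max(0, chrom_lengths[[ch]] - 1), by = offset)
    data.frame(chrom = ch, start = starts, end = starts + window,
               stringsAsFactors = FALSE)
  }))
  # gene counts per window by TSS membership
  g_ord <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
  count_in <- function(sub) {
    vapply(seq_len(nrow(win)), function(i) {
      s <- sub[sub$chrom == win$chrom[i], "tss"]
      sum(s >= win$start[i] & s < win$end[i])
    }, numeric(1))
  }
  win$n <- count_in(g_ord)
  win$k <- count_in(g_ord[g_ord$gene_id %in% de_set, , drop = FALSE])
  tested <- win$n > 0
  win$p <- NA_real_
  win$p[tested] <- stats::phyper(win$k[tested] - 1, K, N - K, win$n[tested],
                                 lower.tail = FALSE)
  win$q <- NA_real_
  win$q[tested] <- stats::p.adjust(win$p[tested], method = "BH")
  keep <- tested & win$k >= min_genes & win$q <= alpha
  if (!any(keep)) return(empty)

  kept <- win[keep, , drop = FALSE]
  merged <- merge_intervals(kept[, c("chrom", "start", "end")])
  de_tss <- g_ord[g_ord$gene_id %in% de_set, , drop = FALSE]
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    mem <- de_tss[de_tss$chrom == m$chrom & de_tss$tss >= m$start &
                    de_tss$tss < m$end, , drop = FALSE]
    mem <- mem[order(mem$tss), , drop = FALSE]
    kw <- kept[kept$chrom == m$chrom & kept$start < m$end & kept$end > m$start, ]
    data.frame(chrom = m$chrom, start = min(mem$tss), end = max(mem$tss) + 1L,
               n_members = nrow(mem),
               p_value = min(kw$p), q_value = min(kw$q),
               direction = direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    mem <- de_tss[de_tss$chrom == m$chrom & de_tss$tss >= m$start &
                    de_tss$tss < m$end, , drop = FALSE]
    mem$gene_id[order(mem$tss)]
  })
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(cluster_id = sprintf("cluster_%s_%03d", direction, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Find hotspots of chromosomal clusters
#'
#' A hotspot is a maximal group of at least `min_clusters` clusters whose
#' start positions fall within some sliding window of length `window`
#' (1 Mb by default); no p-value or multiple-testing correction is applied
#' at this level. Overlapping qualifying groups are merged.
#'
#' @param clusters cluster data frame from [find_clusters()].
#' @param window hotspot window length in bp (default 1e6).
#' @param min_clusters minimum clusters per hotspot (default 2).
#' @return data frame with `hotspot_id`, `chrom`, `start`, `end`
#'   (span of member clusters) and `cluster_ids` (list column).
#' @export
find_hotspots <- function(clusters, window = 1e6, min_clusters = 2) {
  empty <- data.frame(hotspot_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  empty$cluster_ids <- list()
  if (nrow(clusters) < min_clusters) return(empty)
  out <- NULL
  for (ch in unique(clusters$chrom)) {
    cl <- clusters[clusters$chrom == ch, , drop = FALSE]
    cl <- cl[order(cl$start), , drop = FALSE]
    n <- nrow(cl)
    runs <- NULL
    for (i in seq_len(n)) {
      j <- max(which(cl$start - cl$start[i] < window))
      if (j - i + 1 >= min_clusters) runs <- rbind(runs, c(i, j))
    }
    if (is.null(runs)) next
    # merge overlapping index runs into maximal groups
    groups <- list(runs[1, ])
    if (nrow(runs) > 1) for (r in 2:nrow(runs)) {
      last <- groups[[length(groups)]]
      if (runs[r, 1] <= last[2]) {
        groups[[length(groups)]] <- c(last[1], max(last[2], runs[r, 2]))
      } else groups[[length(groups) + 1]] <- runs[r, ]
    }
    for (g in groups) {
      mem <- cl[g[1]:g[2], , drop = FALSE]
      row <- data.frame(chrom = ch, start = min(mem$start), end = max(mem$end),
                        stringsAsFactors = FALSE)
      row$cluster_ids <- list(mem$cluster_id)
      out <- rbind(out, row)
    }
  }
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  cbind(hotspot_id = sprintf("hotspot_%03d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Coregulation summary for a set of cluster members
#'
#' Scores every unordered pair of member genes with [coregulation()] on
#' their per-timepoint mean FPKM in one condition; pairs with undefined
#' correlation are excluded from the summaries.
#'
#' @param members character vector of member gene ids.
#' @param expr expression data frame.
#' @param condition condition used for the profiles (default regeneration).
#' @param pseudocount see [coregulation()].
#' @return list with `mean_r`, `median_r`, `n_pairs` (pairs with defined r)
#'   and `r` (vector of defined pairwise correlations). When fewer than two
#'   members have expression, an empty summary is returned with a warning.
#' @export
cluster_coregulation <- function(members, expr, condition = "regeneration",
                                 pseudocount = 0.01) {
  members <- intersect(members, expr$gene_id)
  if (length(members) < 2) {
    warning("fewer than two scorable members")
    return(list(mean_r = NA_real_, median_r = NA_real_, n_pairs = 0L,
                r = numeric(0)))
  }
  prof <- vapply(TIMEPOINTS, function(tp)
    expression_means(expr, condition, tp)[members], numeric(length(members)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  pairs <- utils::combn(length(members), 2)
  r <- apply(pairs, 2, function(ij)
    coregulation(prof[ij[1], ], prof[ij[2], ], pseudocount))
  r <- r[!is.na(r)]
  list(mean_r = if (length(r)) mean(r) else NA_real_,
       median_r = if (length(r)) stats::median(r) else NA_real_,
       n_pairs = length(r), r = r)
}
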