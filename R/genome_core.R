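# Interval arithmetic, gene-model geometry and plain-text readers/writers.
#
# All coordinates are 0-based half-open (BED convention). GTF input/output
# (1-based, closed) is converted at the parser boundary so that interval
# arithmetic is uniform everywhere else.

#' Validate a region data frame
#'
#' Regions are plain data frames with at least `chrom`, `start`, `end`
#' columns in 0-based half-open coordinates.
#'
#' @param x data frame to check.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
assert_regions <- function(x, what = "regions") {
  if (!is.data.frame(x))
    stop(what, " must be a data frame", call. = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(x)) {
    chrom <- as.character(x$chrom)
    if (anyNA(chrom) || any(!nzchar(chrom)))
      stop(what, ": chrom must be non-empty", call. = FALSE)
    bad <- is.na(x$start) | is.na(x$end) | x$start < 0 | x$end <= x$start
    if (any(bad))
      stop(what, ": invalid coordinates (need 0 <= start < end) in row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# 0-based half-open data frame -> GRanges (1-based closed) and back
as_gr <- function(x) {
  GenomicRanges::GRanges(as.character(x$chrom),
                         IRanges::IRanges(x$start + 1L, x$end))
}

# put two GRanges on the union of their seqlevels so overlap operations do
# not warn when the chromosomes are disjoint
align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

gr_to_regions <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

sort_regions <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Merge genomic intervals into a disjoint sorted union
#'
#' Overlapping and book-ended intervals (where one ends exactly where the
#' next starts) are merged, mirroring BEDOPS-style union semantics used to
#' build consensus open-chromatin regions.
#'
#' @param x region data frame (`chrom`, `start`, `end`; 0-based half-open).
#' @return region data frame, disjoint and sorted by (chrom, start).
#' @examples
#' merge_intervals(data.frame(chrom = "chr2L", start = c(10, 15), end = c(20, 30)))
#' @export
merge_intervals <- function(x) {
  assert_regions(x)
  if (!nrow(x)) return(empty_regions())
  out <- gr_to_regions(GenomicRanges::reduce(as_gr(x), min.gapwidth = 1L))
  rownames(out) <- NULL
  sort_regions(out)
}

#' Test which query regions overlap any subject region
#'
#' Half-open semantics: abutting intervals do not overlap; one shared base
#' suffices.
#'
#' @param query,subject region data frames.
#' @return logical vector, one element per `query` row.
#' @export
region_overlaps <- function(query, subject) {
  assert_regions(query, "query")
  assert_regions(subject, "subject")
  if (!nrow(query)) return(logical(0))
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  gr <- align_seqlevels(as_gr(query), as_gr(subject))
  GenomicRanges::countOverlaps(gr[[1]], gr[[2]]) > 0
}

# all (query_row, subject_row) overlap pairs as a data.frame
overlap_pairs <- function(query, subject) {
  if (!nrow(query) || !nrow(subject))
    return(data.frame(query = integer(), subject = integer()))
  gr <- align_seqlevels(as_gr(query), as_gr(subject))
  h <- GenomicRanges::findOverlaps(gr[[1]], gr[[2]])
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Construct a gene model
#'
#' A gene model is a gene id, chromosome, strand, and one or more
#' transcripts, each a data frame of exon intervals.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts named or unnamed list of exon data frames
#'   (`start`, `end`), each sorted and non-overlapping within a transcript.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (!is.list(transcripts) || length(transcripts) < 1L)
    stop("gene ", gene_id, " needs at least one transcript", call. = FALSE)
  for (tx in transcripts) {
    assert_regions(cbind(chrom = chrom, tx), paste0("exons of ", gene_id))
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s(%s), %d transcript(s), TSS %d\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts),
              gene_tss_position(x)))
  invisible(x)
}

# 0-based position of the first transcribed base
gene_tss_position <- function(gene) {
  ex <- do.call(rbind, gene$transcripts)
  as.integer(if (gene$strand == "+") min(ex$start) else max(ex$end) - 1L)
}

#' Table of transcription start sites for a set of gene models
#'
#' The TSS of a multi-transcript gene is the 5'-most transcript start across
#' all transcripts, giving one deterministic anchor per gene.
#'
#' @param genes list of [gene_model()] objects.
#' @return data frame with `gene_id`, `chrom`, `tss` (0-based position of
#'   the first transcribed base) and `strand`.
#' @export
gene_tss <- function(genes) {
  out <- data.frame(
    gene_id = vapply(genes, function(g) g$gene_id, character(1)),
    chrom   = vapply(genes, function(g) g$chrom, character(1)),
    tss     = vapply(genes, gene_tss_position, integer(1)),
    strand  = vapply(genes, function(g) g$strand, character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Projected exons and first intron of a gene
#'
#' Projected exons are the merged union of exons over all annotated
#' transcripts. The first intron is the gap between the first and second
#' projected exons in the 5'-to-3' direction of the gene (absent when the
#' projection has fewer than two exons).
#'
#' @param gene a [gene_model()].
#' @return list with `exons` (region data frame ordered 5' to 3') and
#'   `first_intron` (single-row region data frame, or `NULL`).
#' @export
projected_exons <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- do.call(rbind, lapply(gene$transcripts, function(tx)
    data.frame(chrom = gene$chrom, start = tx$start, end = tx$end,
               stringsAsFactors = FALSE)))
  merged <- merge_intervals(ex)
  dec <- gene$strand == "-"
  merged <- merged[order(merged$start, decreasing = dec), , drop = FALSE]
  rownames(merged) <- NULL
  first_intron <- NULL
  if (nrow(merged) >= 2) {
    e1 <- merged[1, ]
    e2 <- merged[2, ]
    left <- if (e1$start < e2$start) e1 else e2
    right <- if (e1$start < e2$start) e2 else e1
    first_intron <- data.frame(chrom = gene$chrom, start = left$end,
                               end = right$start, stringsAsFactors = FALSE)
  }
  list(exons = merged, first_intron = first_intron)
}

#' Table of first introns for a set of gene models
#'
#' @param genes list of [gene_model()] objects.
#' @return region data frame with a `gene_id` column; genes whose exon
#'   projection has a single exon are absent.
#' @export
first_introns <- function(genes) {
  rows <- lapply(genes, function(g) {
    fi <- projected_exons(g)$first_intron
    if (is.null(fi)) return(NULL)
    cbind(gene_id = g$gene_id, fi)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(cbind(data.frame(gene_id = character()), empty_regions()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- readers / writers -----------------------------------------------------

#' Read gene models from a GTF/GFF file
#'
#' Only `exon` features are used; genes and transcripts are reconstructed
#' from the `gene_id` and `transcript_id` attributes. GTF 1-based closed
#' coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return named list of [gene_model()] objects.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path, call. = FALSE)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end   = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  genes <- lapply(split(df, df$gene_id), function(d) {
    txs <- lapply(split(d, d$transcript_id), function(t) {
      t <- t[order(t$start), , drop = FALSE]
      data.frame(start = t$start, end = t$end)
    })
    gene_model(d$gene_id[1], d$chrom[1], d$strand[1], txs)
  })
  genes[order(names(genes))]
}

#' Write gene models to a GTF file
#'
#' Emits gene, transcript and exon features with `gene_id`/`transcript_id`
#' attributes; output is deterministic (no timestamp headers).
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    tx_names <- names(g$transcripts)
    if (is.null(tx_names)) tx_names <- paste0(g$gene_id, ".t", seq_along(g$transcripts))
    all_ex <- do.call(rbind, g$transcripts)
    fmt <- function(feature, start0, end0, attrs)
      sprintf("%s\tdrrekit\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, feature, start0 + 1L, end0, g$strand, attrs)
    lines <- c(lines, fmt("gene", min(all_ex$start), max(all_ex$end),
                          sprintf("gene_id \"%s\";", g$gene_id)))
    for (i in seq_along(g$transcripts)) {
      tx <- g$transcripts[[i]]
      at <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", g$gene_id, tx_names[i])
      lines <- c(lines, fmt("transcript", min(tx$start), max(tx$end), at))
      for (j in seq_len(nrow(tx)))
        lines <- c(lines, fmt("exon", tx$start[j], tx$end[j], at))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak file (BED6+2: summit, height)
#'
#' @param path tab-delimited file with columns chrom, start, end, name,
#'   score, strand, summit (absolute 0-based position), height.
#' @return peak data frame.
#' @export
read_peaks <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand", "summit", "height"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character",
                                        "integer", "numeric"))
  assert_regions(x, "peaks")
  bad <- x$summit < x$start | x$summit >= x$end
  if (any(bad)) stop("summit outside its peak in row(s) ",
                     paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  x
}

#' Write a peak file (BED6+2)
#' @param x peak data frame (see [read_peaks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  assert_regions(x, "peaks")
  x <- sort_regions(x)
  utils::write.table(
    data.frame(x$chrom, x$start, x$end, x$name, x$score, x$strand,
               x$summit, signif(x$height, 10)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 region file
#' @param path file path.
#' @return region data frame.
#' @export
read_regions_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty_regions())
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  assert_regions(x)
  x
}

#' Write a BED3 region file
#' @param x region data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(x, path) {
  assert_regions(x)
  x <- sort_regions(x)
  utils::write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' A track is a data frame of non-overlapping steps (`chrom`, `start`,
#' `end`, `value`); positions not covered by any step read as 0.
#'
#' @param path bedGraph file path.
#' @return track data frame sorted by (chrom, start).
#' @export
read_bedgraph <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(cbind(empty_regions(), value = numeric()))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer", "numeric"))
  validate_track(x)
}

#' Write a bedGraph signal track
#' @param x track data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  x <- validate_track(x)
  utils::write.table(
    data.frame(x$chrom, x$start, x$end, signif(x$value, 10)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# sort and check step disjointness / non-negativity
validate_track <- function(x) {
  assert_regions(x, "track")
  if (!"value" %in% names(x)) stop("track lacks a value column", call. = FALSE)
  if (any(x$value < 0)) stop("track values must be >= 0", call. = FALSE)
  x <- sort_regions(x)
  rownames(x) <- NULL
  if (nrow(x) > 1) {
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    if (any(same & x$start[-1] < x$end[-nrow(x)]))
      stop("track steps overlap within a chromosome", call. = FALSE)
  }
  x
}

#' Look up per-base track values at positions
#'
#' @param track track data frame (see [read_bedgraph()]).
#' @param chrom single chromosome name.
#' @param positions integer vector of 0-based positions.
#' @return numeric vector of values (0 where the track has no step).
#' @export
track_values_at <- function(track, chrom, positions) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(t)) return(numeric(length(positions)) )
  t <- t[order(t$start), , drop = FALSE]
  idx <- findInterval(positions, t$start)
  val <- numeric(length(positions))
  ok <- idx > 0
  ok[ok] <- positions[ok] < t$end[idx[ok]]
  val[ok] <- t$value[idx[ok]]
  val
}

#' Summarize track signal over regions
#'
#' `stat = "max"` returns the maximum per-base value in each region (the
#' peak-height statistic); `stat = "mean"` the average per-base value,
#' counting uncovered bases as 0.
#'
#' @param track track data frame.
#' @param regions region data frame.
#' @param stat `"max"` or `"mean"`.
#' @return numeric vector, one value per region.
#' @export
region_signal <- function(track, regions, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  assert_regions(regions)
  track <- validate_track(track)
  n <- nrow(regions)
  out <- numeric(n)
  if (!n || !nrow(track)) return(out)
  hits <- overlap_pairs(regions, track)
  if (!nrow(hits)) return(out)
  ov_start <- pmax(regions$start[hits$query], track$start[hits$subject])
  ov_end <- pmin(regions$end[hits$query], track$end[hits$subject])
  w <- ov_end - ov_start
  v <- track$value[hits$subject]
  if (stat == "max") {
    agg <- tapply(v, hits$query, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  } else {
    sums <- tapply(v * w, hits$query, sum)
    q <- as.integer(names(sums))
    out[q] <- as.numeric(sums) / (regions$end[q] - regions$start[q])
  }
  out
}
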