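# Shared fixtures and independent brute-force oracles used across tests.

# brute-force overlap of two single intervals by per-base membership
brute_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1))) > 0
}

# brute-force merge by painting bases on a toy chromosome and reading runs
brute_merge <- function(regions, chrom_len = 1000) {
  out <- NULL
  for (ch in sort(unique(regions$chrom))) {
    paint <- logical(chrom_len)
    r <- regions[regions$chrom == ch, ]
    for (i in seq_len(nrow(r))) paint[(r$start[i] + 1):r$end[i]] <- TRUE
    runs <- rle(paint)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    keep <- runs$values
    if (any(keep))
      out <- rbind(out, data.frame(chrom = ch, start = starts[keep],
                                   end = ends[keep]))
  }
  if (is.null(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  out
}

# random small intervals on a toy chromosome
random_intervals <- function(n, chrom = "chrT", chrom_len = 1000, max_len = 50) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# exhaustive hypergeometric upper tail by enumerating DE-label assignments:
# probability that a fixed window of n genes holds >= k DE genes when K of
# N genes are DE uniformly at random
enum_hyper_tail <- function(N, K, n, k) {
  combos <- combn(N, K)
  in_win <- seq_len(n)  # the window holds genes 1..n
  hits <- apply(combos, 2, function(set) sum(set %in% in_win))
  mean(hits >= k)
}

# two-gene toy gene set for annotation tests
toy_genes <- function() {
  list(
    gene_model("gA", "chrT", "+",
               list(t1 = data.frame(start = c(1000, 3000), end = c(2000, 4000)))),
    gene_model("gB", "chrT", "-",
               list(t1 = data.frame(start = c(8000, 9500), end = c(9000, 9900)))))
}

toy_track <- function() {
  data.frame(chrom = "chrT", start = c(0L, 50L), end = c(50L, 100L),
             value = c(2, 7), stringsAsFactors = FALSE)
}

make_peaks <- function(chrom, start, end, height, name = NULL) {
  n <- length(start)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = if (is.null(name)) sprintf("p%d", seq_len(n)) else name,
             score = 0, strand = ".",
             summit = as.integer((start + end) %/% 2), height = height,
             stringsAsFactors = FALSE)
}
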