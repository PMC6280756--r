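# Interval arithmetic, gene geometry and format round trips.

test_that("merge_intervals unions, merges book-ended intervals, handles empties", {
  got <- merge_intervals(data.frame(chrom = "c", start = c(10, 15), end = c(20, 30)))
  expect_equal(got$start, 10)
  expect_equal(got$end, 30)

  book <- merge_intervals(data.frame(chrom = "c", start = c(10, 20), end = c(20, 25)))
  expect_equal(nrow(book), 1)
  expect_equal(c(book$start, book$end), c(10, 25))

  expect_equal(nrow(merge_intervals(data.frame(chrom = character(),
                                               start = integer(),
                                               end = integer()))), 0)
  expect_error(merge_intervals(data.frame(chrom = "c", start = 5, end = 5)),
               "coordinates")
})

test_that("merge_intervals is idempotent, order-invariant, never grows coverage", {
  set.seed(11)
  for (i in 1:20) {
    x <- random_intervals(30)
    m1 <- merge_intervals(x)
    expect_identical(merge_intervals(m1), m1)
    shuffled <- x[sample.int(nrow(x)), ]
    expect_identical(merge_intervals(shuffled), m1)
    expect_lte(sum(m1$end - m1$start), sum(x$end - x$start))
  }
})

test_that("merge agrees with a per-base painting oracle", {
  set.seed(12)
  for (i in 1:10) {
    x <- random_intervals(40)
    expect_equal(merge_intervals(x), brute_merge(x), ignore_attr = TRUE)
  }
})

test_that("region_overlaps follows half-open semantics and chromosomes", {
  a <- data.frame(chrom = "chr2", start = 0, end = 10)
  expect_false(region_overlaps(a, data.frame(chrom = "chr2", start = 10, end = 20)))
  expect_true(region_overlaps(a, data.frame(chrom = "chr2", start = 9, end = 20)))
  expect_false(region_overlaps(a, data.frame(chrom = "chr3", start = 0, end = 10)))
})

test_that("region_overlaps agrees with per-base membership on random intervals", {
  set.seed(13)
  q <- random_intervals(60)
  s <- random_intervals(60)
  got <- region_overlaps(q, s)
  for (i in seq_len(nrow(q))) {
    want <- any(vapply(seq_len(nrow(s)), function(j)
      brute_overlap(q[i, ], s[j, ]), logical(1)))
    expect_identical(got[i], want)
  }
})

test_that("projected exons merge transcripts and locate the first intron", {
  g <- gene_model("g1", "c", "+",
                  list(t1 = data.frame(start = c(100, 300), end = c(200, 400))))
  pe <- projected_exons(g)
  expect_equal(pe$exons$start, c(100, 300))
  expect_equal(c(pe$first_intron$start, pe$first_intron$end), c(200, 300))

  # overlapping transcripts collapse to one exon: no first intron
  g2 <- gene_model("g2", "c", "+",
                   list(t1 = data.frame(start = 100, end = 200),
                        t2 = data.frame(start = 150, end = 250)))
  expect_null(projected_exons(g2)$first_intron)

  # minus strand: 5' exon is the genomically last one, intron unchanged
  g3 <- gene_model("g3", "c", "-",
                   list(t1 = data.frame(start = c(100, 300), end = c(200, 400))))
  pe3 <- projected_exons(g3)
  expect_equal(pe3$exons$start[1], 300)
  expect_equal(c(pe3$first_intron$start, pe3$first_intron$end), c(200, 300))

  expect_error(gene_model("g", "c", "+", list()), "transcript")
})

test_that("projection is invariant to transcript order; TSS is strand-aware", {
  t1 <- data.frame(start = c(100, 300), end = c(200, 400))
  t2 <- data.frame(start = c(150, 500), end = c(250, 600))
  a <- projected_exons(gene_model("g", "c", "+", list(t1, t2)))
  b <- projected_exons(gene_model("g", "c", "+", list(t2, t1)))
  expect_identical(a$exons, b$exons)

  tss <- gene_tss(list(gene_model("gp", "c", "+", list(t1)),
                       gene_model("gm", "c", "-", list(t1))))
  expect_equal(tss$tss, c(100, 399))
})

test_that("track lookups, heights and means follow step semantics", {
  tr <- toy_track()
  expect_equal(track_values_at(tr, "chrT", c(0, 49, 50, 99, 100, 500)),
               c(2, 2, 7, 7, 0, 0))
  reg <- data.frame(chrom = "chrT", start = 0, end = 100)
  expect_equal(region_signal(tr, reg, "max"), 7)
  expect_equal(region_signal(tr, reg, "mean"), (2 * 50 + 7 * 50) / 100)
  # uncovered bases count as zero in the mean
  reg2 <- data.frame(chrom = "chrT", start = 50, end = 150)
  expect_equal(region_signal(tr, reg2, "mean"), 7 * 50 / 100)
  expect_equal(region_signal(tr, data.frame(chrom = "chrX", start = 0, end = 10),
                             "max"), 0)
  expect_error(validate_track(data.frame(chrom = "c", start = c(0, 5),
                                         end = c(10, 15), value = 1)),
               "overlap")
})

test_that("GTF, peak, BED and bedGraph round trips preserve content", {
  genes <- toy_genes()
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_genes(genes, f)
  back <- read_gtf_genes(f)
  expect_setequal(names(back), c("gA", "gB"))
  expect_identical(gene_tss(back[order(names(back))]),
                   gene_tss(genes))
  expect_identical(projected_exons(back$gA)$exons,
                   projected_exons(genes[[1]])$exons)

  pk <- make_peaks("chrT", c(100, 500), c(300, 800), c(5.5, 2.25))
  fp <- withr::local_tempfile(fileext = ".bed")
  write_peaks(pk, fp)
  expect_equal(read_peaks(fp), pk, ignore_attr = TRUE)

  tr <- toy_track()
  ft <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, ft)
  expect_equal(read_bedgraph(ft), tr, ignore_attr = TRUE)
})
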