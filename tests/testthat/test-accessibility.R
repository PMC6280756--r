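# Fragment classes, concordant/consensus peaks, differential accessibility,
# and the emerging/increasing classifier.

test_that("fragment classification partitions lengths at the stated cutoffs", {
  expect_equal(classify_fragment(c(99, 100, 180, 247, 248, 150, 1)),
               c("NF", "other", "MN", "MN", "other", "other", "NF"))
  expect_error(classify_fragment(0), "positive")
  expect_error(classify_fragment(-5), "positive")
  lens <- sample.int(500, 200)
  expect_true(all(classify_fragment(lens) %in% c("NF", "MN", "other")))
})

test_that("concordant_peaks keeps rep1 coordinates and averages heights", {
  r1 <- make_peaks("c", c(100, 1000), c(300, 1200), c(10, 4))
  r2 <- make_peaks("c", c(250, 5000), c(400, 5100), c(20, 9))
  got <- concordant_peaks(r1, r2)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 100)            # rep1 coordinates kept
  expect_equal(got$height, mean(c(10, 20)))

  expect_equal(nrow(concordant_peaks(r1, make_peaks("c", 9000, 9100, 1))), 0)
  same <- concordant_peaks(r1, r1)
  expect_equal(same[, c("chrom", "start", "end", "height")],
               r1[, c("chrom", "start", "end", "height")])
})

test_that("concordant_peaks is monotone: enlarging rep2 never drops peaks", {
  set.seed(51)
  r1 <- make_peaks("c", seq(0, 9000, by = 1000), seq(400, 9400, by = 1000),
                   runif(10, 1, 10))
  r2 <- r1[sample.int(10, 5), ]
  kept_small <- concordant_peaks(r1, r2)$name
  kept_big <- concordant_peaks(r1, rbind(r2, make_peaks("c", 20000, 20400, 3)))$name
  expect_true(all(kept_small %in% kept_big))
})

test_that("consensus_regions merges across samples", {
  a <- make_peaks("c", 100, 300, 1)
  b <- make_peaks("c", 250, 500, 1)
  got <- consensus_regions(list(a, b))
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(100, 500))
  expect_equal(nrow(consensus_regions(list())), 0)
})

test_that("differential_accessibility applies presence and 1.5-fold height rules", {
  ctl <- make_peaks("c", c(1000, 3000, 5000), c(1400, 3400, 5400), c(15, 14, 10))
  reg <- make_peaks("c", c(1000, 3000, 8000), c(1400, 3400, 8400), c(30, 15, 12))
  got <- differential_accessibility(ctl, reg)
  expect_equal(nrow(got), 2)
  po <- got[got$mode == "presence_only", ]
  expect_equal(po$start, 8000)
  hf <- got[got$mode == "height_fold", ]
  expect_equal(hf$fold, 30.01 / 15.01)
  # reg 15 vs ctl 14 dropped: fold ~1.07 below threshold
  expect_false(3000 %in% got$start)
})

test_that("differential output count is non-increasing in the threshold", {
  set.seed(52)
  starts <- seq(0, 49000, by = 1000)
  ctl <- make_peaks("c", starts, starts + 400, runif(50, 5, 20))
  reg <- make_peaks("c", starts, starts + 400, runif(50, 5, 40))
  n <- vapply(c(1.2, 1.5, 2, 3), function(th)
    nrow(differential_accessibility(ctl, reg, fc = th)), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("classify_drre: any prior openness makes a region increasing", {
  diff <- data.frame(chrom = "c", start = c(100, 700, 1500),
                     end = c(300, 900, 1700),
                     name = c("a", "b", "d"), stringsAsFactors = FALSE)
  ctl_open <- data.frame(chrom = "c", start = 100, end = 200)
  l3_open <- data.frame(chrom = "c", start = 800, end = 1000)
  got <- classify_drre(diff, ctl_open, l3_open)
  expect_equal(got$drre_class, c("increasing", "increasing", "emerging"))
  # emerging regions never intersect either open set, by construction
  emg <- got[got$drre_class == "emerging", ]
  expect_false(any(region_overlaps(emg, rbind(ctl_open, l3_open))))
})

test_that("planted emerging/increasing labels are recovered exactly", {
  for (s in c(61, 62, 63)) {
    b <- simulate_study(sim_config(seed = s))
    conc_c <- concordant_peaks(b$atac$control$rep1, b$atac$control$rep2)
    conc_r <- concordant_peaks(b$atac$regeneration$rep1, b$atac$regeneration$rep2)
    diff <- differential_accessibility(conc_c, conc_r,
                                       b$tracks$control, b$tracks$regeneration)
    drre <- classify_drre(diff,
                          consensus_regions(list(conc_c)),
                          consensus_regions(list(concordant_peaks(
                            b$atac$l3$rep1, b$atac$l3$rep2))))
    m <- merge(drre[, c("name", "drre_class")],
               b$truth$drre[, c("name", "drre_class")], by = "name")
    expect_equal(nrow(m), nrow(b$truth$drre))
    expect_equal(mean(m$drre_class.x == m$drre_class.y), 1)
  }
})
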