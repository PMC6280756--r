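# Active-enhancer feature statuses, activity calls, delta-delta-Ct.

flat_track <- function(v, len = 10000L)
  data.frame(chrom = "c", start = 0L, end = len, value = v)

test_that("feature_status: marked peak window, strict higher-signal, tie", {
  drre <- data.frame(chrom = "c", start = 2000L, end = 2400L, name = "d1")
  # ChIP peak 400 bp upstream of the DRRE edge: within the 500-bp window
  near <- data.frame(chrom = "c", start = 1500, end = 1600)
  expect_equal(feature_status(drre, near, flat_track(1), flat_track(1)), "marked")
  far <- data.frame(chrom = "c", start = 1000, end = 1100)
  expect_equal(feature_status(drre, far, flat_track(12), flat_track(8)),
               "higher_signal")
  expect_equal(feature_status(drre, far, flat_track(7), flat_track(7)),
               "not_marked")
  # higher_signal is antisymmetric under swapping the tracks
  expect_equal(feature_status(drre, far, flat_track(8), flat_track(12)),
               "not_marked")
})

test_that("activity_call: presence iff any feature marked or higher", {
  st <- data.frame(name = c("a", "b", "d"),
                   H3K4me1 = c("not_marked", "marked", "marked"),
                   H3K27ac = c("not_marked", "not_marked", "marked"),
                   PolII = c("not_marked", "not_marked", "marked"),
                   stringsAsFactors = FALSE)
  got <- activity_call(st)
  expect_equal(got$activity, c("absence", "presence", "presence"))
  expect_equal(got$n_features_present, c(0L, 1L, 3L))
  st$PolII[1] <- NA
  expect_error(activity_call(st), "missing")
})

test_that("planted marked fraction is reproduced exactly in a synthetic cohort", {
  b <- simulate_study(sim_config(seed = 91))
  conc_c <- concordant_peaks(b$atac$control$rep1, b$atac$control$rep2)
  conc_r <- concordant_peaks(b$atac$regeneration$rep1, b$atac$regeneration$rep2)
  drre <- classify_drre(
    differential_accessibility(conc_c, conc_r, b$tracks$control,
                               b$tracks$regeneration),
    consensus_regions(list(conc_c)),
    consensus_regions(list(concordant_peaks(b$atac$l3$rep1, b$atac$l3$rep2))))
  act <- activity_call(feature_status_table(drre, b$chip))
  m <- merge(act[, c("name", "activity")], b$truth$activity, by = "name")
  expect_equal(nrow(m), nrow(b$truth$activity))
  expect_equal(mean(m$activity.x == m$activity.y), 1)
  expect_equal(sum(act$activity == "presence"), length(b$truth$marked))
})

test_that("ddct_fold_enrichment implements the 2^-ddCt formula with SEM", {
  tab <- function(tc, rc, tr, rr) {
    expand <- function(cond, role, v)
      data.frame(region_id = "r1", condition = cond, role = role,
                 replicate = seq_along(v), ct = v, stringsAsFactors = FALSE)
    rbind(expand("control", "target", tc), expand("control", "reference", rc),
          expand("regeneration", "target", tr),
          expand("regeneration", "reference", rr))
  }
  # identical Cts everywhere: fold 1
  same <- ddct_fold_enrichment(tab(20, 18, 20, 18), "r1")
  expect_equal(same$fold, 1)
  # regeneration delta-Ct one cycle lower: fold 2
  expect_equal(ddct_fold_enrichment(tab(25, 20, 24, 20), "r1")$fold, 2)
  # hand evaluation: targets (25, 24), references (20, 20) -> ddCt -1, fold 2
  hand <- ddct_fold_enrichment(tab(25, 20, 24, 20), "r1")
  expect_equal(hand$ddct, -1)
  # replicate spread propagates into a positive SEM
  spread <- ddct_fold_enrichment(tab(c(25, 25.2), c(20, 20.1),
                                     c(24, 23.8), c(20, 19.9)), "r1")
  expect_gt(spread$sem, 0)
  expect_error(ddct_fold_enrichment(tab(25, 20, 24, 20)[-(1:3), ], "r1"),
               "missing")
  expect_error(ddct_fold_enrichment(tab(25, 20, 24, 20), "nope"), "no rows")
})

test_that("self-comparison of any Ct table gives fold 1", {
  set.seed(92)
  for (i in 1:5) {
    ct_t <- runif(3, 18, 30)
    ct_r <- runif(3, 15, 25)
    tab <- rbind(
      data.frame(region_id = "x", condition = "control", role = "target",
                 replicate = 1:3, ct = ct_t),
      data.frame(region_id = "x", condition = "control", role = "reference",
                 replicate = 1:3, ct = ct_r),
      data.frame(region_id = "x", condition = "regeneration", role = "target",
                 replicate = 1:3, ct = ct_t),
      data.frame(region_id = "x", condition = "regeneration",
                 role = "reference", replicate = 1:3, ct = ct_r))
    expect_equal(ddct_fold_enrichment(tab, "x")$fold, 1)
  }
})
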