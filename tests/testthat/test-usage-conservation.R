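# Reused/novel usage, anchored profiles, species conservation, activity.

test_that("classify_usage follows the at-least-one-dataset rule", {
  drres <- data.frame(chrom = "c", start = c(100, 500, 900),
                      end = c(200, 600, 1000), name = c("a", "b", "d"),
                      stringsAsFactors = FALSE)
  refs <- list(embryo = data.frame(chrom = "c", start = 150, end = 250),
               leg = data.frame(chrom = "c", start = c(120, 910),
                                end = c(180, 950)),
               cns = data.frame(chrom = "c", start = 905, end = 990))
  got <- classify_usage(drres, refs)
  expect_equal(got$usage, c("reused", "novel", "reused"))
  expect_equal(got$n_supporting, c(2, 0, 2))
  expect_equal(got$supporting_datasets[1], "embryo,leg")

  # adding reference sets never converts reused -> novel
  more <- c(refs, list(extra = data.frame(chrom = "c", start = 550, end = 620)))
  got2 <- classify_usage(drres, more)
  expect_true(all(got$usage == "reused" | got2$usage == got$usage |
                    got2$usage == "reused"))
  expect_equal(got2$usage[2], "reused")

  labels <- data.frame(label = "bad", stage = "L3", tissue = "wing")
  expect_error(classify_usage(drres, refs["embryo"], labels), "assayed")
})

test_that("anchor_profile averages track values positionwise and is linear", {
  regs <- data.frame(chrom = "c", summit = c(100L, 500L))
  flat <- data.frame(chrom = "c", start = 0L, end = 1000L, value = 3)
  prof <- anchor_profile(regs, flat, flank = 10)
  expect_equal(prof$mean, rep(3, 21))
  expect_equal(prof$offset, -10:10)

  spike <- data.frame(chrom = "c", start = c(100L, 500L), end = c(101L, 501L),
                      value = c(0.2, 0.8))
  ps <- anchor_profile(regs, spike, flank = 5)
  expect_equal(ps$mean[ps$offset == 0], 0.5)
  expect_equal(ps$mean[ps$offset != 0], rep(0, 10))

  # linearity: profile of summed tracks = sum of profiles
  both <- anchor_profile(regs, validate_track(rbind(
    data.frame(chrom = "c", start = 0L, end = 100L, value = 3),
    data.frame(chrom = "c", start = 100L, end = 101L, value = 3.2),
    data.frame(chrom = "c", start = 101L, end = 500L, value = 3),
    data.frame(chrom = "c", start = 500L, end = 501L, value = 3.8),
    data.frame(chrom = "c", start = 501L, end = 1000L, value = 3))), flank = 5)
  expect_equal(both$mean, prof$mean[prof$offset %in% -5:5] + ps$mean)

  expect_equal(nrow(anchor_profile(regs[0, ], flat)), 0)
})

test_that("species_conservation counts species at the tau boundary", {
  drre <- data.frame(chrom = "c", start = 0L, end = 100L, name = "d1")
  masks <- c(lapply(1:5, function(i) data.frame(chrom = "c", start = 0, end = 100)),
             lapply(1:5, function(i) data.frame(chrom = "c", start = 900, end = 950)))
  names(masks) <- sprintf("sp%02d", 1:10)
  got <- species_conservation(drre, masks)
  expect_equal(got$n_species, 5L)
  expect_equal(got$percent_aligned, 50)

  none <- species_conservation(drre, masks[6:10])
  expect_equal(none$n_species, 0L)
  expect_equal(none$percent_aligned, 0)

  # exactly half covered counts as present at tau = 0.5, absent just above
  half <- list(s1 = data.frame(chrom = "c", start = 0, end = 50))
  expect_equal(species_conservation(drre, half, tau = 0.5)$n_species, 1L)
  expect_equal(species_conservation(drre, half, tau = 0.51)$n_species, 0L)

  # n_species is non-increasing in tau
  set.seed(81)
  dd <- data.frame(chrom = "c", start = seq(0, 900, 100),
                   end = seq(50, 950, 100))
  msk <- lapply(1:4, function(i) random_intervals(20, chrom = "c"))
  names(msk) <- paste0("s", 1:4)
  ns <- vapply(c(0.2, 0.5, 0.8), function(tau)
    sum(species_conservation(dd, msk, tau)$n_species), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("activity_overlap reports the overlapping percentage", {
  d4 <- data.frame(chrom = "c", start = c(0, 100, 200, 300),
                   end = c(50, 150, 250, 350))
  act <- data.frame(chrom = "c", start = 10, end = 20)
  expect_equal(activity_overlap(d4, act), 25)
  expect_equal(activity_overlap(d4, d4), 100)
  expect_equal(activity_overlap(d4, data.frame(chrom = "c", start = 900,
                                               end = 950)), 0)
  expect_warning(na <- activity_overlap(d4[0, ], act), "undefined")
  expect_true(is.na(na))
})

test_that("planted reused fraction is observed exactly on synthetic data", {
  b <- simulate_study(sim_config(seed = 82))
  emg <- b$truth$drre[b$truth$drre$drre_class == "emerging", ]
  got <- classify_usage(emg, b$refs, b$ref_labels)
  m <- merge(got[, c("name", "usage")], b$truth$usage, by = "name")
  expect_equal(mean(m$usage.x == m$usage.y), 1)
  expect_equal(sum(got$usage == "reused"),
               round(b$config$reused_fraction * nrow(emg)))
})
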