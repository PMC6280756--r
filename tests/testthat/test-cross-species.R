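# Ortholog classes, cross-species up calls, the regeneration core, the
# permutation null, and the zebrafish DRRE arm.

toy_map <- function() {
  data.frame(
    fly_gene = c("f1", "f1", "f2", "f3", "f3"),
    species = c("zebrafish", "mouse", "zebrafish", "mouse", "zebrafish"),
    ortholog = c("z1", "m1", "z2", "m3", "z3"),
    stringsAsFactors = FALSE)
}

test_that("ortholog_class reflects per-species presence", {
  got <- ortholog_class(c("f1", "f2", "f4"), toy_map())
  expect_equal(got, c("both", "zebrafish_only", "none"))
  expect_equal(ortholog_class("f3", toy_map()), "both")
})

test_that("call_up_species applies the 1.5-fold rule inclusively", {
  expr <- data.frame(gene_id = c("a", "b", "d"),
                     uninjured = c(10, 10, 10), injured = c(30, 10, 14))
  expect_equal(call_up_species(expr), "a")
  # boundary: ratio exactly at threshold is up
  at <- data.frame(gene_id = "x", uninjured = 10, injured = 1.5 * 10.01 - 0.01)
  expect_equal(call_up_species(at), "x")
})

test_that("core_genes requires up orthologs in both species, fly-oriented", {
  map <- toy_map()
  got <- core_genes(fly_up_early = c("f1", "f2"), fly_up_mid = "f3",
                    fish_up = c("z1", "z2", "z3"), mouse_up = c("m1", "m3"),
                    map = map)
  # f1: z1 and m1 both up -> member; f2: no mouse ortholog -> excluded;
  # f3 (mid-only): z3 and m3 up -> member
  expect_setequal(got$gene_id, c("f1", "f3"))
  expect_equal(got$fish_support[got$gene_id == "f1"], "z1")

  # a fly gene with several up fish orthologs still counts once
  map2 <- rbind(map, data.frame(fly_gene = "f1", species = "zebrafish",
                                ortholog = "z9"))
  got2 <- core_genes("f1", character(0), c("z1", "z9"), "m1", map2)
  expect_equal(nrow(got2), 1)

  # monotone in each up-set
  got3 <- core_genes(c("f1", "f2"), "f3", c("z1", "z2", "z3"),
                     c("m1", "m3", "extra"), map)
  expect_true(all(got$gene_id %in% got3$gene_id))
})

test_that("ortholog_enrichment_test degenerate and planted cases", {
  bg <- sprintf("g%03d", 1:200)
  all_true <- setNames(rep(TRUE, 200), bg)
  got <- ortholog_enrichment_test(bg[1:50], bg, all_true, B = 200, seed = 1)
  expect_equal(got$p_value, 1)
  got2 <- ortholog_enrichment_test(bg, bg, setNames(runif(200) < 0.5, bg),
                                   B = 200, seed = 2)
  expect_equal(got2$p_value, 1)
  expect_error(ortholog_enrichment_test(c(bg, "extra"), bg, all_true),
               "larger|subset")

  # planted 2x enrichment is detected, and matches a hypergeometric check
  set.seed(3)
  ind <- c(rep(TRUE, 150), rep(FALSE, 350))[sample.int(500)]
  names(ind) <- sprintf("h%03d", 1:500)
  fly_up <- names(ind)[sample(which(ind), 60)]  # all carriers: enriched
  res <- ortholog_enrichment_test(fly_up, names(ind), ind, B = 2000, seed = 4)
  expect_lt(res$p_value, 0.01)
  p_hyper <- phyper(sum(ind[fly_up]) - 1, sum(ind), sum(!ind), 60,
                    lower.tail = FALSE)
  expect_lt(p_hyper, 0.01)
})

test_that("the permutation test is seeded and reproducible", {
  bg <- sprintf("g%03d", 1:100)
  ind <- setNames(rep(c(TRUE, FALSE), 50), bg)
  a <- ortholog_enrichment_test(bg[1:20], bg, ind, B = 500, seed = 7)
  b <- ortholog_enrichment_test(bg[1:20], bg, ind, B = 500, seed = 7)
  expect_identical(a$p_value, b$p_value)
})

test_that("the planted cross-species core is recovered exactly", {
  b <- simulate_study(sim_config(seed = 101))
  de_early <- call_de(b$expression, "early")
  de_mid <- call_de(b$expression, "mid")
  core <- core_genes(de_early$gene_id[de_early$direction == "up"],
                     de_mid$gene_id[de_mid$direction == "up"],
                     call_up_species(b$species_expression$zebrafish),
                     call_up_species(b$species_expression$mouse),
                     b$orthologs)
  expect_setequal(core$gene_id, b$truth$core)
  expect_equal(nrow(core), b$config$n_core_genes)
})

test_that("zebrafish DRREs: emerging/increasing and embryo reusage", {
  b <- simulate_study(sim_config(seed = 102))
  zf <- zebrafish_drre(
    concordant_peaks(b$zf$uninjured$rep1, b$zf$uninjured$rep2),
    concordant_peaks(b$zf$injured$rep1, b$zf$injured$rep2),
    embryo_open = b$zf$embryo_open, genes = b$zf$genes)
  m <- merge(zf[, c("name", "drre_class", "usage")], b$truth$zf, by = "name")
  expect_equal(nrow(m), nrow(b$truth$zf))
  expect_equal(mean(m$drre_class.x == m$drre_class.y), 1)
  emg <- m$drre_class.y == "emerging"
  expect_equal(mean(m$usage.x[emg] == m$usage.y[emg]), 1)
  # annotation used the wider zebrafish core-promoter window
  expect_true(all(zf$category %in% c("CP", "FI", "proximal", "distal")))
})
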