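test_that("gene dropping respects degenerate allele frequencies", {
  ped <- toy_quad()
  g0 <- gene_drop(ped, rep(0, 5), seed = 1)
  expect_true(all(g0$calls == 0L))
  g1 <- gene_drop(ped, rep(1, 5), seed = 1)
  expect_true(all(g1$calls == 2L))
})

test_that("gene dropping is deterministic under a fixed seed", {
  ped <- hbc_pedigree(1)
  set.seed(1); afs <- runif(50, 0, 0.5)
  a <- gene_drop(ped, afs, seed = 99)
  b <- gene_drop(hbc_pedigree(1), afs, seed = 99)
  expect_identical(a$calls, b$calls)
  expect_false(identical(a$calls, gene_drop(ped, afs, seed = 100)$calls))
})

test_that("male X genotypes are single maternal alleles", {
  ped <- toy_quad()  # two sons
  g <- gene_drop(ped, rep(0.5, 400), seed = 5, chrom = "chrX")
  sons <- c("b1", "b2")
  expect_true(all(g$calls[, sons] %in% c(0L, 2L)))
  expect_true(all(g$hemi[, sons]))
  expect_equal(nrow(mendelian_check(g, ped)), 0L)
})

test_that("planting with full penetrance makes the affected set the carrier set", {
  ped <- hbc_pedigree(1)
  pl <- plant_causal_variant(ped, founder_id = "gm", penetrance = 1,
                             phenocopy = 0, seed = 3)
  expect_setequal(pl$affected, pl$truth$carriers)
  pl0 <- plant_causal_variant(ped, founder_id = "gm", penetrance = 0,
                              phenocopy = 0, seed = 3)
  expect_length(intersect(pl0$affected, pl0$truth$carriers), 0L)
})

test_that("strict recovery rate of a partially penetrant plant matches enumeration", {
  # Family-1-shaped pedigree, variant planted in the affected grandmother's
  # lineage; per replicate the filter config is derived from the realized
  # phenotypes (obligates = affected sequenced, pool = unaffected sequenced)
  ped <- hbc_pedigree(1)
  seq_ids <- sequenced_ids(ped)
  f <- 0.8
  # exhaustive enumeration over the 2^5 transmission patterns:
  # mother inherits from gm; the four daughters inherit from mother
  p_exact <- 0
  for (tm in 0:1) for (t1 in 0:1) for (t2 in 0:1) for (t3 in 0:1)
    for (t4 in 0:1) {
      mother <- tm == 1
      daughters <- mother & (c(t1, t2, t3, t4) == 1)
      n_seq_carriers <- sum(mother, daughters)
      if (n_seq_carriers >= 1) {
        p_exact <- p_exact + (1 / 32) * f^n_seq_carriers
      }
    }
  n_rep <- 400L
  set.seed(20)
  hits <- 0L
  for (r in seq_len(n_rep)) {
    pl <- plant_causal_variant(ped, founder_id = "gm", penetrance = f,
                               phenocopy = 0)
    obl <- intersect(pl$affected, seq_ids)
    if (!length(obl)) next
    pool <- setdiff(seq_ids, obl)
    res <- segregate_strict(pl$geno[, seq_ids], obl, character(0), pool)
    if (res$stratum == "strict") hits <- hits + 1L
  }
  p_hat <- hits / n_rep
  se <- sqrt(p_exact * (1 - p_exact) / n_rep)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("simulated annotations are deterministic and honour the mix", {
  a <- simulate_annotations(200, sim_config(), seed = 42)
  b <- simulate_annotations(200, sim_config(), seed = 42)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_annotation_table(a, f1); write_annotation_table(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  onlym <- simulate_annotations(
    100, sim_config(consequence_mix = c("nonsynonymous SNV" = 1)), seed = 1)
  expect_true(all(onlym$consequence == "missense"))
})

test_that("simulated MMAF mass below the rarity cut matches the analytic mixture", {
  cfg <- sim_config()
  ann <- simulate_annotations(10000, cfg, seed = 13)
  p_exact <- af_mass_below(cfg, 0.001)
  p_hat <- mean(ann$mmaf < 0.001)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(p_hat - p_exact), 3 * se)
  # a round trip through the annotation reader preserves the frequencies
  tf <- tempfile(fileext = ".tsv")
  write_annotation_table(ann, tf)
  back <- read_annotation_table(tf)
  expect_equal(back$mmaf, ann$mmaf, tolerance = 1e-12)
  expect_equal(back$consequence, ann$consequence)
})
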