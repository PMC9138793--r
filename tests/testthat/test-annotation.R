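test_that("MMAF is the maximum over sources, zero-and-novel when empty", {
  expect_equal(as.numeric(compute_mmaf(c(swegen = 2e-4, gnomad = 1.5e-4))),
               2e-4)
  m <- compute_mmaf(list())
  expect_equal(as.numeric(m), 0)
  expect_true(attr(m, "novel"))
  expect_false(attr(compute_mmaf(c(gnomad = 0.1)), "novel"))
  expect_error(compute_mmaf(c(a = 1.2)), "\\[0,1\\]")
  # monotone: adding a source never decreases the MMAF
  set.seed(41)
  for (i in 1:50) {
    base <- stats::runif(sample(1:4, 1))
    extra <- stats::runif(1)
    expect_gte(as.numeric(compute_mmaf(c(base, extra))),
               as.numeric(compute_mmaf(base)))
  }
})

test_that("population filter keeps strictly-below-threshold variants", {
  th <- thresholds()
  ann <- toy_ann(mmaf = c(0.00083, 0.001, 0.0009999, 0, 0.05))
  kept <- population_filter(ann, th)
  expect_setequal(kept$mmaf, c(0.00083, 0.0009999, 0))
  # brute-force comparison oracle on random frequency sets
  set.seed(7)
  ann2 <- toy_ann(mmaf = stats::runif(200, 0, 0.003))
  expect_identical(population_filter(ann2, th)$key,
                   ann2$key[vapply(ann2$mmaf, function(m) m < th$mmaf_max,
                                   logical(1))])
  # idempotent
  expect_identical(population_filter(population_filter(ann2, th), th),
                   population_filter(ann2, th))
})

test_that("consequence classification follows the mapping table", {
  expect_equal(classify_consequence("stopgain"), "nonsense")
  expect_equal(classify_consequence("nonsynonymous SNV"), "missense")
  expect_equal(classify_consequence("frameshift insertion"), "frameshift")
  expect_equal(classify_consequence("splicing"), "splicing")
  expect_warning(out <- classify_consequence("lincRNA"), "lincRNA")
  expect_equal(out, "other")
})

test_that("exonic filter keeps protein-affecting classes and counts add up", {
  mix <- c(missense = 40L, nonsense = 5L, splicing = 8L, frameshift = 3L,
           inframe_indel = 2L, synonymous = 20L, non_exonic = 30L,
           other = 2L)
  ann <- toy_ann(mmaf = 0, consequence = rep(names(mix), times = mix))
  kept <- exonic_filter(ann)
  # counting oracle: retained count equals the sum of per-class counts
  expect_equal(nrow(kept),
               sum(mix[c("missense", "nonsense", "splicing", "frameshift",
                         "inframe_indel")]))
  expect_false(any(kept$consequence %in%
                     c("synonymous", "non_exonic", "other")))
  expect_identical(exonic_filter(kept), kept)
})

test_that("CADD tiers use strict boundaries", {
  th <- thresholds()
  expect_equal(cadd_tiers(c(20.2, 20.0, 27.1, 25.0, 25.2, 0), th),
               c("candidate", "fail", "high_risk", "candidate", "high_risk",
                 "fail"))
  # monotone in thresholds: relaxing never demotes a retained variant
  relaxed <- thresholds(cadd_min = 15, cadd_highrisk = 25)
  t1 <- cadd_tiers(c(16, 22, 30), th)
  t2 <- cadd_tiers(c(16, 22, 30), relaxed)
  expect_true(all(t2[t1 != "fail"] != "fail"))
})

test_that("panel screen reports panel genes below the MMAF cut, side-channel only", {
  expect_length(panel_genes(), 64L)
  fx <- fixtures_once()
  ann <- read_annotation_table(fx$family2$annotations)
  rep2 <- panel_screen(ann)
  expect_true("BRCA2" %in% rep2$gene)
  expect_equal(rep2$rsid[rep2$gene == "BRCA2"], "rs80358899")
  expect_equal(rep2$clinvar[rep2$gene == "BRCA2"], "benign")
  # CASP8 is not on the 64-gene panel
  expect_false("CASP8" %in% rep2$gene)
  # the Family 1 fixture carries 4 panel variants in 3 genes
  ann1 <- read_annotation_table(fx$family1$annotations)
  rep1 <- panel_screen(ann1)
  expect_equal(nrow(rep1), 4L)
  expect_setequal(unique(rep1$gene), c("FANCA", "FANCM", "TOPBP1"))
  # above the 0.2 cut -> dropped
  hot <- toy_ann(mmaf = 0.25, gene = "FANCA")
  expect_equal(nrow(panel_screen(hot)), 0L)
  expect_error(panel_screen(ann, panel = character(0)), "empty")
})

test_that("risk-SNP screen lists carriers with affected status", {
  fx <- fixtures_once()
  f <- fx$family2
  ped <- read_ped(f$ped, f$phenotypes)
  geno <- read_vcf(f$vcf)
  ann <- read_annotation_table(f$annotations)
  rep <- known_snp_screen(ann, geno, ped, "rs1045485")
  expect_setequal(rep$carrier, c("proband", "sister"))
  expect_true(all(rep$affected))
  rep2 <- known_snp_screen(ann, geno, ped, c("rs1045485", "rs999999"))
  expect_equal(rep2$status[rep2$rsid == "rs999999"], "not_observed")
  expect_equal(nrow(known_snp_screen(ann, geno, ped, character(0))), 0L)
})

test_that("annotation filters commute with each other", {
  set.seed(11)
  ann <- simulate_annotations(300, sim_config(), seed = 11)
  th <- thresholds()
  cadd_keep <- function(a) a[cadd_tiers(a$cadd, th) != "fail", , drop = FALSE]
  orders <- list(
    function(a) cadd_keep(exonic_filter(population_filter(a, th))),
    function(a) population_filter(exonic_filter(cadd_keep(a)), th),
    function(a) exonic_filter(cadd_keep(population_filter(a, th))))
  keys <- lapply(orders, function(f) sort(f(ann)$key))
  expect_identical(keys[[1]], keys[[2]])
  expect_identical(keys[[1]], keys[[3]])
})
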