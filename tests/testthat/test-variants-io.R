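write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}

test_that("simple and multi-allelic records decompose to allele counts", {
  p <- write_toy_vcf(c(
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tA\tC,T\t.\tPASS\t.\tGT\t1/2\t0/2",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0|1"))
  g <- read_vcf(p)
  expect_equal(nrow(g$calls), 4L)  # triallelic site became two variants
  expect_equal(unname(g$calls["chr1:100_A/C", ]), c(1L, 2L))
  # each decomposed allele counted against its own key
  expect_equal(unname(g$calls["chr1:200_A/C", ]), c(1L, 0L))
  expect_equal(unname(g$calls["chr1:200_A/T", ]), c(1L, 1L))
  # decomposition preserves each individual's total alt-allele count
  expect_equal(sum(g$calls[c("chr1:200_A/C", "chr1:200_A/T"), "s1"]), 2L)
  # missing and phased calls
  expect_true(is.na(g$calls["chr1:300_G/A", "s1"]))
  expect_equal(unname(g$calls["chr1:300_G/A", "s2"]), 1L)
})

test_that("requesting an absent sample names it in the error", {
  p <- write_toy_vcf("chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/0")
  expect_error(read_vcf(p, sample_subset = c("s1", "nope")), "nope")
})

test_that("VCF write/read round trip preserves keys, order and counts", {
  calls <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3,
                  dimnames = list(NULL, c("s1", "s2")))
  g <- toy_geno(calls)
  p <- tempfile(fileext = ".vcf")
  write_vcf(g, p)
  back <- read_vcf(p)
  expect_identical(rownames(back$calls), rownames(g$calls))
  expect_identical(colnames(back$calls), colnames(g$calls))
  expect_identical(back$calls, g$calls)
  # a second round trip is byte-stable
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("hemizygous male X calls round trip as haploid genotypes", {
  keys <- data.frame(chrom = "chrX", pos = 1000L, ref = "G", alt = "A")
  calls <- matrix(c(2L, 1L), 1, dimnames = list(NULL, c("boy", "girl")))
  hemi <- matrix(c(TRUE, FALSE), 1)
  g <- genotype_matrix(keys, calls, hemi)
  p <- tempfile(fileext = ".vcf")
  write_vcf(g, p)
  expect_match(readLines(p)[5], "GT\t1\t0/1")
  back <- read_vcf(p, sex_of = c(boy = "male", girl = "female"))
  expect_identical(back$calls, g$calls)
  expect_true(back$hemi[1, "boy"])
})

test_that("annotation tables parse fields, novelty and MMAF", {
  fx <- fixtures_once()
  ann <- read_annotation_table(fx$family1$annotations)
  ub <- ann[ann$gene == "UBASH3A", ]
  expect_equal(ub$cadd, 30)
  expect_equal(ub$mmaf, 2e-4)          # max(swegen 2e-4, gnomad 1.5e-4)
  expect_equal(ub$af_gnomad, 1.5e-4)
  expect_false(ub$novel)
  nm <- ann[ann$gene == "NMRK2", ]     # no rsID, observed in no database
  expect_true(nm$novel)
  expect_equal(nm$mmaf, 0)
  expect_equal(nm$consequence, "splicing")
})

test_that("annotation reader rejects duplicates and bad values", {
  tf <- tempfile(fileext = ".tsv")
  hdr <- "chrom\tpos\tref\talt\tgene\tconsequence\tcadd\taf_db"
  writeLines(c(hdr,
               "chr1\t10\tA\tT\tG1\tmissense\t25\t0.0001",
               "chr1\t10\tA\tT\tG1\tmissense\t25\t0.0001"), tf)
  expect_error(read_annotation_table(tf), "duplicate")
  writeLines(c(hdr, "chr1\t10\tA\tT\tG1\tmissense\thigh\t0.0001"), tf)
  expect_error(read_annotation_table(tf), "row 1")
  writeLines(c(hdr, "chr1\t10\tA\tT\tG1\tmissense\t25\t1.7"), tf)
  expect_error(read_annotation_table(tf), "\\[0,1\\]")
  writeLines(hdr, tf)
  expect_equal(nrow(read_annotation_table(tf)), 0L)
})

test_that("candidate tables sort by stratum, CADD, then position", {
  cand <- data.frame(
    filter = c(2L, 1L, 2L, 2L), gene = c("B", "A", "C", "D"),
    chrom = "chr1", pos = c(500L, 100L, 300L, 200L),
    ref = "A", alt = "T", rsid = ".", consequence = "missense",
    hgvs = ".", mmaf = 0, cadd = c(30, 22, 25, 25),
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_candidate_table(cand, p)
  out <- utils::read.delim(p, check.names = FALSE)
  expect_identical(names(out)[1:4], c("Filter", "Gene", "Position", "Ref/Alt"))
  # stratum 1 first, then CADD descending; the CADD-25 tie by position
  expect_identical(out$Gene, c("A", "B", "D", "C"))
  write_candidate_table(cand[0, ], p)
  expect_identical(readLines(p), paste(names(out), collapse = "\t"))
})

test_that("family configs apply defaults and reject bad input", {
  tf <- tempfile(fileext = ".ini")
  writeLines(c("[family]", "id = T", "[obligate_carriers]", "ids = a,b",
               "[excluders]", "ids = c",
               "[slack_pool]", "ids = d,e,f"), tf)
  cfg <- read_family_config(tf)
  expect_equal(cfg$thresholds$mmaf_max, 0.001)
  expect_equal(cfg$thresholds$cadd_min, 20)
  expect_equal(cfg$thresholds$cadd_highrisk, 25)
  expect_equal(cfg$slack_k, 1L)
  expect_length(cfg$strata, 2L)
  expect_equal(cfg$strata[[2]]$slack_max, 1L)

  writeLines(c("[obligate_carriers]", "ids = a", "[slack_pool]", "ids = b",
               "[thresholds]", "slack = -1"), tf)
  expect_error(read_family_config(tf), "nonnegative")

  writeLines(c("[obligate_carriers]", "ids = ghost"), tf)
  expect_error(read_family_config(tf, hbc_pedigree(3)), "ghost")
})

test_that("config write/read round trips the fixture families", {
  for (fam in 1:3) {
    cfg <- hbc_config(fam)
    tf <- tempfile(fileext = ".ini")
    write_family_config(cfg, tf)
    back <- read_family_config(tf, hbc_pedigree(fam))
    expect_equal(back$obligate_carriers, cfg$obligate_carriers)
    expect_equal(length(back$strata), length(cfg$strata))
    for (i in seq_along(cfg$strata)) {
      expect_equal(back$strata[[i]]$obligate_carriers,
                   cfg$strata[[i]]$obligate_carriers)
      expect_equal(back$strata[[i]]$slack_max, cfg$strata[[i]]$slack_max)
    }
  }
})
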