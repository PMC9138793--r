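test_that("carrier status follows the inheritance model", {
  expect_equal(is_carrier(c(0, 1, 2, NA)), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(is_carrier(c(0, 1, 2, NA), model = "recessive"),
               c("non", "het", "hom", "non"))
})

test_that("hemizygous male X carriers are detected", {
  # an X-linked variant: mother het, son hemizygous alt
  keys <- data.frame(chrom = "chrX", pos = 500L, ref = "G", alt = "A")
  calls <- matrix(c(1L, 2L, 0L), 1,
                  dimnames = list(NULL, c("mo", "son", "fa")))
  hemi <- matrix(c(FALSE, TRUE, TRUE), 1)
  g <- genotype_matrix(keys, calls, hemi)
  res <- segregate_strict(g, obligate_carriers = c("mo", "son"),
                          hard_excluders = "fa")
  expect_equal(res$stratum, "strict")
})

test_that("strict segregation matches brute-force set logic on all 3^4 patterns", {
  ids <- c("fa", "mo", "pro", "sis")
  pat <- all_patterns(ids)
  g <- toy_geno(pat)
  obl <- c("mo", "pro"); excl <- "fa"; pool <- "sis"
  res <- segregate_strict(g, obl, excl, pool)
  want <- vapply(seq_len(nrow(pat)), function(i) {
    oracle_strict(carriers_of(pat[i, ]), obl, excl, pool)
  }, logical(1))
  expect_identical(res$stratum == "strict", want)
})

test_that("count and enumeration slack semantics agree on all 3^6 patterns", {
  ids <- c("m", "p", "f", "s1", "s2", "s3")
  pat <- all_patterns(ids)
  g <- toy_geno(pat)
  obl <- c("m", "p"); excl <- "f"; pool <- c("s1", "s2", "s3")
  for (k in 1:2) {
    by_count <- segregate_slack(g, obl, excl, pool, slack_k = k,
                                method = "count")
    by_enum <- segregate_slack(g, obl, excl, pool, slack_k = k,
                               method = "enumerate")
    expect_identical(by_count$stratum == "slack_only",
                     by_enum$stratum == "slack_only")
    # and both agree with the direct set-comprehension oracle
    want <- vapply(seq_len(nrow(pat)), function(i) {
      oracle_slack_only(carriers_of(pat[i, ]), obl, excl, pool, k)
    }, logical(1))
    expect_identical(by_count$stratum == "slack_only", want)
  }
})

test_that("strict and slack strata are disjoint and slack grows with k", {
  ids <- c("m", "p", "f", "s1", "s2", "s3")
  pat <- all_patterns(ids)
  g <- toy_geno(pat)
  obl <- c("m", "p"); excl <- "f"; pool <- c("s1", "s2", "s3")
  prev_pass <- NULL
  for (k in 0:3) {
    strata <- dominant_strata(obl, excl, pool, k)
    res <- segregate(g, strata)
    strict_keys <- res$key[res$stratum == "strict"]
    slack_keys <- res$key[res$stratum == "slack"]
    expect_length(intersect(strict_keys, slack_keys), 0L)
    if (k == 0) expect_length(slack_keys, 0L)
    pass <- union(strict_keys, slack_keys)
    if (!is.null(prev_pass)) expect_true(all(prev_pass %in% pass))
    prev_pass <- pass
  }
})

test_that("missing genotypes fail obligates but tolerate pool members", {
  calls <- rbind(c(NA, 1L, 0L, 0L),
                 c(1L, 1L, NA, 0L))
  colnames(calls) <- c("m", "p", "s1", "f")
  g <- toy_geno(calls)
  res <- segregate(g, dominant_strata(c("m", "p"), "f", "s1", 1L))
  expect_equal(res$stratum[1], "fail")
  expect_equal(res$reason[1], "genotype_incomplete")
  # missing slack-pool call counts as non-carrier, flagged
  expect_equal(res$stratum[2], "strict")
  expect_true(res$missing_nonobligate[2])
})

test_that("per-stratum obligate sets separate shared-by-three from shared-by-four", {
  # Family 2 style: 3 breast+lung obligates, breast-only proband decides
  ids <- c("mother", "aunt", "sister", "proband")
  strata <- hbc_config(2)$strata
  calls <- rbind(c(1L, 1L, 1L, 0L),   # the three only   -> strict
                 c(1L, 1L, 1L, 1L),   # all four         -> slack_only
                 c(1L, 1L, 0L, 1L),   # obligate missing -> fail
                 c(0L, 0L, 0L, 1L))   # proband only     -> fail
  colnames(calls) <- ids
  res <- segregate(toy_geno(calls), strata)
  expect_equal(res$stratum, c("strict", "slack_only", "fail", "fail"))
})

test_that("recessive search requires homozygous patients and het parents", {
  ids <- c("fa", "mo", "b1", "b2")
  calls <- rbind(c(1L, 1L, 2L, 2L),   # the textbook pattern -> pass
                 c(2L, 1L, 2L, 2L),   # a homozygous parent  -> fail
                 c(1L, 1L, 2L, 1L),   # het patient          -> fail
                 c(1L, 1L, 2L, NA))   # missing patient      -> fail
  colnames(calls) <- ids
  res <- segregate_recessive(toy_geno(calls), obligate_carriers = c("b1", "b2"),
                             parent_set = c("fa", "mo"))
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$reason[2], "parent_not_heterozygous")
  expect_equal(res$reason[4], "genotype_incomplete")
  expect_error(segregate_recessive(toy_geno(calls), "b1", character(0)),
               "non-empty")
})

test_that("the empty cascade yields empty candidates and a zero funnel", {
  ann <- toy_ann(numeric(0))
  g <- toy_geno(matrix(integer(0), 0, 2,
                       dimnames = list(NULL, c("m", "p"))))
  cc <- run_family_cascade(ann, g, dominant_strata("m", character(0), "p", 1L))
  expect_equal(nrow(cc$candidates), 0L)
  expect_true(all(cc$funnel$count == 0L))
})

test_that("funnel counts never increase along the cascade", {
  fx <- fixtures_once()
  for (fam in names(fx)) {
    cc <- run_fixture_cascade(fx[[fam]])
    fl <- cc$funnel
    pre <- fl$count[fl$stage %in% c("total", "post_population", "post_exonic")]
    expect_true(all(diff(pre) <= 0))
    seg_total <- sum(fl$count[fl$stage %in%
      c("post_segregation_strict", "post_segregation_slack")])
    expect_lte(seg_total, fl$count[fl$stage == "post_exonic"])
    expect_lte(fl$count[fl$stage == "candidates_total"], seg_total)
    # summary parts always add to the total
    s <- summarize_candidates(cc)
    expect_equal(s$strict + s$slack_only, s$total)
  }
})
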