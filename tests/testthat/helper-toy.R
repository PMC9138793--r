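# shared builders and independent oracles

toy_quad <- function() {
  pedigree("quad", data.frame(
    id = c("fa", "mo", "b1", "b2"),
    father_id = c(NA, NA, "fa", "fa"),
    mother_id = c(NA, NA, "mo", "mo"),
    sex = c("male", "female", "male", "male"),
    sequenced = TRUE),
    phenotypes = list(
      b1 = data.frame(label = "breast_cancer", onset = 25),
      b2 = data.frame(label = "rcc", onset = 35)))
}

# genotype matrix from a plain calls matrix (cols = individuals)
toy_geno <- function(calls, chrom = "chr1") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n <- nrow(calls)
  keys <- data.frame(chrom = rep_len(chrom, n), pos = seq_len(n) * 10L,
                     ref = rep_len("A", n), alt = rep_len("G", n),
                     stringsAsFactors = FALSE)
  genotype_matrix(keys, calls)
}

# all allele-count patterns (0/1/2) over the given individuals, one per row
all_patterns <- function(ids) {
  g <- as.matrix(expand.grid(rep(list(0:2), length(ids))))
  colnames(g) <- ids
  g
}

# set-comprehension oracles for the segregation predicates
oracle_strict <- function(carriers, obl, excl, pool) {
  all(obl %in% carriers) && !any(c(excl, pool) %in% carriers)
}
oracle_slack_only <- function(carriers, obl, excl, pool, k) {
  n_pool <- sum(pool %in% carriers)
  all(obl %in% carriers) && !any(excl %in% carriers) &&
    n_pool >= 1 && n_pool <= k
}

carriers_of <- function(pattern_row) {
  names(pattern_row)[pattern_row >= 1]
}

# minimal annotation frame for filter tests
toy_ann <- function(mmaf, consequence = "missense", cadd = 30,
                    gene = NULL, chrom = "chr1") {
  n <- if (length(mmaf) == 0L) 0L
       else max(length(mmaf), length(consequence), length(cadd))
  mmaf <- rep_len(mmaf, n); consequence <- rep_len(consequence, n)
  cadd <- rep_len(cadd, n)
  if (is.null(gene)) gene <- paste0("G", seq_len(n))
  ann <- data.frame(
    chrom = rep_len(chrom, n), pos = seq_len(n) * 100L,
    ref = rep_len("A", n), alt = rep_len("T", n),
    gene = rep_len(gene, n), consequence = consequence,
    consequence_raw = consequence, cadd = cadd, mmaf = mmaf,
    rsid = rep_len(".", n), clinvar = rep_len("absent", n),
    hgvs = rep_len(".", n), novel = mmaf == 0, stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  class(ann) <- c("variant_annotation", "data.frame")
  ann
}

# one cached fixture bundle per test run
fixtures_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- hbc_family_fixtures(file.path(tempdir(), "pedfilter-fixtures"))
    }
    cache
  }
})

run_fixture_cascade <- function(f) {
  ped <- read_ped(f$ped, f$phenotypes)
  cfg <- read_family_config(f$config, ped)
  geno <- read_vcf(f$vcf, sex_of = stats::setNames(ped$ind$sex, ped$ind$id))
  ann <- read_annotation_table(f$annotations)
  run_family_cascade(ann, geno, cfg)
}
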