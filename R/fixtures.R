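# Built-in fixtures: three hereditary breast cancer families (non-BRCA,
# autosomal dominant pattern) with their published candidate-variant tables.
# Genotypes encode the reported carrier patterns; per-source allele
# frequencies and the decoy variants are synthetic reconstructions.

#' Pedigree of a built-in example family
#'
#' Family 1: three generations of bilateral breast cancer; sequenced are
#' the proband (onset 40), her affected mother (onset 52), her unaffected
#' father and three healthy sisters. Family 2: four women with breast
#' cancer (three also with lung cancer), all sequenced; the proband's son
#' with a GIST is unaffected for breast-cancer filtering and unsequenced.
#' Family 3: two brothers with early-onset cancer (breast at 25, renal
#' cell at 35) and their healthy sequenced parents.
#'
#' @param family Integer 1, 2 or 3.
#' @return A [pedigree()].
#' @export
hbc_pedigree <- function(family) {
  if (family == 1) {
    ind <- data.frame(
      id = c("gm", "gf", "father", "mother", "proband",
             "sister1", "sister2", "sister3"),
      father_id = c(NA, NA, NA, "gf", "father", "father", "father", "father"),
      mother_id = c(NA, NA, NA, "gm", "mother", "mother", "mother", "mother"),
      sex = c("female", "male", "male", "female", "female",
              "female", "female", "female"),
      sequenced = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
    phen <- list(
      gm = data.frame(label = "breast_cancer", onset = 42),
      mother = data.frame(label = "breast_cancer", onset = 52),
      proband = data.frame(label = "breast_cancer", onset = 40))
    return(pedigree("Family1", ind, phen))
  }
  if (family == 2) {
    ind <- data.frame(
      id = c("gf2", "gm2", "father", "mother", "aunt", "husband",
             "proband", "sister", "son"),
      father_id = c(NA, NA, NA, "gf2", "gf2", NA, "father", "father",
                    "husband"),
      mother_id = c(NA, NA, NA, "gm2", "gm2", NA, "mother", "mother",
                    "proband"),
      sex = c("male", "female", "male", "female", "female", "male",
              "female", "female", "male"),
      sequenced = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE,
                    FALSE))
    phen <- list(
      mother = data.frame(label = c("breast_cancer", "lung_cancer"),
                          onset = c(72, NA)),
      aunt = data.frame(label = c("breast_cancer", "lung_cancer"),
                        onset = c(75, 84)),
      proband = data.frame(label = "breast_cancer", onset = 51),
      sister = data.frame(label = c("breast_cancer", "lung_cancer"),
                          onset = c(47, 57)),
      son = data.frame(label = "gist", onset = 42))
    return(pedigree("Family2", ind, phen))
  }
  if (family == 3) {
    ind <- data.frame(
      id = c("father", "mother", "brother1", "brother2"),
      father_id = c(NA, NA, "father", "father"),
      mother_id = c(NA, NA, "mother", "mother"),
      sex = c("male", "female", "male", "male"),
      sequenced = TRUE)
    phen <- list(
      brother1 = data.frame(label = "breast_cancer", onset = 25),
      brother2 = data.frame(label = "rcc", onset = 35))
    return(pedigree("Family3", ind, phen))
  }
  stop("family must be 1, 2 or 3")
}

#' Segregation configuration of a built-in example family
#'
#' Family 1: the affected mother and proband are obligate carriers, the
#' father is a hard excluder in both strata (maternal inheritance), the
#' three healthy sisters form the slack pool with one non-penetrant
#' carrier tolerated. Family 2: stratum 1 obligates the three breast+lung
#' patients with the breast-only proband in a zero-slack pool (her
#' carrying moves a variant to stratum 2 rather than discarding it);
#' stratum 2 obligates all four. Family 3: the brothers are obligate, the
#' healthy parents form the slack pool with one carrier tolerated.
#'
#' @param family Integer 1, 2 or 3.
#' @return A `family_config` list (see [read_family_config()]).
#' @export
hbc_config <- function(family) {
  th <- thresholds()
  if (family == 1) {
    cfg <- list(family_id = "Family1", model = "dominant",
                affected = c("mother", "proband"),
                obligate_carriers = c("mother", "proband"),
                hard_excluders = "father",
                slack_pool = c("sister1", "sister2", "sister3"),
                slack_k = 1L, parent_set = character(0), thresholds = th)
    cfg$strata <- dominant_strata(cfg$obligate_carriers, cfg$hard_excluders,
                                  cfg$slack_pool, 1L)
    cfg$strata[[2]]$name <- "slack_only"
  } else if (family == 2) {
    cfg <- list(family_id = "Family2", model = "dominant",
                affected = c("mother", "aunt", "sister", "proband"),
                obligate_carriers = c("mother", "aunt", "sister"),
                hard_excluders = character(0),
                slack_pool = "proband",
                slack_k = 0L, parent_set = character(0), thresholds = th)
    s2 <- seg_stratum("slack_only",
                      c("mother", "aunt", "sister", "proband"))
    cfg$strata <- list(
      seg_stratum("strict", cfg$obligate_carriers, character(0),
                  "proband", 0L, 0L),
      s2)
    cfg$stratum2_override <- s2
  } else if (family == 3) {
    cfg <- list(family_id = "Family3", model = "dominant",
                affected = c("brother1", "brother2"),
                obligate_carriers = c("brother1", "brother2"),
                hard_excluders = character(0),
                slack_pool = c("mother", "father"),
                slack_k = 1L, parent_set = character(0), thresholds = th)
    cfg$strata <- dominant_strata(cfg$obligate_carriers, character(0),
                                  cfg$slack_pool, 1L)
    cfg$strata[[2]]$name <- "slack_only"
  } else stop("family must be 1, 2 or 3")
  class(cfg) <- "family_config"
  cfg
}

raw_label_of <- c(missense = "nonsynonymous SNV", nonsense = "stopgain",
                  splicing = "splicing")

read_builtin_table <- function(family) {
  path <- system.file("extdata",
                      sprintf("family%d_candidates.tsv", family),
                      package = "pedfilter")
  tb <- utils::read.delim(path, colClasses = "character")
  tb$chrom <- sub(":.*$", "", tb$position)
  tb$pos <- as.integer(sub("^.*:", "", tb$position))
  tb$mmaf <- as.numeric(tb$mmaf)
  tb$cadd <- as.numeric(tb$cadd)
  tb$filter <- as.integer(tb$filter)
  tb
}

#' Published candidate tables of the built-in families
#'
#' The per-family candidate variants (gene, hg19 position, alleles, rsID,
#' consequence, transcript change, MMAF, CADD, filter stratum) as bundled
#' under `extdata`. The Family 1 FBXL4 position exceeds the chr6 length;
#' it is carried verbatim and flagged, not corrected.
#'
#' @param family Integer 1, 2 or 3.
#' @return Data.frame of the table rows.
#' @export
hbc_candidate_table <- function(family) read_builtin_table(family)

# decoy + side-channel variants; each decoy fails exactly one stage
fixture_extras <- function(family) {
  strict_carriers <- switch(as.character(family),
    `1` = "mother,proband",
    `2` = "mother,aunt,sister",
    `3` = "brother1,brother2")
  d <- data.frame(
    gene = sprintf("DECOY%d_%02d", family, 1:16),
    chrom = "chr1",
    pos = 100000L + family * 1000L + 1:16,
    ref = "C", alt = "T", rsid = ".",
    type = "missense", change = ".",
    mmaf = 0, cadd = 26, clinvar = ".",
    carriers = strict_carriers,
    stringsAsFactors = FALSE)
  d$mmaf[1:4] <- c(0.05, 0.01, 0.12, 0.3)           # fail population filter
  d$type[5:8] <- c("intronic", "UTR5", "synonymous SNV", "ncRNA_intronic")
  d$mmaf[5:8] <- 0.00005                            # fail exonic filter only
  d$cadd[9:12] <- c(5, 12, 19.5, 20)                # fail CADD (20 boundary)
  d$mmaf[9:12] <- 0.00005
  seg_patterns <- switch(as.character(family),                    # fail segregation only
    `1` = c("father,mother,proband",                # hard excluder carries
            "mother,proband,sister1,sister2",       # two slack carriers
            "NA:mother|proband",                    # obligate genotype missing
            "proband"),                             # obligate non-carrier
    `2` = c("mother,aunt",                          # 2 of 3 obligates
            "proband",
            "NA:mother|aunt,sister",
            "aunt,sister,proband"),                 # mother non-carrier
    `3` = c("father,mother,brother1,brother2",      # both parents carry
            "brother1",
            "NA:brother1|brother2",
            "father,mother"))
  d$carriers[13:16] <- seg_patterns
  extras <- NULL
  if (family == 1) {
    extras <- data.frame(
      gene = c("FANCA", "FANCA", "FANCM", "TOPBP1"),
      chrom = c("chr16", "chr16", "chr14", "chr3"),
      pos = c(89849480L, 89858000L, 45658326L, 133376651L),
      ref = c("C", "G", "T", "G"), alt = c("T", "A", "C", "A"),
      rsid = ".", type = "missense", change = ".",
      mmaf = c(0.02, 0.003, 0.15, 0.08), cadd = c(10, 8, 12, 9),
      clinvar = "benign", carriers = "mother,proband",
      stringsAsFactors = FALSE)
  }
  if (family == 2) {
    extras <- data.frame(
      gene = c("BRCA2", "CASP8"),
      chrom = c("chr13", "chr2"),
      pos = c(32913055L, 202149589L),
      ref = c("A", "G"), alt = c("G", "C"),
      rsid = c("rs80358899", "rs1045485"),
      type = "missense", change = ".",
      mmaf = c(0.0005, 0.13), cadd = c(15, 10),
      clinvar = "benign",
      carriers = c("proband", "proband,sister"),
      stringsAsFactors = FALSE)
  }
  rbind(d, extras)
}

fixture_variant_frame <- function(family) {
  tb <- read_builtin_table(family)
  pool <- switch(as.character(family),
    `1` = c("sister1", "sister2", "sister3"),
    `2` = character(0),
    `3` = c("mother", "father"))
  strict <- switch(as.character(family),
    `1` = c("mother", "proband"),
    `2` = c("mother", "aunt", "sister"),
    `3` = c("brother1", "brother2"))
  slack_extra <- switch(as.character(family), `1` = NULL, `2` = "proband", `3` = NULL)
  carriers <- character(nrow(tb))
  slack_i <- 0L
  for (r in seq_len(nrow(tb))) {
    if (tb$filter[r] == 1L) {
      carriers[r] <- paste(strict, collapse = ",")
    } else if (family == 2) {
      carriers[r] <- paste(c(strict, slack_extra), collapse = ",")
    } else {
      # rotate the single permitted non-penetrant carrier through the pool
      slack_i <- slack_i + 1L
      extra <- pool[(slack_i - 1L) %% length(pool) + 1L]
      carriers[r] <- paste(c(strict, extra), collapse = ",")
    }
  }
  main <- data.frame(
    gene = tb$gene, chrom = tb$chrom, pos = tb$pos, ref = tb$ref,
    alt = tb$alt, rsid = tb$rsid, type = tb$type, change = tb$change,
    mmaf = tb$mmaf, cadd = tb$cadd, clinvar = tb$clinvar,
    carriers = carriers, stringsAsFactors = FALSE)
  rbind(main, fixture_extras(family))
}

fixture_annotation <- function(vf) {
  af1 <- ifelse(vf$mmaf > 0, vf$mmaf, NA_real_)
  ann <- data.frame(
    chrom = vf$chrom, pos = vf$pos, ref = vf$ref, alt = vf$alt,
    gene = vf$gene,
    consequence_raw = ifelse(vf$type %in% names(raw_label_of),
                             raw_label_of[vf$type], vf$type),
    cadd = vf$cadd, rsid = vf$rsid,
    clinvar = ifelse(vf$clinvar == ".", "absent", vf$clinvar),
    hgvs = vf$change,
    af_swegen = af1, af_gnomad = signif(0.75 * af1, 3),
    stringsAsFactors = FALSE)
  ann$mmaf <- ifelse(is.na(af1), 0, af1)
  ann$novel <- is.na(af1) & ann$rsid == "."
  ann$consequence <- classify_consequence(ann$consequence_raw)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  attr(ann, "af_cols") <- c("af_swegen", "af_gnomad")
  class(ann) <- c("variant_annotation", "data.frame")
  ann
}

fixture_genotypes <- function(vf, ped) {
  samples <- sequenced_ids(ped)
  calls <- matrix(0L, nrow(vf), length(samples),
                  dimnames = list(NULL, samples))
  for (r in seq_len(nrow(vf))) {
    pattern <- vf$carriers[r]
    na_ids <- character(0)
    if (grepl("^NA:", pattern)) {
      body <- sub("^NA:", "", pattern)
      parts <- strsplit(body, "|", fixed = TRUE)[[1]]
      na_ids <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
      pattern <- if (length(parts) > 1L) parts[2] else ""
    }
    ids <- if (nzchar(pattern)) strsplit(pattern, ",", fixed = TRUE)[[1]]
           else character(0)
    calls[r, intersect(ids, samples)] <- 1L
    calls[r, intersect(na_ids, samples)] <- NA_integer_
  }
  keys <- vf[, c("chrom", "pos", "ref", "alt")]
  sex_of <- stats::setNames(ped$ind$sex, ped$ind$id)
  hemi <- matrix(FALSE, nrow(vf), length(samples),
                 dimnames = list(NULL, samples))
  on_x <- norm_chrom(vf$chrom) == "chrX"
  for (s in samples) {
    if (identical(sex_of[[s]], "male")) {
      hemi[on_x, s] <- TRUE
      calls[on_x, s] <- 2L * calls[on_x, s]
    }
  }
  genotype_matrix(keys, calls, hemi)
}

#' Build the three example-family fixture bundles
#'
#' Writes, per family, a plain-text VCF of the sequenced members'
#' genotypes, a PED file with a phenotype sidecar, an annotation TSV and a
#' segregation config — everything [run_pipeline()] needs. The genotypes
#' encode the reported carrier patterns: strict-stratum rows are carried
#' by the obligate carriers only; slack rows additionally by exactly one
#' slack-pool member, rotated deterministically (row index modulo pool
#' size) since the source tables do not say which healthy relative
#' carried which variant (the choice affects no count). Each family also
#' carries sixteen decoy variants failing exactly one stage each (common
#' MMAF, non-exonic, low CADD, segregation-inconsistent) plus the panel /
#' risk-SNP side-channel variants. Output is deterministic.
#'
#' @param out_dir Directory to write into (created if needed).
#' @param families Which of 1:3 to build.
#' @return Named list per family with file paths (`vcf`, `ped`,
#'   `phenotypes`, `annotations`, `config`) and the in-memory objects
#'   (`pedigree`, `annotation`, `genotypes`, `config_obj`).
#' @export
hbc_family_fixtures <- function(out_dir = tempfile("hbc_fixtures"),
                                families = 1:3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (fam in families) {
    fd <- file.path(out_dir, sprintf("family%d", fam))
    dir.create(fd, showWarnings = FALSE)
    ped <- hbc_pedigree(fam)
    cfg <- hbc_config(fam)
    vf <- fixture_variant_frame(fam)
    ord <- order(norm_chrom(vf$chrom), vf$pos)
    vf <- vf[ord, , drop = FALSE]
    ann <- fixture_annotation(vf)
    geno <- fixture_genotypes(vf, ped)
    paths <- list(
      vcf = file.path(fd, "genotypes.vcf"),
      ped = file.path(fd, "pedigree.ped"),
      phenotypes = file.path(fd, "phenotypes.tsv"),
      annotations = file.path(fd, "annotations.tsv"),
      config = file.path(fd, "config.ini"))
    write_vcf(geno, paths$vcf)
    write_ped(ped, paths$ped, paths$phenotypes)
    write_annotation_table(ann, paths$annotations)
    write_family_config(cfg, paths$config)
    out[[sprintf("family%d", fam)]] <- c(paths, list(
      pedigree = ped, annotation = ann, genotypes = geno, config_obj = cfg,
      dir = fd))
  }
  out
}
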