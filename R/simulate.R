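#' Simulation configuration
#'
#' Defaults describe a rare-exome background: per-site alternate-allele
#' frequencies drawn from a mixture of a point mass at 0 (weight
#' `af_zero_weight`, never-observed sites) and a log-uniform distribution
#' over `af_range`; CADD scores uniform over `cadd_range`; consequence
#' classes drawn from `consequence_mix`. These are the study conditions the
#' filters assume (rare, mostly missense exonic variation in dominant
#' pedigrees), not tuning knobs.
#'
#' @param n_background_variants Number of background sites.
#' @param af_zero_weight Mixture weight of the point mass at frequency 0.
#' @param af_range Log-uniform support for nonzero frequencies.
#' @param cadd_range Uniform support for simulated CADD scores.
#' @param consequence_mix Named probability vector over raw consequence
#'   labels (must sum to 1).
#' @param penetrance Probability that a causal-variant carrier is affected.
#' @param phenocopy Probability that a non-carrier is affected.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_background_variants = 1000L,
                       af_zero_weight = 0.05,
                       af_range = c(1e-6, 0.5),
                       cadd_range = c(0, 40),
                       consequence_mix = c(
                         "nonsynonymous SNV" = 0.55,
                         "synonymous SNV" = 0.25,
                         "intronic" = 0.10,
                         "splicing" = 0.05,
                         "stopgain" = 0.02,
                         "frameshift insertion" = 0.02,
                         "nonframeshift deletion" = 0.01),
                       penetrance = 1, phenocopy = 0) {
  if (abs(sum(consequence_mix) - 1) > 1e-8) {
    stop("consequence_mix must sum to 1")
  }
  probs <- c(af_zero_weight, penetrance, phenocopy)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  structure(list(n_background_variants = as.integer(n_background_variants),
                 af_zero_weight = af_zero_weight, af_range = af_range,
                 cadd_range = cadd_range, consequence_mix = consequence_mix,
                 penetrance = penetrance, phenocopy = phenocopy),
            class = "sim_config")
}

#' Analytic mass of the simulated MMAF distribution below a bound
#'
#' Closed form for the default mixture of [sim_config()]: the point mass at
#' zero plus the log-uniform mass below `bound`.
#'
#' @param config A [sim_config()].
#' @param bound Frequency bound (exclusive).
#' @return Probability that a simulated site's frequency is `< bound`.
#' @export
af_mass_below <- function(config, bound) {
  lo <- config$af_range[1]; hi <- config$af_range[2]
  p <- if (bound <= lo) 0 else if (bound >= hi) 1 else {
    (log(bound) - log(lo)) / (log(hi) - log(lo))
  }
  config$af_zero_weight + (1 - config$af_zero_weight) * p
}

ped_topo_order <- function(ped) {
  ind <- ped$ind
  order_ids <- character(0)
  remaining <- ind$id
  repeat {
    ready <- vapply(remaining, function(id) {
      i <- match(id, ind$id)
      f <- ind$father_id[i]; m <- ind$mother_id[i]
      (is.na(f) || f %in% order_ids) && (is.na(m) || m %in% order_ids)
    }, logical(1))
    if (!any(ready)) stop("pedigree is not acyclic")
    order_ids <- c(order_ids, remaining[ready])
    remaining <- remaining[!ready]
    if (!length(remaining)) break
  }
  order_ids
}

#' Mendelian gene dropping down a pedigree
#'
#' Founders draw two alleles independently with the per-site alternate
#' frequency; every non-founder inherits one uniformly chosen allele from
#' each parent. On male X (non-PAR) a male carries a single maternal
#' allele, stored as allele count 0/2 with a hemizygous flag, and transmits
#' his X allele to every daughter.
#'
#' @param ped A [pedigree()].
#' @param site_afs Numeric vector of alternate-allele frequencies in
#'   `[0,1]`, one per site.
#' @param seed Optional integer seed.
#' @param chrom Chromosome name(s) per site (default `"chr1"`, autosomal).
#' @return A [genotype_matrix()] over all pedigree individuals (subset to
#'   [sequenced_ids()] before segregation analysis).
#' @export
gene_drop <- function(ped, site_afs, seed = NULL, chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  if (any(site_afs < 0 | site_afs > 1)) stop("site_afs must lie in [0,1]")
  n <- length(site_afs)
  chrom <- rep_len(norm_chrom(chrom), n)
  ids <- ped$ind$id
  sex <- stats::setNames(ped$ind$sex, ids)
  fa <- stats::setNames(ped$ind$father_id, ids)
  mo <- stats::setNames(ped$ind$mother_id, ids)
  is_x <- grepl("^chrX$", chrom)
  a1 <- a2 <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (id in ped_topo_order(ped)) {
    founder_f <- is.na(fa[[id]]); founder_m <- is.na(mo[[id]])
    male <- identical(sex[[id]], "male")
    # maternal allele
    a2[, id] <- if (founder_m) stats::rbinom(n, 1L, site_afs) else {
      pick <- stats::runif(n) < 0.5
      ifelse(pick, a1[, mo[[id]]], a2[, mo[[id]]])
    }
    # paternal allele
    pat <- if (founder_f) stats::rbinom(n, 1L, site_afs) else {
      pick <- stats::runif(n) < 0.5
      pat_auto <- ifelse(pick, a1[, fa[[id]]], a2[, fa[[id]]])
      # on X a father transmits his single (maternal-origin) X allele
      ifelse(is_x, a2[, fa[[id]]], pat_auto)
    }
    a1[, id] <- pat
    if (male) a1[is_x, id] <- a2[is_x, id]  # male X: single maternal allele
  }
  calls <- a1 + a2
  hemi <- matrix(FALSE, n, length(ids), dimnames = list(NULL, ids))
  for (id in ids) if (identical(sex[[id]], "male")) hemi[is_x, id] <- TRUE
  keys <- data.frame(chrom = chrom, pos = seq_len(n) * 1000L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(keys, calls, hemi)
}

#' Check a genotype matrix for Mendelian consistency
#'
#' Exhaustive trio check: for every individual with at least one parent in
#' the pedigree and every site, the allele count must be composable from
#' one allele of each available parent (allele sets: 0 -> \{0\}, 1 ->
#' \{0,1\}, 2 -> \{1\}; missing parents contribute \{0,1\}).
#' Hemizygous-flagged calls are checked as single maternal alleles.
#'
#' @param geno A [genotype_matrix()] covering the pedigree individuals.
#' @param ped A [pedigree()].
#' @return Data.frame of violations (`key`, `individual`), zero rows when
#'   fully consistent.
#' @export
mendelian_check <- function(geno, ped) {
  allele_sets <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  viol <- list()
  ids <- colnames(geno$calls)
  for (id in ids) {
    i <- match(id, ped$ind$id)
    f <- ped$ind$father_id[i]; m <- ped$ind$mother_id[i]
    if (is.na(f) && is.na(m)) next
    for (v in seq_len(nrow(geno$calls))) {
      c_ac <- geno$calls[v, id]
      if (is.na(c_ac)) next
      pa <- if (!is.na(f) && f %in% ids && !is.na(geno$calls[v, f])) {
        allele_sets[[as.character(geno$calls[v, f])]]
      } else c(0L, 1L)
      ma <- if (!is.na(m) && m %in% ids && !is.na(geno$calls[v, m])) {
        allele_sets[[as.character(geno$calls[v, m])]]
      } else c(0L, 1L)
      possible <- if (geno$hemi[v, id]) 2L * ma else unique(outer(pa, ma, "+"))
      if (!c_ac %in% possible) {
        viol[[length(viol) + 1L]] <- data.frame(
          key = rownames(geno$calls)[v], individual = id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(viol)) {
    return(data.frame(key = character(0), individual = character(0)))
  }
  do.call(rbind, viol)
}

#' Plant a causal variant and assign phenotypes
#'
#' Inserts one variant transmitted from a chosen founder by gene dropping
#' (dominant: the founder is heterozygous; recessive: every founder in
#' `parent_ids` is made heterozygous) and assigns affected status with
#' probability `penetrance` to carriers (dominant: any alt allele;
#' recessive: homozygotes) and `phenocopy` to the rest. The truth record is
#' returned alongside, never written into the genotypes.
#'
#' @param ped A [pedigree()].
#' @param founder_id Founder whose lineage transmits the variant (dominant
#'   model).
#' @param model `"dominant"` or `"recessive"`.
#' @param penetrance,phenocopy Probabilities in `[0,1]`.
#' @param parent_ids For the recessive model, the founders forced
#'   heterozygous.
#' @param seed Optional integer seed.
#' @param chrom Chromosome of the planted site.
#' @return List with `geno` (single-site [genotype_matrix()] over all
#'   individuals), `affected` (ids), and `truth` (list: model, founder,
#'   carriers, penetrance, phenocopy).
#' @export
plant_causal_variant <- function(ped, founder_id = NULL,
                                 model = c("dominant", "recessive"),
                                 penetrance = 1, phenocopy = 0,
                                 parent_ids = NULL, seed = NULL,
                                 chrom = "chr1") {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  ids <- ped$ind$id
  fa <- stats::setNames(ped$ind$father_id, ids)
  mo <- stats::setNames(ped$ind$mother_id, ids)
  a1 <- a2 <- stats::setNames(integer(length(ids)), ids)
  if (model == "dominant") {
    if (is.null(founder_id) || !founder_id %in% ids) {
      stop("founder_id must name a pedigree individual")
    }
    if (!is.na(fa[[founder_id]]) || !is.na(mo[[founder_id]])) {
      stop("founder_id must be a founder")
    }
    a1[founder_id] <- 1L
  } else {
    if (is.null(parent_ids) || !length(parent_ids)) {
      stop("recessive planting requires parent_ids")
    }
    a1[parent_ids] <- 1L
  }
  for (id in ped_topo_order(ped)) {
    if (is.na(fa[[id]]) && is.na(mo[[id]])) next
    pat <- if (is.na(fa[[id]])) 0L else {
      if (stats::runif(1) < 0.5) a1[[fa[[id]]]] else a2[[fa[[id]]]]
    }
    mat <- if (is.na(mo[[id]])) 0L else {
      if (stats::runif(1) < 0.5) a1[[mo[[id]]]] else a2[[mo[[id]]]]
    }
    a1[id] <- pat; a2[id] <- mat
  }
  calls <- matrix(a1 + a2, nrow = 1L, dimnames = list(NULL, ids))
  keys <- data.frame(chrom = chrom, pos = 500000L, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  geno <- genotype_matrix(keys, calls)
  carriers <- if (model == "dominant") ids[calls[1, ] >= 1L]
              else ids[calls[1, ] == 2L]
  aff_p <- ifelse(ids %in% carriers, penetrance, phenocopy)
  affected <- ids[stats::runif(length(ids)) < aff_p]
  list(geno = geno, affected = affected,
       truth = list(model = model, founder = founder_id,
                    carriers = carriers, penetrance = penetrance,
                    phenocopy = phenocopy))
}

#' Simulate a variant annotation table
#'
#' Draws per-source allele frequencies, raw consequence labels and CADD
#' scores from the configured distributions for the given variant keys.
#' The site frequency is drawn from the zero/log-uniform mixture; the first
#' source reports it exactly and the second reports 0.75x (so the MMAF
#' equals the drawn frequency and the mixture mass below any bound is
#' analytic, see [af_mass_below()]); never-observed sites get `NA` in both
#' sources. Deterministic under a fixed seed.
#'
#' @param keys Data.frame with columns `chrom`, `pos`, `ref`, `alt` (e.g.
#'   the `keys` of a [gene_drop()] result), or an integer count of sites to
#'   fabricate.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A `variant_annotation` data.frame (as from
#'   [read_annotation_table()]); write with [write_annotation_table()].
#' @export
simulate_annotations <- function(keys, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(keys) && length(keys) == 1L) {
    keys <- data.frame(chrom = "chr1", pos = seq_len(keys) * 1000L,
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  n <- nrow(keys)
  zero <- stats::runif(n) < config$af_zero_weight
  lo <- log(config$af_range[1]); hi <- log(config$af_range[2])
  af <- exp(stats::runif(n, lo, hi))
  af[zero] <- NA_real_
  cons <- sample(names(config$consequence_mix), n, replace = TRUE,
                 prob = config$consequence_mix)
  cadd <- stats::runif(n, config$cadd_range[1], config$cadd_range[2])
  ann <- data.frame(
    chrom = norm_chrom(keys$chrom), pos = as.integer(keys$pos),
    ref = keys$ref, alt = keys$alt,
    gene = paste0("GENE", seq_len(n)),
    consequence_raw = cons,
    cadd = round(cadd, 1), rsid = ".", clinvar = "absent", hgvs = ".",
    af_swegen = af, af_gnomad = signif(0.75 * af, 6),
    stringsAsFactors = FALSE)
  ann$mmaf <- ifelse(is.na(af), 0, af)
  ann$novel <- is.na(af)
  ann$consequence <- classify_consequence(cons)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  attr(ann, "af_cols") <- c("af_swegen", "af_gnomad")
  class(ann) <- c("variant_annotation", "data.frame")
  ann
}
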