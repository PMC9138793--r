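#' Filtering thresholds
#'
#' Defaults follow the hereditary-breast-cancer study design this package
#' models: variants with MMAF >= 0.1% are excluded (strict `<` keeps
#' 0.00083, drops 0.001 itself), CADD > 20 marks a candidate and CADD > 25
#' a high-risk variant (both strict `>`), MMAF < 0.0001 defines the
#' ultra-rare subset, and the gene-panel screen uses a wider MMAF < 0.2 cut.
#'
#' @param mmaf_max Population-filter MMAF upper bound (exclusive).
#' @param mmaf_ultrarare Ultra-rare reporting bound (exclusive).
#' @param cadd_min Minimum CADD for a candidate (exclusive).
#' @param cadd_highrisk Minimum CADD for the high-risk tier (exclusive).
#' @param panel_mmaf_max MMAF bound for the gene-panel screen (exclusive).
#' @return A list of class `thresholds`.
#' @export
thresholds <- function(mmaf_max = 0.001, mmaf_ultrarare = 1e-4,
                       cadd_min = 20, cadd_highrisk = 25,
                       panel_mmaf_max = 0.2) {
  th <- list(mmaf_max = mmaf_max, mmaf_ultrarare = mmaf_ultrarare,
             cadd_min = cadd_min, cadd_highrisk = cadd_highrisk,
             panel_mmaf_max = panel_mmaf_max)
  for (f in c("mmaf_max", "mmaf_ultrarare", "panel_mmaf_max")) {
    if (th[[f]] < 0 || th[[f]] > 1) stop(f, " must lie in [0,1]")
  }
  if (th$cadd_highrisk < th$cadd_min) stop("cadd_highrisk must be >= cadd_min")
  structure(th, class = "thresholds")
}

#' Maximum minor allele frequency over sources
#'
#' The rarity statistic: the maximum of a variant's alternate-allele
#' frequencies across the consulted population databases (e.g. SweGen and
#' gnomAD). An empty mapping (observed in no database) gives 0 and marks
#' the variant novel. In the rare-variant regime targeted here (< 0.1%)
#' alternate-allele and folded minor-allele frequencies coincide.
#'
#' @param af_by_source Named numeric vector (or list) of per-source
#'   frequencies in `[0,1]`; `NA` entries mean "not observed" and are
#'   ignored.
#' @return Single numeric, with attribute `novel` (TRUE iff no source
#'   reported the variant).
#' @export
compute_mmaf <- function(af_by_source) {
  x <- unlist(af_by_source, use.names = FALSE)
  x <- x[!is.na(x)]
  if (length(x) && (any(x < 0) || any(x > 1))) {
    stop("allele frequencies must lie in [0,1]")
  }
  if (!length(x)) return(structure(0, novel = TRUE))
  structure(max(x), novel = FALSE)
}

# annotation-tool vocabulary -> consequence categories; editable via
# options(pedfilter.consequence_map = ...)
default_consequence_map <- c(
  "missense"                   = "missense",
  "nonsynonymous snv"          = "missense",
  "nonsense"                   = "nonsense",
  "stopgain"                   = "nonsense",
  "splicing"                   = "splicing",
  "splice_acceptor"            = "splicing",
  "splice_donor"               = "splicing",
  "synonymous"                 = "synonymous",
  "synonymous snv"             = "synonymous",
  "frameshift"                 = "frameshift",
  "frameshift insertion"       = "frameshift",
  "frameshift deletion"        = "frameshift",
  "frameshift substitution"    = "frameshift",
  "inframe_indel"              = "inframe_indel",
  "nonframeshift insertion"    = "inframe_indel",
  "nonframeshift deletion"     = "inframe_indel",
  "nonframeshift substitution" = "inframe_indel",
  "non_exonic"                 = "non_exonic",
  "intronic"                   = "non_exonic",
  "intergenic"                 = "non_exonic",
  "utr3"                       = "non_exonic",
  "utr5"                       = "non_exonic",
  "ncrna_intronic"             = "non_exonic",
  "ncrna_exonic"               = "non_exonic",
  "upstream"                   = "non_exonic",
  "downstream"                 = "non_exonic"
)

#' Classify raw consequence labels
#'
#' Maps annotation-tool vocabulary (ANNOVAR-style labels such as
#' `"nonsynonymous SNV"`, `"stopgain"`, `"frameshift insertion"`) onto the
#' category set `missense`, `nonsense`, `splicing`, `synonymous`,
#' `frameshift`, `inframe_indel`, `non_exonic`, `other`, through an explicit
#' table that can be replaced via `options(pedfilter.consequence_map = ...)`.
#' Unknown labels map to `other` with a warning.
#'
#' @param raw_label Character vector of raw labels.
#' @return Character vector of categories, same length.
#' @export
classify_consequence <- function(raw_label) {
  map <- getOption("pedfilter.consequence_map", default_consequence_map)
  out <- unname(map[tolower(trimws(raw_label))])
  unk <- is.na(out)
  if (any(unk)) {
    warning("unknown consequence label(s) mapped to 'other': ",
            paste(unique(raw_label[unk]), collapse = ", "))
    out[unk] <- "other"
  }
  out
}

#' Population-frequency filter
#'
#' Retains exactly the variants with `mmaf < mmaf_max` (strict: a variant at
#' exactly the bound is excluded, matching "MMAF >= 0.1% were excluded").
#'
#' @param ann A `variant_annotation` data.frame carrying `mmaf`.
#' @param th A [thresholds()] object.
#' @return The retained subset of `ann`.
#' @export
population_filter <- function(ann, th = thresholds()) {
  ann[ann$mmaf < th$mmaf_max, , drop = FALSE]
}

consequences_exonic <- c("missense", "nonsense", "splicing", "frameshift",
                         "inframe_indel")

#' Exonic-consequence filter
#'
#' Retains protein-affecting and splice consequences (`missense`,
#' `nonsense`, `splicing`, `frameshift`, `inframe_indel`); drops
#' `synonymous`, `non_exonic` and `other`.
#'
#' @inheritParams population_filter
#' @return The retained subset of `ann`.
#' @export
exonic_filter <- function(ann) {
  ann[ann$consequence %in% consequences_exonic, , drop = FALSE]
}

#' CADD deleteriousness tiers
#'
#' `fail` if CADD <= `cadd_min`, `candidate` if `cadd_min` < CADD <=
#' `cadd_highrisk`, `high_risk` above that (strict inequalities: CADD
#' exactly 20 fails; 20.2 is a candidate; 25.2 is high risk).
#'
#' @param cadd Numeric vector of phred-scaled CADD scores.
#' @param th A [thresholds()] object.
#' @return Character vector of tiers.
#' @export
cadd_tiers <- function(cadd, th = thresholds()) {
  ifelse(cadd > th$cadd_highrisk, "high_risk",
         ifelse(cadd > th$cadd_min, "candidate", "fail"))
}

#' The built-in 64-gene hereditary breast cancer panel
#'
#' The gene symbols of the diagnostic panel used to pre-screen the families
#' (BRCA1/2, the Fanconi anemia genes, DNA-repair genes, etc.), one symbol
#' per line in `extdata/panel_genes_64.txt`.
#'
#' @return Character vector of 64 gene symbols.
#' @export
panel_genes <- function() {
  readLines(system.file("extdata", "panel_genes_64.txt",
                        package = "pedfilter"))
}

#' Screen variants against a hereditary-cancer gene panel
#'
#' Reports every variant whose gene is on the panel and whose MMAF is below
#' `panel_mmaf_max`, with its ClinVar assertion. This is a side channel:
#' reported variants are never removed from the main filtering cascade, and
#' benign/likely-benign assertions are reported, not used to exclude.
#'
#' @param ann A `variant_annotation` data.frame.
#' @param panel Character vector of panel gene symbols (default: the
#'   built-in 64-gene panel). Must be non-empty.
#' @param th A [thresholds()] object.
#' @return Data.frame with one row per reported variant: `gene`, `key`,
#'   `rsid`, `consequence`, `mmaf`, `cadd`, `clinvar`.
#' @export
panel_screen <- function(ann, panel = panel_genes(), th = thresholds()) {
  if (!length(panel)) stop("panel gene list is empty")
  hit <- ann$gene %in% panel & ann$mmaf < th$panel_mmaf_max
  out <- ann[hit, c("gene", "key", "rsid", "consequence", "mmaf", "cadd",
                    "clinvar"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen genotypes for known risk SNPs
#'
#' For each requested rsID, reports whether it was observed in the data and,
#' if so, which individuals carry it and whether they are affected (carry
#' any of `disease_labels`; all labels by default).
#'
#' @param ann A `variant_annotation` data.frame (supplies the rsID ->
#'   variant mapping).
#' @param geno A [genotype_matrix()].
#' @param ped A [pedigree()].
#' @param rsids Character vector of rsIDs to screen (may be empty).
#' @param disease_labels Phenotype labels defining "affected"; default: any
#'   label in the pedigree.
#' @return Data.frame with columns `rsid`, `status`, `carrier`, `affected`;
#'   one row per carrier for observed SNPs, a single `not_observed` row
#'   otherwise; zero rows for an empty `rsids`.
#' @export
known_snp_screen <- function(ann, geno, ped, rsids,
                             disease_labels = NULL) {
  if (is.null(disease_labels)) disease_labels <- phenotype_labels(ped)
  affected <- if (length(disease_labels)) {
    select_individuals(ped, disease_labels, mode = "any_of")
  } else character(0)
  rows <- list()
  for (rs in rsids) {
    idx <- which(ann$rsid == rs)
    if (!length(idx)) {
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = rs, status = "not_observed", carrier = NA_character_,
        affected = NA, stringsAsFactors = FALSE)
      next
    }
    for (i in idx) {
      key <- ann$key[i]
      if (!key %in% rownames(geno$calls)) next
      ac <- geno$calls[key, ]
      carriers <- colnames(geno$calls)[!is.na(ac) & ac >= 1L]
      if (!length(carriers)) {
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = rs, status = "observed_no_carriers",
          carrier = NA_character_, affected = NA, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = rs, status = "observed", carrier = carriers,
          affected = carriers %in% affected, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(rsid = character(0), status = character(0),
                      carrier = character(0), affected = logical(0)))
  }
  do.call(rbind, rows)
}
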