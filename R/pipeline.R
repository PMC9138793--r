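validation_error <- function(...) {
  stop(structure(class = c("pedfilter_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    validation_error("missing ", what, " file: ",
                     if (is.null(path)) "(not given)" else path)
  }
  path
}

#' Run the filtering pipeline end to end on files
#'
#' Reads the multi-sample VCF, pedigree (PED + phenotype sidecar),
#' annotation table and family config, validates them, runs
#' [run_family_cascade()], and writes into `out_dir`: `candidates.tsv`
#' (per-stratum candidate table), `funnel.tsv` and `funnel.json`,
#' `panel_screen.tsv`, `snp_screen.tsv` (when a SNP list is given) and
#' `manifest.json` (input digests, config snapshot, package version, seed,
#' stage counts, timestamp). Re-running on identical inputs reproduces
#' identical outputs except the manifest timestamp. Validation problems
#' raise a condition of class `pedfilter_validation_error` (the command
#' line wrapper maps it to exit status 2).
#'
#' @param vcf,ped,annotations,config Input file paths.
#' @param out_dir Output directory (created if needed).
#' @param phenotypes Optional phenotype sidecar path for the PED.
#' @param snp_list Optional path to a file of rsIDs (one per line) for the
#'   risk-SNP screen.
#' @param panel Optional path to a panel gene list (one symbol per line);
#'   default: the built-in 64-gene panel.
#' @param seed Optional integer recorded in the manifest (the cascade
#'   itself is deterministic).
#' @return The `family_cascade` object, invisibly.
#' @export
run_pipeline <- function(vcf, ped, annotations, config, out_dir,
                         phenotypes = NULL, snp_list = NULL, panel = NULL,
                         seed = NULL) {
  require_file(vcf, "VCF")
  require_file(ped, "PED")
  require_file(annotations, "annotation")
  require_file(config, "config")
  if (!is.null(phenotypes)) require_file(phenotypes, "phenotype sidecar")
  if (!is.null(snp_list)) require_file(snp_list, "SNP list")
  if (!is.null(panel)) require_file(panel, "panel gene list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pedigree <- read_ped(ped, phenotypes)
  ped_diag <- validate_pedigree(pedigree)
  if (length(ped_diag)) {
    validation_error("pedigree invalid: ", paste(ped_diag, collapse = "; "))
  }
  cfg <- tryCatch(read_family_config(config, pedigree),
                  error = function(e) validation_error(conditionMessage(e)))
  sex_of <- stats::setNames(pedigree$ind$sex, pedigree$ind$id)
  geno <- read_vcf(vcf, sample_subset = NULL, sex_of = sex_of)
  extra <- setdiff(colnames(geno$calls), pedigree$ind$id)
  if (length(extra)) {
    validation_error("VCF sample(s) not in pedigree: ",
                     paste(extra, collapse = ", "))
  }
  ann <- read_annotation_table(annotations)
  cascade <- run_family_cascade(ann, geno, cfg)

  write_candidate_table(cascade, file.path(out_dir, "candidates.tsv"))
  utils::write.table(cascade$funnel, file.path(out_dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(cascade$funnel$count), cascade$funnel$stage),
    file.path(out_dir, "funnel.json"), auto_unbox = TRUE, digits = NA)
  panel_symbols <- if (is.null(panel)) panel_genes() else readLines(panel)
  utils::write.table(panel_screen(ann, panel_symbols, cascade$thresholds),
                     file.path(out_dir, "panel_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(snp_list)) {
    rsids <- readLines(snp_list)
    rsids <- rsids[nzchar(trimws(rsids))]
    utils::write.table(known_snp_screen(ann, geno, pedigree, rsids),
                       file.path(out_dir, "snp_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  inputs <- c(vcf = vcf, ped = ped, annotations = annotations,
              config = config)
  if (!is.null(phenotypes)) inputs["phenotypes"] <- phenotypes
  manifest <- list(
    tool = "pedfilter",
    version = as.character(utils::packageVersion("pedfilter")),
    inputs = as.list(tools::md5sum(inputs)),
    config = cfg[c("family_id", "model", "obligate_carriers",
                   "hard_excluders", "slack_pool", "slack_k")],
    thresholds = unclass(cascade$thresholds),
    seed = seed,
    funnel = stats::setNames(as.list(cascade$funnel$count),
                             cascade$funnel$stage),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(cascade)
}
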