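#' Run the full per-family filtering cascade
#'
#' Applies, in the study's order: the population-frequency filter
#' (MMAF < `mmaf_max`), the exonic-consequence filter, segregation over the
#' configured strata (strict first, then the incomplete-penetrance
#' stratum), and the CADD tiering, keeping `candidate` and `high_risk`
#' variants. The three annotation filters are per-variant predicates and
#' therefore commute; the funnel reports them in the order above. The
#' result is deterministic for fixed inputs.
#'
#' @param ann A `variant_annotation` data.frame
#'   ([read_annotation_table()]).
#' @param geno A [genotype_matrix()] covering at least the configured
#'   individuals; only variants present in both `ann` and `geno` enter the
#'   cascade.
#' @param config A `family_config` ([read_family_config()]) or a list of
#'   [seg_stratum()] objects for a dominant analysis.
#' @param th A [thresholds()] object; defaults to the config's thresholds
#'   when available.
#' @return An object of class `family_cascade`: list with `candidates`
#'   (data.frame: `key`, `filter`, `stratum`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `rsid`, `consequence`, `hgvs`, `mmaf`, `cadd`, `tier`,
#'   `clinvar`, `carriers`, `slack_carriers_used`), `funnel` (stage/count
#'   data.frame), `segregation` (full per-variant outcomes), `family_id`
#'   and `thresholds`.
#' @export
run_family_cascade <- function(ann, geno, config, th = NULL) {
  if (inherits(config, "family_config")) {
    if (is.null(th)) th <- config$thresholds
    if (config$model == "recessive") {
      stop("run_family_cascade implements the dominant cascade; ",
           "use segregate_recessive for the recessive search")
    }
    strata <- config$strata
    family_id <- config$family_id
  } else {
    strata <- config
    family_id <- "family"
  }
  if (is.null(th)) th <- thresholds()
  common <- intersect(ann$key, rownames(geno$calls))
  if (length(common) < nrow(ann)) {
    warning(nrow(ann) - length(common),
            " annotated variant(s) lack genotypes and are dropped")
  }
  ann <- ann[match(common, ann$key), , drop = FALSE]
  funnel <- data.frame(stage = "total", count = nrow(ann),
                       stringsAsFactors = FALSE)
  a1 <- population_filter(ann, th)
  funnel <- rbind(funnel, data.frame(stage = "post_population", count = nrow(a1)))
  a2 <- exonic_filter(a1)
  funnel <- rbind(funnel, data.frame(stage = "post_exonic", count = nrow(a2)))
  seg <- if (nrow(a2)) {
    segregate(geno[a2$key, , drop = FALSE], strata)
  } else {
    segregate(geno, strata)[0, , drop = FALSE]
  }
  strat_names <- vapply(strata, `[[`, character(1), "name")
  n_strict <- sum(seg$filter %in% 1L)
  n_slack <- sum(seg$filter %in% 2L)
  funnel <- rbind(funnel,
                  data.frame(stage = "post_segregation_strict", count = n_strict),
                  data.frame(stage = "post_segregation_slack", count = n_slack))
  keep <- seg[!is.na(seg$filter), , drop = FALSE]
  a3 <- a2[match(keep$key, a2$key), , drop = FALSE]
  tier <- cadd_tiers(a3$cadd, th)
  pass <- tier != "fail"
  cand <- data.frame(
    key = a3$key, filter = keep$filter,
    stratum = strat_names[keep$filter],
    gene = a3$gene, chrom = a3$chrom, pos = a3$pos, ref = a3$ref,
    alt = a3$alt, rsid = a3$rsid, consequence = a3$consequence,
    hgvs = a3$hgvs, mmaf = a3$mmaf, cadd = a3$cadd, tier = tier,
    clinvar = a3$clinvar, carriers = keep$carriers,
    slack_carriers_used = keep$slack_carriers_used,
    stringsAsFactors = FALSE)[pass, , drop = FALSE]
  cand <- cand[order(cand$filter, -cand$cadd, cand$chrom, cand$pos), ,
               drop = FALSE]
  rownames(cand) <- NULL
  funnel <- rbind(funnel,
                  data.frame(stage = "post_cadd_strict",
                             count = sum(cand$filter == 1L)),
                  data.frame(stage = "post_cadd_slack",
                             count = sum(cand$filter == 2L)),
                  data.frame(stage = "candidates_total", count = nrow(cand)))
  structure(list(candidates = cand, funnel = funnel, segregation = seg,
                 family_id = family_id, thresholds = th),
            class = "family_cascade")
}

#' @export
print.family_cascade <- function(x, ...) {
  cat("Family cascade for '", x$family_id, "'\n", sep = "")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-26s %d\n", x$funnel$stage[i], x$funnel$count[i]))
  }
  invisible(x)
}

#' @export
summary.family_cascade <- function(object, ...) {
  cd <- object$candidates
  th <- object$thresholds
  out <- data.frame(
    family = object$family_id,
    total = nrow(cd),
    strict = sum(cd$filter == 1L),
    slack_only = sum(cd$filter == 2L),
    high_risk = sum(cd$tier == "high_risk"),
    ultrarare = sum(cd$mmaf < th$mmaf_ultrarare),
    max_cadd = if (nrow(cd)) max(cd$cadd) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("cascade_summary", "data.frame")
  out
}

#' Summarize one or more cascade results
#'
#' Per-family totals, per-stratum totals, the high-risk (CADD above the
#' high-risk bound) subset and the ultra-rare (MMAF below the ultra-rare
#' bound) subset. Totals always satisfy strict + slack_only = total.
#'
#' @param cascades A `family_cascade` or list of them.
#' @return A `cascade_summary` data.frame, one row per family.
#' @export
summarize_candidates <- function(cascades) {
  if (inherits(cascades, "family_cascade")) cascades <- list(cascades)
  out <- do.call(rbind, lapply(cascades, summary))
  rownames(out) <- NULL
  out
}
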