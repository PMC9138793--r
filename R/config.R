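parse_ini <- function(path) {
  lines <- readLines(path)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- NA_character_
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section)) stop("config key outside any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[tolower(trimws(kv[1]))]] <-
        trimws(paste(kv[-1], collapse = "="))
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  out
}

split_ids <- function(x) {
  if (is.null(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Read a per-family segregation configuration
#'
#' Plain-text INI-style file with sections `[family]` (key `id`), `[model]`
#' (`type = dominant|recessive`), `[affected]`, `[obligate_carriers]`,
#' `[excluders]`, `[slack_pool]` (each with `ids = a,b,c`), `[thresholds]`
#' (`mmaf_max`, `cadd_min`, `cadd_highrisk`, `slack`, optionally
#' `mmaf_ultrarare`, `panel_mmaf_max`), an optional `[stratum2]` section
#' overriding the second stratum's sets (`obligate_carriers`, `excluders`,
#' `slack_pool`, `slack`), and for the recessive model a `[parent_set]`
#' section. Omitted thresholds fall back to the defaults of
#' [thresholds()] with `slack = 1`.
#'
#' Without a `[stratum2]` override the strata are [dominant_strata()]:
#' strict first, then up-to-`slack` non-penetrant pool carriers. With the
#' override (used when the two filters differ by obligate set, as in a
#' family whose second filter obligates an additional affected member),
#' stratum 2 is built from the override's own sets.
#'
#' @param path Config file path.
#' @param ped Optional [pedigree()]; when given, all configured ids must
#'   exist in it (error otherwise).
#' @return A list of class `family_config` with elements `family_id`,
#'   `model`, `affected`, `strata` (list of [seg_stratum()]), `slack_k`,
#'   `parent_set` and `thresholds`.
#' @export
read_family_config <- function(path, ped = NULL) {
  ini <- parse_ini(path)
  fam <- if (!is.null(ini$family$id)) ini$family$id else "family"
  model <- tolower(if (!is.null(ini$model$type)) ini$model$type else "dominant")
  if (!model %in% c("dominant", "recessive")) {
    stop("unknown inheritance model: ", model)
  }
  thr <- ini$thresholds
  num <- function(key, default) {
    if (is.null(thr[[key]])) default else as.numeric(thr[[key]])
  }
  slack_k <- as.integer(num("slack", 1))
  if (is.na(slack_k) || slack_k < 0L) stop("slack must be a nonnegative integer")
  th <- thresholds(
    mmaf_max = num("mmaf_max", 0.001),
    mmaf_ultrarare = num("mmaf_ultrarare", 1e-4),
    cadd_min = num("cadd_min", 20),
    cadd_highrisk = num("cadd_highrisk", 25),
    panel_mmaf_max = num("panel_mmaf_max", 0.2))
  obl <- split_ids(ini$obligate_carriers$ids)
  excl <- split_ids(ini$excluders$ids)
  pool <- split_ids(ini$slack_pool$ids)
  affected <- split_ids(ini$affected$ids)
  parent_set <- split_ids(ini$parent_set$ids)
  if (!is.null(ped)) {
    s2_ids <- unlist(lapply(
      ini$stratum2[c("obligate_carriers", "excluders", "slack_pool")],
      split_ids))
    ids <- unique(c(obl, excl, pool, affected, parent_set, s2_ids))
    absent <- setdiff(ids, ped$ind$id)
    if (length(absent)) {
      stop("config references id(s) not in pedigree: ",
           paste(absent, collapse = ", "))
    }
  }
  strata <- NULL
  if (model == "dominant") {
    if (!length(obl)) stop("dominant model requires obligate_carriers")
    if (!is.null(ini$stratum2)) {
      s2 <- ini$stratum2
      s2_pool <- split_ids(s2$slack_pool)
      s2_slack <- if (is.null(s2$slack)) 0L else as.integer(s2$slack)
      strata <- list(
        seg_stratum("strict", obl, excl, pool, 0L, 0L),
        seg_stratum("slack_only",
                    split_ids(s2$obligate_carriers),
                    split_ids(s2$excluders),
                    s2_pool,
                    if (s2_slack > 0L) 1L else 0L,
                    s2_slack))
    } else {
      strata <- dominant_strata(obl, excl, pool, slack_k)
      if (length(strata) == 2L) strata[[2]]$name <- "slack_only"
    }
  } else {
    if (!length(parent_set)) stop("recessive model requires a [parent_set]")
  }
  structure(list(family_id = fam, model = model, affected = affected,
                 obligate_carriers = obl, hard_excluders = excl,
                 slack_pool = pool, slack_k = slack_k,
                 parent_set = parent_set, strata = strata, thresholds = th),
            class = "family_config")
}

#' Write a family configuration file
#'
#' Inverse of [read_family_config()] for configurations expressible in the
#' standard sections (including a `[stratum2]` override given as a
#' [seg_stratum()]).
#'
#' @param config A `family_config`-like list (see [read_family_config()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_family_config <- function(config, path) {
  th <- config$thresholds
  lines <- c(
    "[family]", paste("id =", config$family_id),
    "[model]", paste("type =", config$model),
    "[affected]", paste("ids =", paste(config$affected, collapse = ",")),
    "[obligate_carriers]",
    paste("ids =", paste(config$obligate_carriers, collapse = ",")),
    "[excluders]", paste("ids =", paste(config$hard_excluders, collapse = ",")),
    "[slack_pool]", paste("ids =", paste(config$slack_pool, collapse = ",")),
    "[thresholds]",
    paste("mmaf_max =", th$mmaf_max),
    paste("mmaf_ultrarare =", th$mmaf_ultrarare),
    paste("cadd_min =", th$cadd_min),
    paste("cadd_highrisk =", th$cadd_highrisk),
    paste("panel_mmaf_max =", th$panel_mmaf_max),
    paste("slack =", config$slack_k))
  if (!is.null(config$stratum2_override)) {
    s2 <- config$stratum2_override
    lines <- c(lines, "[stratum2]",
               paste("obligate_carriers =",
                     paste(s2$obligate_carriers, collapse = ",")),
               paste("excluders =", paste(s2$hard_excluders, collapse = ",")),
               paste("slack_pool =", paste(s2$slack_pool, collapse = ",")),
               paste("slack =", s2$slack_max))
  }
  if (length(config$parent_set)) {
    lines <- c(lines, "[parent_set]",
               paste("ids =", paste(config$parent_set, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
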