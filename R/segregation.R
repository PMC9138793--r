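#' Define a segregation stratum
#'
#' A stratum is one configuration of the dominant co-segregation test:
#' every obligate carrier must carry the variant, no hard excluder may
#' carry it, and the number of carriers inside the slack pool must fall in
#' `[slack_min, slack_max]`. The strict filter is the stratum with slack
#' range 0..0; an incomplete-penetrance ("slack") filter allows 1..k
#' unaffected pool members to carry.
#'
#' @param name Stratum label (e.g. `"strict"`, `"slack"`).
#' @param obligate_carriers Ids that must carry (typically the affected,
#'   sequenced individuals under the stratum's phenotype definition).
#' @param hard_excluders Ids that must not carry, regardless of slack.
#' @param slack_pool Ids of whom a bounded number may carry.
#' @param slack_min,slack_max Allowed range of slack-pool carriers.
#' @return A list of class `seg_stratum`.
#' @export
seg_stratum <- function(name, obligate_carriers, hard_excluders = character(0),
                        slack_pool = character(0), slack_min = 0L,
                        slack_max = 0L) {
  sets <- list(obligate_carriers, hard_excluders, slack_pool)
  if (anyDuplicated(unlist(sets))) {
    stop("obligate_carriers, hard_excluders and slack_pool must be pairwise disjoint")
  }
  if (slack_min < 0L || slack_max < slack_min) stop("invalid slack range")
  if (slack_max > length(slack_pool)) {
    stop("slack_max exceeds the slack pool size")
  }
  structure(list(name = name,
                 obligate_carriers = as.character(obligate_carriers),
                 hard_excluders = as.character(hard_excluders),
                 slack_pool = as.character(slack_pool),
                 slack_min = as.integer(slack_min),
                 slack_max = as.integer(slack_max)),
            class = "seg_stratum")
}

#' Standard strict + slack stratum pair for a dominant model
#'
#' Builds the two-stratum cascade used by default: a strict stratum
#' (nobody outside the obligates carries) followed by a slack stratum in
#' which between 1 and `slack_k` slack-pool members may carry
#' (incomplete penetrance). With `slack_k = 0` only the strict stratum is
#' returned.
#'
#' @inheritParams seg_stratum
#' @param slack_k Maximum number of non-penetrant carriers tolerated.
#' @return List of `seg_stratum` objects, most stringent first.
#' @export
dominant_strata <- function(obligate_carriers, hard_excluders = character(0),
                            slack_pool = character(0), slack_k = 1L) {
  if (slack_k < 0L) stop("slack_k must be nonnegative")
  strata <- list(seg_stratum("strict", obligate_carriers, hard_excluders,
                             slack_pool, 0L, 0L))
  if (slack_k > 0L && length(slack_pool)) {
    strata[[2]] <- seg_stratum("slack", obligate_carriers, hard_excluders,
                               slack_pool, 1L, as.integer(slack_k))
  }
  strata
}

#' Carrier status of a genotype call
#'
#' Dominant model: carrier iff the alternate-allele count is 1 or 2
#' (hemizygous male X calls are stored as 2, hence carriers). Recessive
#' model: `"hom"` (affected-carrier) iff count 2, `"het"` iff 1. Missing
#' calls are never carriers; how a missing call is treated (fail vs warn)
#' is decided by the segregation functions based on the individual's role.
#'
#' @param allele_count Integer vector of alt-allele counts (0/1/2/NA).
#' @param model `"dominant"` or `"recessive"`.
#' @return For `"dominant"`, logical vector; for `"recessive"`, character
#'   vector in `{"non", "het", "hom"}` (`NA` counts are `"non"`).
#' @export
is_carrier <- function(allele_count, model = c("dominant", "recessive")) {
  model <- match.arg(model)
  ac <- as.integer(allele_count)
  if (model == "dominant") {
    !is.na(ac) & ac >= 1L
  } else {
    ifelse(is.na(ac) | ac == 0L, "non", ifelse(ac == 2L, "hom", "het"))
  }
}

check_ids_present <- function(geno, ids) {
  absent <- setdiff(ids, colnames(geno$calls))
  if (length(absent)) {
    stop("individual(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  }
}

eval_stratum <- function(carr, miss, stratum) {
  # carr, miss: named logical vectors for one variant
  obl <- stratum$obligate_carriers
  if (any(miss[obl])) {
    return(list(pass = FALSE, reason = "genotype_incomplete", slack_used = NA_integer_))
  }
  if (!all(carr[obl])) {
    return(list(pass = FALSE, reason = "obligate_noncarrier", slack_used = NA_integer_))
  }
  if (length(stratum$hard_excluders) && any(carr[stratum$hard_excluders])) {
    return(list(pass = FALSE, reason = "excluder_carrier", slack_used = NA_integer_))
  }
  n_slack <- if (length(stratum$slack_pool)) sum(carr[stratum$slack_pool]) else 0L
  if (n_slack < stratum$slack_min || n_slack > stratum$slack_max) {
    return(list(pass = FALSE, reason = "slack_out_of_range", slack_used = n_slack))
  }
  list(pass = TRUE, reason = "", slack_used = n_slack)
}

#' Segregation filtering over ordered strata
#'
#' The core co-segregation decision. For each variant, strata are evaluated
#' most-stringent-first and the variant is assigned to the first stratum
#' whose predicate holds (obligates all carry, no hard excluder carries,
#' slack-pool carriers within the allowed range); otherwise it fails. A
#' missing genotype in an obligate carrier fails the variant
#' (`genotype_incomplete`); missing in a slack-pool or excluder individual
#' counts as non-carrier, with a per-variant warning flag.
#'
#' @param geno A [genotype_matrix()].
#' @param strata List of [seg_stratum()] objects, ordered most stringent
#'   first (see [dominant_strata()]).
#' @return Data.frame with one row per variant: `key`, `stratum` (a stratum
#'   name or `"fail"`), `filter` (1-based stratum index, `NA` on fail),
#'   `slack_carriers_used`, `carriers` (comma-separated ids), `reason` (why
#'   the variant failed the least stringent stratum; empty on pass) and
#'   `missing_nonobligate` (TRUE when a non-obligate call was missing).
#' @export
segregate <- function(geno, strata) {
  stopifnot(inherits(geno, "genotype_matrix"), length(strata) >= 1L)
  all_ids <- unique(unlist(lapply(strata, function(s) {
    c(s$obligate_carriers, s$hard_excluders, s$slack_pool)
  })))
  check_ids_present(geno, all_ids)
  keys <- rownames(geno$calls)
  n <- length(keys)
  res <- data.frame(
    key = keys, stratum = rep_len("fail", n),
    filter = rep_len(NA_integer_, n),
    slack_carriers_used = rep_len(NA_integer_, n),
    carriers = rep_len("", n), reason = rep_len("", n),
    missing_nonobligate = rep_len(FALSE, n), stringsAsFactors = FALSE)
  for (v in seq_len(n)) {
    ac <- geno$calls[v, ]
    carr <- stats::setNames(is_carrier(ac), colnames(geno$calls))
    miss <- stats::setNames(is.na(ac), colnames(geno$calls))
    res$carriers[v] <- paste(colnames(geno$calls)[carr], collapse = ",")
    last_reason <- ""
    for (si in seq_along(strata)) {
      s <- strata[[si]]
      ev <- eval_stratum(carr, miss, s)
      non_obl <- setdiff(c(s$hard_excluders, s$slack_pool), character(0))
      if (any(miss[non_obl])) res$missing_nonobligate[v] <- TRUE
      if (ev$pass) {
        res$stratum[v] <- s$name
        res$filter[v] <- si
        res$slack_carriers_used[v] <- ev$slack_used
        last_reason <- ""
        break
      }
      last_reason <- ev$reason
    }
    res$reason[v] <- last_reason
  }
  res
}

#' Strict dominant segregation
#'
#' A variant passes iff every obligate carrier carries it and nobody in the
#' hard-excluder or slack pools does (full penetrance assumed).
#'
#' @inheritParams segregate
#' @inheritParams seg_stratum
#' @return As [segregate()], with stratum `"strict"` or `"fail"`.
#' @export
segregate_strict <- function(geno, obligate_carriers,
                             hard_excluders = character(0),
                             slack_pool = character(0)) {
  segregate(geno, list(seg_stratum("strict", obligate_carriers,
                                   hard_excluders, slack_pool, 0L, 0L)))
}

#' Incomplete-penetrance ("slack") dominant segregation
#'
#' A variant is `slack_only` iff every obligate carrier carries it, no hard
#' excluder carries it, and between 1 and `slack_k` slack-pool members
#' carry it — i.e. it would survive for at least one choice of `slack_k`
#' pool members designated permissible (non-penetrant) carriers, but does
#' not survive the strict filter. Variants passing strict are not
#' re-reported (the reported strata are disjoint, matching the "additional
#' variants" framing).
#'
#' Two equivalent formulations are implemented: `"count"` applies the
#' carrier-count bound directly; `"enumerate"` enumerates every
#' `slack_k`-subset of the pool, treats its complement as excluders, and
#' accepts the variant if any designation succeeds. Their equivalence is
#' exercised in the test suite on exhaustive small instances.
#'
#' @inheritParams segregate_strict
#' @param slack_k Maximum number of pool carriers tolerated (>= 1).
#' @param method `"count"` or `"enumerate"`.
#' @return As [segregate()], with stratum `"slack_only"`, `"strict"`
#'   (flagged so callers can drop it) or `"fail"`.
#' @export
segregate_slack <- function(geno, obligate_carriers,
                            hard_excluders = character(0),
                            slack_pool = character(0), slack_k = 1L,
                            method = c("count", "enumerate")) {
  method <- match.arg(method)
  if (slack_k < 1L) stop("slack_k must be >= 1 for the slack filter")
  if (method == "count") {
    res <- segregate(geno, dominant_strata(obligate_carriers, hard_excluders,
                                           slack_pool, slack_k))
    res$stratum[res$stratum == "slack"] <- "slack_only"
    return(res)
  }
  # enumeration semantics: designate each k-subset of the pool permissible
  strict <- segregate_strict(geno, obligate_carriers, hard_excluders,
                             slack_pool)
  res <- strict
  res$stratum[res$stratum != "fail"] <- "strict"
  combos <- utils::combn(length(slack_pool), min(slack_k, length(slack_pool)),
                         simplify = FALSE)
  pass_any <- rep(FALSE, nrow(res))
  slack_used <- rep(NA_integer_, nrow(res))
  for (cmb in combos) {
    allowed <- slack_pool[cmb]
    rest <- setdiff(slack_pool, allowed)
    r <- segregate(geno, list(seg_stratum(
      "s", obligate_carriers, c(hard_excluders, rest), allowed,
      0L, length(allowed))))
    ok <- r$stratum != "fail"
    newly <- ok & !pass_any
    slack_used[newly] <- r$slack_carriers_used[newly]
    pass_any <- pass_any | ok
  }
  slackers <- pass_any & strict$stratum == "fail" &
    strict$reason != "genotype_incomplete"
  res$stratum[slackers] <- "slack_only"
  res$filter[slackers] <- 2L
  res$slack_carriers_used[slackers] <- slack_used[slackers]
  res$reason[slackers] <- ""
  res
}

#' Recessive segregation
#'
#' Single-variant homozygous-recessive search: a variant passes iff every
#' obligate carrier (the affected individuals) is homozygous for the
#' alternate allele and every member of `parent_set` is heterozygous.
#' Compound heterozygotes are not searched.
#'
#' @inheritParams segregate_strict
#' @param parent_set Ids required to be heterozygous (the unaffected
#'   parents). Must be non-empty.
#' @return Data.frame with one row per variant: `key`, `pass`, `reason`.
#' @export
segregate_recessive <- function(geno, obligate_carriers, parent_set) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!length(parent_set)) stop("parent_set must be non-empty")
  check_ids_present(geno, c(obligate_carriers, parent_set))
  keys <- rownames(geno$calls)
  res <- data.frame(key = keys, pass = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (v in seq_along(keys)) {
    ac <- geno$calls[v, ]
    if (any(is.na(ac[obligate_carriers]))) {
      res$reason[v] <- "genotype_incomplete"
    } else if (!all(ac[obligate_carriers] == 2L)) {
      res$reason[v] <- "obligate_not_homozygous"
    } else if (any(is.na(ac[parent_set])) || !all(ac[parent_set] == 1L)) {
      res$reason[v] <- "parent_not_heterozygous"
    } else {
      res$pass[v] <- TRUE
    }
  }
  res
}
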