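#' Construct a pedigree
#'
#' A pedigree holds the family structure (parent links, sex), a sequenced
#' flag per individual, and free-form phenotype labels with optional onset
#' ages (e.g. `breast_cancer@40`). Phenotypes are deliberately plain labels,
#' not ontology codes: segregation filtering only needs to know which
#' diagnoses define "affected" for the disease under study.
#'
#' @param family_id Single character family identifier.
#' @param individuals A data.frame with columns `id`, `father_id`,
#'   `mother_id`, `sex` (`"male"`, `"female"` or `"unknown"`) and `sequenced`
#'   (logical). Absent parents are `NA` (founders have both parents `NA`).
#' @param phenotypes Named list, one entry per individual id, each a
#'   data.frame with columns `label` (character) and `onset` (numeric years,
#'   `NA` when unknown). Individuals without an entry carry no diagnosis.
#'
#' @return An object of class `pedigree`.
#' @examples
#' trio <- pedigree("trio", data.frame(
#'   id = c("fa", "mo", "ch"),
#'   father_id = c(NA, NA, "fa"), mother_id = c(NA, NA, "mo"),
#'   sex = c("male", "female", "female"), sequenced = TRUE),
#'   phenotypes = list(ch = data.frame(label = "breast_cancer", onset = 40)))
#' validate_pedigree(trio)
#' @export
pedigree <- function(family_id, individuals, phenotypes = list()) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  req <- c("id", "father_id", "mother_id", "sex", "sequenced")
  miss <- setdiff(req, names(individuals))
  if (length(miss)) {
    stop("individuals table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ind <- individuals[, req]
  for (col in c("id", "father_id", "mother_id", "sex")) {
    ind[[col]] <- as.character(ind[[col]])
  }
  ind$sequenced <- as.logical(ind$sequenced)
  ind$sex[is.na(ind$sex)] <- "unknown"
  bad_sex <- setdiff(unique(ind$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "))
  if (any(ind$sex == "unknown")) {
    warning("pedigree '", family_id, "' has individual(s) of unknown sex: ",
            paste(ind$id[ind$sex == "unknown"], collapse = ", "))
  }
  extra <- setdiff(names(phenotypes), ind$id)
  if (length(extra)) {
    stop("phenotypes given for unknown individual(s): ",
         paste(extra, collapse = ", "))
  }
  phenotypes <- lapply(phenotypes, function(p) {
    data.frame(label = as.character(p$label),
               onset = if ("onset" %in% names(p)) as.numeric(p$onset) else NA_real_)
  })
  structure(list(family_id = family_id, ind = ind, phen = phenotypes),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  n_seq <- sum(x$ind$sequenced)
  cat("Pedigree '", x$family_id, "': ", nrow(x$ind), " individuals (",
      n_seq, " sequenced)\n", sep = "")
  lab <- vapply(x$ind$id, function(id) {
    p <- x$phen[[id]]
    if (is.null(p) || nrow(p) == 0L) return("")
    paste(ifelse(is.na(p$onset), p$label, paste0(p$label, "@", p$onset)),
          collapse = ",")
  }, character(1))
  df <- cbind(x$ind, phenotypes = lab)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Validate a pedigree
#'
#' Checks the structural invariants: unique ids, parent references that
#' resolve to individuals of compatible sex (fathers male, mothers female),
#' an acyclic ancestry graph, and nonnegative onset ages. Diagnostics are
#' returned, not raised, so callers can decide severity.
#'
#' @param ped A [pedigree()].
#' @return Character vector of diagnostics; empty when all invariants hold.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  diag <- character(0)
  dup <- unique(ind$id[duplicated(ind$id)])
  for (d in dup) diag <- c(diag, sprintf("duplicate individual id '%s'", d))
  sex_of <- stats::setNames(ind$sex, ind$id)
  for (i in seq_len(nrow(ind))) {
    for (role in c("father", "mother")) {
      pid <- ind[[paste0(role, "_id")]][i]
      if (is.na(pid)) next
      if (!pid %in% ind$id) {
        diag <- c(diag, sprintf("%s '%s' of '%s' not in pedigree",
                                role, pid, ind$id[i]))
      } else {
        want <- if (role == "father") "male" else "female"
        if (sex_of[[pid]] != want) {
          diag <- c(diag, sprintf(
            "%s '%s' of '%s' has sex '%s' (expected %s)",
            role, pid, ind$id[i], sex_of[[pid]], want))
        }
      }
    }
  }
  # cycle check: repeatedly peel individuals whose parents are all peeled
  known <- ind$id
  resolved <- character(0)
  remaining <- ind
  repeat {
    ok <- vapply(seq_len(nrow(remaining)), function(i) {
      f <- remaining$father_id[i]; m <- remaining$mother_id[i]
      (is.na(f) || f %in% resolved || !f %in% known) &&
        (is.na(m) || m %in% resolved || !m %in% known)
    }, logical(1))
    if (!any(ok)) break
    resolved <- c(resolved, remaining$id[ok])
    remaining <- remaining[!ok, , drop = FALSE]
    if (nrow(remaining) == 0L) break
  }
  for (id in remaining$id) {
    diag <- c(diag, sprintf("individual '%s' lies on an ancestry cycle", id))
  }
  for (id in names(ped$phen)) {
    p <- ped$phen[[id]]
    bad <- !is.na(p$onset) & p$onset < 0
    for (lab in p$label[bad]) {
      diag <- c(diag, sprintf("negative onset age for '%s' (%s)", id, lab))
    }
  }
  diag
}

#' Phenotype labels present in a pedigree
#' @param ped A [pedigree()].
#' @return Character vector of distinct labels.
#' @export
phenotype_labels <- function(ped) {
  unique(unlist(lapply(ped$phen, function(p) p$label), use.names = FALSE))
}

#' Select individuals by phenotype
#'
#' Returns the ids of individuals whose diagnosis labels satisfy the query:
#' `all_of` requires every requested label to be present (e.g. the Family 2
#' patients with both breast and lung cancer), `any_of` requires at least
#' one. Optionally intersects with the sequenced set.
#'
#' @param ped A [pedigree()].
#' @param labels Character vector of phenotype labels (non-empty).
#' @param mode `"all_of"` or `"any_of"`.
#' @param sequenced_only Restrict to sequenced individuals?
#' @return Character vector of individual ids (possibly empty).
#' @export
select_individuals <- function(ped, labels, mode = c("all_of", "any_of"),
                               sequenced_only = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(ped, "pedigree"), length(labels) >= 1L)
  known <- phenotype_labels(ped)
  unknown <- setdiff(labels, known)
  if (length(unknown)) {
    stop("unknown phenotype label(s): ", paste(unknown, collapse = ", "))
  }
  hit <- vapply(ped$ind$id, function(id) {
    have <- if (is.null(ped$phen[[id]])) character(0) else ped$phen[[id]]$label
    if (mode == "all_of") all(labels %in% have) else any(labels %in% have)
  }, logical(1))
  ids <- ped$ind$id[hit]
  if (sequenced_only) ids <- intersect(ids, ped$ind$id[ped$ind$sequenced])
  ids
}

#' Sequenced individual ids
#' @param ped A [pedigree()].
#' @return Character vector.
#' @export
sequenced_ids <- function(ped) ped$ind$id[ped$ind$sequenced]

#' Read a PED file (with optional phenotype sidecar)
#'
#' Standard 6-column PED: family, individual, father, mother, sex (1 male /
#' 2 female / 0 unknown), affection (1 unaffected / 2 affected / 0 unknown);
#' `"0"` as a parent id denotes a founder. The optional sidecar is a
#' tab-separated table with columns `individual`, `phenotypes`
#' (comma-separated `label@onset` entries, `.` for none) and optionally
#' `sequenced` (0/1). Without a sidecar every individual is taken as
#' sequenced and affected individuals get the generic label `"affected"`.
#'
#' @param path PED file path.
#' @param phenotype_path Optional sidecar path.
#' @return A [pedigree()] (the PED's first family).
#' @export
read_ped <- function(path, phenotype_path = NULL) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(raw) < 6L) stop("PED file must have at least 6 columns: ", path)
  names(raw)[1:6] <- c("family", "id", "father", "mother", "sex", "aff")
  fam <- unique(raw$family)
  if (length(fam) > 1L) {
    warning("PED contains several families; using '", fam[1], "'")
    raw <- raw[raw$family == fam[1], , drop = FALSE]
  }
  ind <- data.frame(
    id = raw$id,
    father_id = ifelse(raw$father == "0", NA_character_, raw$father),
    mother_id = ifelse(raw$mother == "0", NA_character_, raw$mother),
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[raw$sex],
    sequenced = TRUE,
    stringsAsFactors = FALSE
  )
  phen <- list()
  if (is.null(phenotype_path)) {
    for (i in which(raw$aff == "2")) {
      phen[[ind$id[i]]] <- data.frame(label = "affected", onset = NA_real_)
    }
  } else {
    side <- utils::read.delim(phenotype_path, colClasses = "character")
    if (!all(c("individual", "phenotypes") %in% names(side))) {
      stop("phenotype sidecar needs columns 'individual' and 'phenotypes'")
    }
    if ("sequenced" %in% names(side)) {
      m <- match(ind$id, side$individual)
      ind$sequenced <- ifelse(is.na(m), FALSE, side$sequenced[m] == "1")
    }
    for (i in seq_len(nrow(side))) {
      ph <- side$phenotypes[i]
      if (is.na(ph) || ph == "." || ph == "") next
      parts <- strsplit(ph, ",", fixed = TRUE)[[1]]
      lab <- sub("@.*$", "", parts)
      age <- suppressWarnings(as.numeric(sub("^[^@]*@?", "", parts)))
      phen[[side$individual[i]]] <- data.frame(label = lab, onset = age)
    }
  }
  pedigree(fam[1], ind, phen)
}

#' Write a pedigree as PED plus phenotype sidecar
#'
#' Inverse of [read_ped()]: emits the 6-column PED (affection 2 for any
#' individual carrying a phenotype label, else 1) and a sidecar carrying the
#' labels, onset ages and the sequenced flag.
#'
#' @param ped A [pedigree()].
#' @param path PED output path.
#' @param phenotype_path Sidecar output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path, phenotype_path) {
  ind <- ped$ind
  aff <- ifelse(vapply(ind$id, function(id) {
    p <- ped$phen[[id]]; !is.null(p) && nrow(p) > 0L
  }, logical(1)), "2", "1")
  out <- data.frame(
    family = ped$family_id, id = ind$id,
    father = ifelse(is.na(ind$father_id), "0", ind$father_id),
    mother = ifelse(is.na(ind$mother_id), "0", ind$mother_id),
    sex = c(male = "1", female = "2", unknown = "0")[ind$sex],
    aff = aff
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- data.frame(
    individual = ind$id,
    phenotypes = vapply(ind$id, function(id) {
      p <- ped$phen[[id]]
      if (is.null(p) || nrow(p) == 0L) return(".")
      paste(ifelse(is.na(p$onset), p$label, paste0(p$label, "@", p$onset)),
            collapse = ",")
    }, character(1)),
    sequenced = ifelse(ind$sequenced, "1", "0")
  )
  utils::write.table(side, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
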