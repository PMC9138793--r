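#' Canonical variant key strings
#'
#' Variants are keyed as `"chr:pos_ref/alt"` with hg19-style `"chr"`-prefixed
#' chromosome names; bare names (`"17"`) are normalized to `"chr17"` on the
#' way in. Positions are 1-based; indels follow the VCF left-anchored
#' convention (so a printed `TG/T` deletion is ref `TG`, alt `T` at the
#' printed position).
#'
#' @param chrom Chromosome name(s), with or without `"chr"` prefix.
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings (one alt per key; multi-allelic records are
#'   decomposed upstream).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  if (length(pos) == 0L) return(character(0))
  paste0(norm_chrom(chrom), ":", as.integer(pos), "_", ref, "/", alt)
}

norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Construct a genotype matrix
#'
#' Dense per-variant, per-individual alternate-allele counts: 0, 1, 2 or
#' `NA` (missing call). Hemizygous male X calls are normalized to 0/2 and
#' flagged in the `hemi` matrix. Phasing is ignored throughout (carrier
#' logic is phase-free).
#'
#' @param keys A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param calls Integer matrix, variants in rows, individuals in columns
#'   (column names are individual ids).
#' @param hemi Optional logical matrix of the same shape marking hemizygous
#'   calls; defaults to all `FALSE`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(keys, calls, hemi = NULL) {
  stopifnot(is.data.frame(keys),
            all(c("chrom", "pos", "ref", "alt") %in% names(keys)))
  keys$chrom <- norm_chrom(keys$chrom)
  keys$pos <- as.integer(keys$pos)
  if (any(keys$pos < 1L)) stop("positions must be >= 1")
  if (any(keys$ref == keys$alt)) stop("ref and alt alleles must differ")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(keys)) stop("calls/keys row mismatch")
  if (is.null(colnames(calls))) stop("calls must carry individual ids as colnames")
  kk <- variant_key(keys$chrom, keys$pos, keys$ref, keys$alt)
  if (anyDuplicated(kk)) stop("duplicate variant keys")
  rownames(calls) <- kk
  if (is.null(hemi)) {
    hemi <- matrix(FALSE, nrow(calls), ncol(calls))
  }
  hemi <- as.matrix(hemi)
  dimnames(hemi) <- dimnames(calls)
  structure(list(keys = keys, calls = calls, hemi = hemi),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$calls), " variants x ", ncol(x$calls),
      " individuals\n", sep = "")
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  hemi <- x$hemi[i, j, drop = FALSE]
  keys <- x$keys[match(rownames(calls),
                       variant_key(x$keys$chrom, x$keys$pos, x$keys$ref,
                                   x$keys$alt)), , drop = FALSE]
  genotype_matrix(keys, calls, hemi)
}

parse_gt_field <- function(gt) {
  # returns list(alleles = list of integer vectors); "." entries are NA
  gt <- sub(":.*$", "", gt)
  strsplit(gt, "[/|]")
}

#' Read genotypes from a multi-sample VCF
#'
#' Reads a VCF (v4.2) with `vcfR` and returns a [genotype_matrix()] of
#' alternate-allele counts. Multi-allelic records are decomposed into one
#' variant per alternate allele, with each sample's count recoded against
#' that allele (the total number of alt alleles an individual carries at a
#' site is preserved). `./.` becomes `NA`. Haploid calls on male X are
#' normalized to 0/2 with a hemizygous flag, using `sex_of` when given.
#'
#' @param path VCF path (plain or gzipped).
#' @param sample_subset Optional character vector of sample ids to keep; an
#'   error lists any that are absent from the header.
#' @param sex_of Optional named character vector id -> sex, used to flag
#'   haploid X calls as hemizygous.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL, sex_of = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {  # single-record VCFs come back as a bare vector
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no genotype columns: ", path)
  samples <- colnames(gt)[-1]
  if (!is.null(sample_subset)) {
    absent <- setdiff(sample_subset, samples)
    if (length(absent)) {
      stop("sample(s) absent from VCF header: ", paste(absent, collapse = ", "))
    }
    samples <- sample_subset
  }
  keys <- list(); calls <- list(); hemi <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    al <- parse_gt_field(gt[r, samples])
    for (ai in seq_along(alts)) {
      cnt <- integer(length(samples)); hz <- logical(length(samples))
      for (s in seq_along(samples)) {
        a <- al[[s]]
        if (length(a) == 0L || anyNA(a) || any(a == ".")) {
          cnt[s] <- NA_integer_; next
        }
        ia <- suppressWarnings(as.integer(a))
        if (any(is.na(ia))) {
          stop("malformed GT '", gt[r, samples[s]], "' at record ", r)
        }
        n_alt <- sum(ia == ai)
        if (length(ia) == 1L) {  # haploid call
          is_x <- grepl("^(chr)?X$", fix$CHROM[r])
          male <- !is.null(sex_of) && identical(sex_of[[samples[s]]], "male")
          if (is_x && (is.null(sex_of) || male)) {
            cnt[s] <- 2L * n_alt; hz[s] <- TRUE
          } else cnt[s] <- n_alt
        } else cnt[s] <- n_alt
      }
      keys[[length(keys) + 1L]] <- data.frame(
        chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        ref = fix$REF[r], alt = alts[ai], stringsAsFactors = FALSE)
      calls[[length(calls) + 1L]] <- cnt
      hemi[[length(hemi) + 1L]] <- hz
    }
  }
  if (!length(keys)) stop("VCF contains no variant records: ", path)
  keys <- do.call(rbind, keys)
  cm <- do.call(rbind, calls); hm <- do.call(rbind, hemi)
  colnames(cm) <- colnames(hm) <- samples
  genotype_matrix(keys, cm, hm)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT. Diploid counts are written
#' `0/0`, `0/1`, `1/1`; missing as `./.`; hemizygous-flagged calls as
#' haploid `0`/`1`. Round-trips through [read_vcf()] preserve keys, sample
#' order and allele counts exactly.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  k <- geno$keys
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=pedfilter",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno$calls)), collapse = "\t"))
  body <- vapply(seq_len(nrow(k)), function(r) {
    g <- vapply(seq_len(ncol(geno$calls)), function(s) {
      ac <- geno$calls[r, s]
      if (is.na(ac)) return("./.")
      if (geno$hemi[r, s]) return(as.character(ac %/% 2L))
      gt_str[ac + 1L]
    }, character(1))
    paste(c(k$chrom[r], k$pos[r], ".", k$ref[r], k$alt[r], ".", "PASS", ".",
            "GT", g), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

match_col <- function(nms, candidates) {
  hit <- which(tolower(nms) %in% candidates)
  if (length(hit)) hit[1] else NA_integer_
}

#' Read a per-variant annotation table
#'
#' Tab-separated, one row per variant, with header naming at least the
#' chromosome, position, ref/alt alleles, gene symbol, consequence and CADD
#' score. Allele-frequency columns are recognized by name (`af_*` by
#' default, or an explicit list); `"."` or empty frequency cells mean "not
#' observed in that database" and are kept absent, distinct from an explicit
#' zero — both contribute 0 to the MMAF, but absent-everywhere marks the
#' variant as novel together with a missing rsID. MMAF (the maximum
#' alternate-allele frequency over sources) and the novelty flag are
#' computed on read.
#'
#' @param path Annotation TSV path.
#' @param af_cols Optional character vector naming the frequency columns;
#'   default: every column whose name starts with `"af_"` (case-insensitive).
#' @return A data.frame of class `variant_annotation` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `key`, `gene`, `consequence` (classified),
#'   `consequence_raw`, `hgvs`, `rsid`, `clinvar`, the `af_*` columns,
#'   `mmaf` and `novel`.
#' @export
read_annotation_table <- function(path, af_cols = NULL) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  nms <- names(raw)
  idx <- c(chrom = match_col(nms, c("chrom", "chr", "chromosome")),
           pos = match_col(nms, c("pos", "position", "start")),
           ref = match_col(nms, c("ref", "reference")),
           alt = match_col(nms, c("alt", "alternate")),
           gene = match_col(nms, c("gene", "gene.refgene", "symbol")),
           consequence = match_col(nms, c("consequence", "type",
                                          "exonicfunc.refgene", "func")),
           cadd = match_col(nms, c("cadd", "cadd_phred", "cadd13_phred")))
  if (anyNA(idx)) {
    stop("annotation table lacks required column(s): ",
         paste(names(idx)[is.na(idx)], collapse = ", "))
  }
  if (is.null(af_cols)) af_cols <- nms[grepl("^af_", tolower(nms))]
  opt <- c(rsid = match_col(nms, c("rsid", "snp", "avsnp150", "id")),
           clinvar = match_col(nms, c("clinvar", "clnsig")),
           hgvs = match_col(nms, c("hgvs", "change", "aachange")))
  ann <- data.frame(
    chrom = norm_chrom(raw[[idx["chrom"]]]),
    pos = as.integer(raw[[idx["pos"]]]),
    ref = raw[[idx["ref"]]],
    alt = raw[[idx["alt"]]],
    gene = raw[[idx["gene"]]],
    consequence_raw = raw[[idx["consequence"]]],
    stringsAsFactors = FALSE
  )
  cadd_raw <- raw[[idx["cadd"]]]
  cadd <- suppressWarnings(as.numeric(cadd_raw))
  bad <- which(is.na(cadd) & !(cadd_raw %in% c(".", "", NA)))
  if (length(bad)) {
    stop("unparseable CADD value '", cadd_raw[bad[1]], "' at row ", bad[1])
  }
  ann$cadd <- cadd
  for (nm in c("rsid", "clinvar", "hgvs")) {
    v <- if (is.na(opt[nm])) rep(".", nrow(raw)) else raw[[opt[nm]]]
    v[v == "" | is.na(v)] <- "."
    ann[[nm]] <- v
  }
  ann$clinvar <- tolower(ann$clinvar)
  ann$clinvar[ann$clinvar == "."] <- "absent"
  afs <- matrix(NA_real_, nrow(raw), length(af_cols),
                dimnames = list(NULL, af_cols))
  for (ac in af_cols) {
    v <- raw[[ac]]
    v[v %in% c(".", "")] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) stop("unparseable frequency in column ", ac)
    if (any(num < 0 | num > 1, na.rm = TRUE)) {
      stop("allele frequency outside [0,1] in column ", ac)
    }
    afs[, ac] <- num
    ann[[ac]] <- num
  }
  ann$mmaf <- as.numeric(apply(afs, 1L, function(x) {
    if (all(is.na(x))) 0 else max(x, na.rm = TRUE)
  }))
  if (!length(af_cols)) ann$mmaf <- rep(0, nrow(ann))
  ann$novel <- as.logical(apply(afs, 1L, function(x) all(is.na(x)))) &
    ann$rsid == "."
  if (!length(af_cols)) ann$novel <- ann$rsid == "."
  ann$consequence <- classify_consequence(ann$consequence_raw)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$key)) {
    stop("duplicate variant row(s): ",
         paste(unique(ann$key[duplicated(ann$key)]), collapse = ", "))
  }
  attr(ann, "af_cols") <- af_cols
  class(ann) <- c("variant_annotation", "data.frame")
  ann
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]: writes a TSV that function can read
#' back. Absent frequencies, rsIDs and HGVS strings are written as `"."`.
#'
#' @param ann A `variant_annotation` data.frame (or compatible).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(ann, path) {
  af_cols <- attr(ann, "af_cols")
  if (is.null(af_cols)) af_cols <- names(ann)[grepl("^af_", names(ann))]
  out <- data.frame(
    chrom = ann$chrom, pos = ann$pos, ref = ann$ref, alt = ann$alt,
    gene = ann$gene,
    consequence = if ("consequence_raw" %in% names(ann)) ann$consequence_raw
                  else ann$consequence,
    change = ann$hgvs, rsid = ann$rsid,
    clinvar = ifelse(ann$clinvar == "absent", ".", ann$clinvar),
    stringsAsFactors = FALSE)
  for (ac in af_cols) out[[ac]] <- num_or_dot(ann[[ac]])
  out$cadd <- num_or_dot(ann$cadd)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

num_or_dot <- function(x) {
  ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE, digits = 15))
}

#' Write a candidate table
#'
#' Tab-separated with the columns `Filter`, `Gene`, `Position`, `Ref/Alt`,
#' `SNP`, `Type`, `Change`, `MMAF`, `CADD`, sorted by filter stratum
#' ascending, then CADD descending, ties broken by genomic position
#' ascending. Absent fields are `"."`.
#'
#' @param candidates Candidate data.frame as produced by
#'   [run_family_cascade()] (component `candidates`), or a `family_cascade`
#'   object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_table <- function(candidates, path) {
  if (inherits(candidates, "family_cascade")) candidates <- candidates$candidates
  cols <- c("Filter", "Gene", "Position", "Ref/Alt", "SNP", "Type", "Change",
            "MMAF", "CADD")
  if (nrow(candidates) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  ord <- order(candidates$filter,
               -candidates$cadd,
               norm_chrom(candidates$chrom),
               candidates$pos)
  cd <- candidates[ord, , drop = FALSE]
  out <- data.frame(
    Filter = cd$filter, Gene = cd$gene,
    Position = paste0(cd$chrom, ":", cd$pos),
    RefAlt = paste0(cd$ref, "/", cd$alt),
    SNP = cd$rsid, Type = cd$consequence, Change = cd$hgvs,
    MMAF = num_or_dot(cd$mmaf), CADD = num_or_dot(cd$cadd),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- cols
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
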