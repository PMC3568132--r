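# Domain containers and readers/writers: variant tables, pedigrees, site sets.

.variant_columns <- c(
  "chrom", "pos", "ref", "alt", "vtype", "zygosity",
  "depth_ref", "depth_alt", "phred_ref", "phred_alt", "snp_quality",
  "consequence", "gene", "db_flags"
)

#' Construct a variant table
#'
#' A variant table is a plain `data.frame` with one row per called variant
#' in one sample. Required columns are `chrom`, `pos`, `ref` and `alt`;
#' all evidence and annotation columns are filled with defaults when
#' absent. Per-allele read depths (`depth_ref`, `depth_alt`) and
#' Phred-scaled allele quality masses (`phred_ref`, `phred_alt`) may be
#' `NA` when the caller did not report them; downstream scores are then
#' undefined rather than zero. `db_flags` holds comma-separated database
#' membership labels (e.g. `"dbsnp,control_panel"`), empty when none.
#'
#' @param df data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return Validated data frame with the full column set, in canonical
#'   column order.
#' @examples
#' variant_table(data.frame(chrom = "c1", pos = 100, ref = "A", alt = "G"))
#' @export
variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("variant table lacks required columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  if (is.null(df$vtype))
    df$vtype <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV", "INDEL")
  if (is.null(df$zygosity)) df$zygosity <- rep("het", n)
  for (col in c("depth_ref", "depth_alt"))
    df[[col]] <- if (is.null(df[[col]])) rep(NA_integer_, n) else as.integer(df[[col]])
  for (col in c("phred_ref", "phred_alt", "snp_quality"))
    df[[col]] <- if (is.null(df[[col]])) rep(NA_real_, n) else as.numeric(df[[col]])
  if (is.null(df$consequence)) df$consequence <- rep(NA_character_, n)
  df$consequence <- as.character(df$consequence)
  if (is.null(df$gene)) df$gene <- rep("", n)
  df$gene <- as.character(df$gene)
  if (is.null(df$db_flags)) df$db_flags <- rep("", n)
  df$db_flags <- as.character(df$db_flags)

  if (n > 0) {
    if (any(is.na(df$pos)) || any(df$pos < 1L))
      stop("variant positions must be 1-based integers >= 1")
    if (any(!df$vtype %in% c("SNV", "INDEL")))
      stop("vtype must be 'SNV' or 'INDEL'")
    if (any(!df$zygosity %in% c("het", "hom")))
      stop("zygosity must be 'het' or 'hom'")
    bad <- df$vtype == "SNV" & (nchar(df$ref) != 1L | nchar(df$alt) != 1L)
    if (any(bad)) stop("SNV records must have single-base ref and alt alleles")
    for (col in c("depth_ref", "depth_alt")) {
      v <- df[[col]]
      if (any(!is.na(v) & v < 0L)) stop(col, " must be >= 0")
    }
  }
  rownames(df) <- NULL
  df[, .variant_columns]
}

# ---------------------------------------------------------------------------
# VCF dialect

#' VCF dialect configuration
#'
#' The variant reader/writer speaks a minimal single-sample VCF 4.x
#' subset: per-allele read depths and per-allele Phred-scaled quality
#' masses live in named FORMAT fields (`AD`-style `ref,alt` pairs), the
#' site quality in QUAL, and annotations in INFO (`VT`, `CSQ`, `GENE`,
#' `DB`; database flags separated by `|`).
#'
#' @param depth_field FORMAT field holding `ref,alt` read depths.
#' @param qual_field FORMAT field holding `ref,alt` Phred quality masses.
#' @param sample_name sample column name used when writing.
#' @return A list of class `vcf_dialect`.
#' @export
vcf_dialect <- function(depth_field = "AD", qual_field = "PQ",
                        sample_name = "SAMPLE") {
  structure(list(depth_field = depth_field, qual_field = qual_field,
                 sample_name = sample_name), class = "vcf_dialect")
}

#' Read a variant table
#'
#' Reads either the package's VCF dialect (see [vcf_dialect()]) or the
#' flat tab-separated fallback written by [write_variant_table()].
#' Multi-allelic VCF records are split into one call per alternate
#' allele, all sharing `(chrom, pos, ref)`; per-allele depth/quality
#' vectors are unpacked accordingly. Missing per-record values (`.`)
#' become `NA` so downstream scores are undefined rather than zero, but a
#' FORMAT field absent from the file entirely is an error.
#'
#' @param path file path; format is chosen by extension (`.vcf` vs
#'   anything else = TSV) unless `format` is given.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @param dialect a [vcf_dialect()].
#' @return A variant table ([variant_table()]).
#' @export
load_variant_table <- function(path, format = c("auto", "vcf", "tsv"),
                               dialect = vcf_dialect()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "vcf") read_variant_vcf(path, dialect) else read_variant_tsv(path)
}

read_variant_tsv <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character())))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"), na.strings = "NA")
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("variant TSV lacks required columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(df$db_flags)) df$db_flags[is.na(df$db_flags)] <- ""
  if (!is.null(df$gene)) df$gene[is.na(df$gene)] <- ""
  variant_table(df)
}

read_variant_vcf <- function(path, dialect = vcf_dialect()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)  # keeps INFO column
  names(fix) <- toupper(names(fix))
  if (nrow(fix) == 0) {
    return(variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character())))
  }
  gt <- v@gt
  fmt_keys <- unique(unlist(strsplit(gt[, "FORMAT"], ":", fixed = TRUE)))
  for (fld in c(dialect$depth_field, dialect$qual_field)) {
    if (!fld %in% fmt_keys)
      stop("FORMAT field '", fld, "' absent from ", path,
           ": per-allele depth/quality unavailable")
  }
  ad <- vcfR::extract.gt(v, element = dialect$depth_field)[, 1]
  pq <- vcfR::extract.gt(v, element = dialect$qual_field)[, 1]
  gtv <- vcfR::extract.gt(v, element = "GT")[, 1]
  info <- fix$INFO
  info_get <- function(key) {
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info)))
    out
  }
  csq <- info_get("CSQ")
  gene <- info_get("GENE")
  dbf <- info_get("DB")

  pos <- suppressWarnings(as.integer(fix$POS))
  if (any(is.na(pos)))
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[1])

  split_num <- function(x) {
    if (is.na(x) || x == ".") return(NULL)
    suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- split_num(ad[i])
    pqs <- split_num(pq[i])
    al <- strsplit(gtv[i] %||% NA_character_, "[/|]")[[1]]
    for (j in seq_along(alts)) {
      zyg <- if (!anyNA(al) && length(al) == 2 &&
                 al[1] == al[2] && al[1] == as.character(j)) "hom" else "het"
      rec <- data.frame(
        chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts[j],
        zygosity = zyg,
        depth_ref = if (is.null(ads)) NA_integer_ else as.integer(ads[1]),
        depth_alt = if (is.null(ads) || length(ads) < j + 1) NA_integer_
                    else as.integer(ads[j + 1]),
        phred_ref = if (is.null(pqs)) NA_real_ else pqs[1],
        phred_alt = if (is.null(pqs) || length(pqs) < j + 1) NA_real_
                    else pqs[j + 1],
        snp_quality = suppressWarnings(as.numeric(fix$QUAL[i])),
        consequence = csq[i],
        gene = ifelse(is.na(gene[i]), "", gene[i]),
        db_flags = ifelse(is.na(dbf[i]), "", gsub("|", ",", dbf[i], fixed = TRUE)),
        stringsAsFactors = FALSE
      )
      rows[[paste(i, j)]] <- rec
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  variant_table(do.call(rbind, rows))
}

#' Write a variant table
#'
#' Writes either the package's single-sample VCF dialect or the flat TSV
#' form. Both round-trip through [load_variant_table()] field-by-field.
#'
#' @param vt variant table.
#' @param path output path.
#' @param format `"vcf"` or `"tsv"` (default by extension).
#' @param dialect a [vcf_dialect()].
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path, format = c("auto", "vcf", "tsv"),
                                dialect = vcf_dialect()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  vt <- variant_table(vt)
  if (format == "tsv") {
    utils::write.table(vt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type (SNV/INDEL)\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Functional consequence\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=DB,Number=1,Type=String,Description=\"Database membership flags, |-separated\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##FORMAT=<ID=%s,Number=R,Type=Integer,Description=\"Read depths (ref,alt)\">",
            dialect$depth_field),
    sprintf("##FORMAT=<ID=%s,Number=R,Type=Float,Description=\"Phred-scaled allele quality mass (ref,alt)\">",
            dialect$qual_field),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", dialect$sample_name, sep = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
  pair <- function(a, b) ifelse(is.na(a) & is.na(b), ".",
                                paste(fmt_num(a), fmt_num(b), sep = ","))
  info <- paste0("VT=", vt$vtype)
  info <- paste0(info, ifelse(is.na(vt$consequence), "",
                              paste0(";CSQ=", vt$consequence)))
  info <- paste0(info, ifelse(vt$gene == "", "", paste0(";GENE=", vt$gene)))
  info <- paste0(info, ifelse(vt$db_flags == "", "",
                              paste0(";DB=", gsub(",", "|", vt$db_flags, fixed = TRUE))))
  gt <- ifelse(vt$zygosity == "hom", "1/1", "0/1")
  sample_col <- paste(gt, pair(vt$depth_ref, vt$depth_alt),
                      pair(vt$phred_ref, vt$phred_alt), sep = ":")
  body <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, fmt_num(vt$snp_quality),
                ".", info, paste("GT", dialect$depth_field, dialect$qual_field,
                                 sep = ":"),
                sample_col, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pedigrees and family cohorts

#' Construct a family cohort
#'
#' A family cohort bundles the pedigree rows of one family with the
#' per-member variant sets of its sequenced members. The study design
#' sequences one or two members per family; additional affected members
#' enter only through segregation analysis.
#'
#' @param family_id family identifier.
#' @param members data frame with columns `member_id`, `family_id`,
#'   `affected` (logical), `diagnosis_age` (years, `NA` when unknown or
#'   unaffected), `sequenced` (logical), `available` (logical;
#'   availability for segregation follow-up).
#' @param variant_sets named list of variant tables, one per sequenced
#'   member (names must be sequenced member ids).
#' @return Object of class `family_cohort`.
#' @export
family_cohort <- function(family_id, members, variant_sets = list()) {
  stopifnot(is.data.frame(members))
  req <- c("member_id", "family_id", "affected", "diagnosis_age",
           "sequenced", "available")
  miss <- setdiff(req, names(members))
  if (length(miss)) stop("members lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(members$member_id))
    stop("duplicate member_id within family ", family_id)
  bad_age <- !is.na(members$diagnosis_age) & !members$affected
  if (any(bad_age))
    stop("diagnosis_age given for unaffected member(s): ",
         paste(members$member_id[bad_age], collapse = ", "))
  seq_ids <- members$member_id[members$sequenced]
  if (length(seq_ids) == 0)
    stop("family ", family_id, " has no sequenced members")
  if (length(seq_ids) > 2)
    warning("family ", family_id, " has ", length(seq_ids),
            " sequenced members; the design expects at most 2")
  extra <- setdiff(names(variant_sets), seq_ids)
  if (length(extra))
    stop("variant_sets given for non-sequenced member(s): ",
         paste(extra, collapse = ", "))
  structure(list(family_id = family_id, members = members,
                 variant_sets = variant_sets),
            class = "family_cohort")
}

#' @export
print.family_cohort <- function(x, ...) {
  cat("<family_cohort> ", x$family_id, ": ", nrow(x$members), " members, ",
      sum(x$members$sequenced), " sequenced", sep = "")
  if (length(x$variant_sets))
    cat("; variant sets: ",
        paste(sprintf("%s (%d)", names(x$variant_sets),
                      vapply(x$variant_sets, nrow, 0L)), collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' Load a pedigree file into family cohorts
#'
#' Reads a FAM-like tab-separated file with header columns `family_id`,
#' `member_id`, `affected` (0/1), `diagnosis_age` (years or `NA`),
#' `sequenced` (0/1) and `available` (0/1), and groups members by family.
#' Families without any sequenced member are dropped with a warning;
#' families with more than two sequenced members are accepted with a
#' warning. A member listed in two families is an integrity error.
#'
#' @param path pedigree TSV path.
#' @return List of [family_cohort()] objects (variant sets empty).
#' @export
load_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(family_id = "character",
                                         member_id = "character"))
  req <- c("family_id", "member_id", "affected", "diagnosis_age",
           "sequenced", "available")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pedigree lacks columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(df$family_id)) || any(!nzchar(df$member_id)))
    stop("pedigree has empty family_id or member_id")
  fam_per_member <- tapply(df$family_id, df$member_id,
                           function(f) length(unique(f)))
  multi <- names(fam_per_member)[fam_per_member > 1]
  if (length(multi))
    stop("member(s) listed in more than one family: ",
         paste(multi, collapse = ", "))
  df$affected <- as.logical(as.integer(df$affected))
  df$sequenced <- as.logical(as.integer(df$sequenced))
  df$available <- as.logical(as.integer(df$available))
  df$diagnosis_age <- suppressWarnings(as.numeric(df$diagnosis_age))
  cohorts <- list()
  for (fid in unique(df$family_id)) {
    fam <- df[df$family_id == fid, , drop = FALSE]
    rownames(fam) <- NULL
    if (!any(fam$sequenced)) {
      warning("family ", fid, " has no sequenced members; dropped")
      next
    }
    cohorts[[fid]] <- family_cohort(fid, fam)
  }
  cohorts
}

#' Attach a variant set to a cohort member
#'
#' @param cohort a [family_cohort()].
#' @param member_id a sequenced member of the cohort.
#' @param vt the member's variant table.
#' @return The updated cohort.
#' @export
set_variant_set <- function(cohort, member_id, vt) {
  stopifnot(inherits(cohort, "family_cohort"))
  seq_ids <- cohort$members$member_id[cohort$members$sequenced]
  if (!member_id %in% seq_ids)
    stop(member_id, " is not a sequenced member of family ", cohort$family_id)
  cohort$variant_sets[[member_id]] <- variant_table(vt)
  cohort
}

# ---------------------------------------------------------------------------
# Site sets (exclusion lists)

#' Construct a site set
#'
#' A site set is a labelled, deduplicated set of variant identity keys
#' `(chrom, pos, ref, alt)` used as an exclusion list — e.g. the union of
#' a control panel's calls, or a known-variant database. Membership is
#' allele-aware: the same position with a different alternate allele is a
#' different key.
#'
#' @param keys character vector of keys (as from [variant_key()]), or a
#'   data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param label set label.
#' @return Object of class `site_set`.
#' @export
site_set <- function(keys = character(), label = "sites") {
  if (is.data.frame(keys)) keys <- variant_key(keys)
  structure(list(label = label, keys = unique(as.character(keys))),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat("<site_set> '", x$label, "': ", length(x$keys), " keys\n", sep = "")
  invisible(x)
}

#' @export
length.site_set <- function(x) length(x$keys)

#' Load a site set from a 4-column TSV
#'
#' Each line must hold `chrom`, `pos`, `ref`, `alt` separated by tabs
#' (a header line naming those columns is tolerated and skipped).
#' Duplicate keys are collapsed; an unparseable line is an error naming
#' the line number.
#'
#' @param path file path.
#' @param label label for the resulting set.
#' @return A [site_set()].
#' @export
load_site_set <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)))
  keys <- character(0)
  for (i in lines_keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (i == lines_keep[1] && length(f) >= 4 &&
        identical(tolower(f[1:2]), c("chrom", "pos"))) next
    if (length(f) < 4 || is.na(suppressWarnings(as.integer(f[2]))))
      stop("unparseable site-set line ", i, " in ", path, ": ", lines[i])
    keys <- c(keys, variant_key(f[1], as.integer(f[2]), f[3], f[4]))
  }
  site_set(keys, label)
}

#' Write a site set as a 4-column TSV
#'
#' @param sites a [site_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_set <- function(sites, path) {
  stopifnot(inherits(sites, "site_set"))
  parts <- strsplit(sites$keys, ":", fixed = TRUE)
  lines <- vapply(parts, function(p) paste(p, collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
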