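# DS/QS variant scoring and the staged filtering cascade.
#
# The cascade reduces per-sample heterozygous SNV and INDEL call sets to
# a short list of candidate variants per family:
#
#   detected -> shared_in_family -> not_in_control_panel -> not_in_dbsnp
#            -> consequence -> score_and_gene
#
# SNVs and INDELs run through the same stages but with different
# consequence blacklists and score criteria, and are summarized as two
# separate funnels.

#' Cascade configuration
#'
#' Thresholds and switches for the variant-filtering cascade. Defaults
#' are the calibrated operating point of the pipeline: SNVs keep a Depth
#' Score (DS) and Quality Score (QS) between 20 and 210 (inclusive);
#' INDELs require DS strictly below 140, variant-allele Phred quality and
#' caller site quality strictly above 10, and at least 3 reads supporting
#' each allele.
#'
#' @param snp_score_low,snp_score_high inclusive DS/QS window for SNVs.
#' @param indel_ds_max strict DS upper bound for INDELs.
#' @param indel_phred_min strict lower bound on the variant allele's
#'   Phred quality mass (INDELs).
#' @param indel_snpq_min strict lower bound on caller site quality (INDELs).
#' @param indel_min_reads_each minimum reads supporting each of the
#'   reference and variant alleles (INDELs).
#' @param consequence_blacklist_snv consequence labels discarded for SNVs.
#' @param consequence_blacklist_indel consequence labels discarded for
#'   INDELs (synonymous is meaningless for INDELs and is not listed).
#' @param gene_allowlist character vector of gene symbols, or `NULL` to
#'   disable gene filtering.
#' @param het_only restrict SNVs to heterozygous calls (the design
#'   assumes a dominant model in outbred families).
#' @param score_orientation which allele ratio defines DS/QS:
#'   `"alt_over_ref"` (default) computes `100 * alt / ref`;
#'   `"ref_over_alt"` swaps the roles.
#' @param index_member which sequenced member's evidence fields are kept
#'   for a family-shared variant (1 = first listed).
#' @return List of class `cascade_config`.
#' @export
cascade_config <- function(snp_score_low = 20, snp_score_high = 210,
                           indel_ds_max = 140, indel_phred_min = 10,
                           indel_snpq_min = 10, indel_min_reads_each = 3L,
                           consequence_blacklist_snv =
                             c("intronic", "intergenic", "synonymous"),
                           consequence_blacklist_indel =
                             c("intronic", "intergenic"),
                           gene_allowlist = NULL,
                           het_only = TRUE,
                           score_orientation = c("alt_over_ref", "ref_over_alt"),
                           index_member = 1L) {
  score_orientation <- match.arg(score_orientation)
  stopifnot(snp_score_low >= 0, snp_score_low <= snp_score_high,
            indel_min_reads_each >= 0)
  structure(list(
    snp_score_low = snp_score_low, snp_score_high = snp_score_high,
    indel_ds_max = indel_ds_max, indel_phred_min = indel_phred_min,
    indel_snpq_min = indel_snpq_min,
    indel_min_reads_each = as.integer(indel_min_reads_each),
    consequence_blacklist_snv = consequence_blacklist_snv,
    consequence_blacklist_indel = consequence_blacklist_indel,
    gene_allowlist = gene_allowlist, het_only = het_only,
    score_orientation = score_orientation,
    index_member = as.integer(index_member)
  ), class = "cascade_config")
}

#' Depth Score
#'
#' The Depth Score (DS) is the ratio of the read depths of the variant
#' and reference alleles, in percent: `100 * depth_alt / depth_ref`.
#' Equal evidence for both alleles gives DS = 100; values above 100 are
#' legal (more variant than reference reads). When the reference depth is
#' zero the score is undefined (`NA`), not zero.
#'
#' @param depth_alt,depth_ref read counts supporting the variant and
#'   reference alleles.
#' @return Numeric vector of scores (`NA` where undefined).
#' @examples
#' depth_score(10, 10)  # 100
#' depth_score(21, 10)  # 210
#' depth_score(3, 0)    # NA
#' @export
depth_score <- function(depth_alt, depth_ref) {
  out <- 100 * depth_alt / depth_ref
  out[!is.na(depth_ref) & depth_ref == 0] <- NA_real_
  out
}

#' Quality Score
#'
#' The Quality Score (QS) is the ratio of the Phred-scaled quality
#' masses of the variant and reference alleles, in percent:
#' `100 * phred_alt / phred_ref`; undefined (`NA`) when the reference
#' mass is zero.
#'
#' @param phred_alt,phred_ref Phred-scaled quality mass of the variant
#'   and reference alleles.
#' @return Numeric vector of scores (`NA` where undefined).
#' @export
quality_score <- function(phred_alt, phred_ref) {
  out <- 100 * phred_alt / phred_ref
  out[!is.na(phred_ref) & phred_ref == 0] <- NA_real_
  out
}

#' DS/QS score pair for a variant table
#'
#' @param vt variant table.
#' @param config a [cascade_config()]; its `score_orientation` decides
#'   which allele goes in the numerator.
#' @return Data frame with columns `ds`, `qs` aligned with `vt` rows.
#' @export
variant_scores <- function(vt, config = cascade_config()) {
  if (config$score_orientation == "alt_over_ref") {
    data.frame(ds = depth_score(vt$depth_alt, vt$depth_ref),
               qs = quality_score(vt$phred_alt, vt$phred_ref))
  } else {
    data.frame(ds = depth_score(vt$depth_ref, vt$depth_alt),
               qs = quality_score(vt$phred_ref, vt$phred_alt))
  }
}

# ---------------------------------------------------------------------------
# Stage filters

#' Variants shared by all sequenced members of a family
#'
#' For two-member families, keeps variants whose identity key
#' `(chrom, pos, ref, alt)` appears in both members' sets; evidence
#' fields are taken from the configured index member. Single-member
#' families pass through unchanged.
#'
#' @param cohort a [family_cohort()] with variant sets attached.
#' @param index_member which member's records supply the retained
#'   evidence fields (1 = first listed sequenced member).
#' @return Variant table of the shared variants.
#' @export
shared_in_family <- function(cohort, index_member = 1L) {
  stopifnot(inherits(cohort, "family_cohort"))
  sets <- cohort$variant_sets
  if (length(sets) == 0) stop("cohort has no variant sets attached")
  idx <- sets[[index_member]]
  if (length(sets) == 1) return(idx)
  keys <- lapply(sets, variant_key)
  keep <- keys[[index_member]]
  for (j in seq_along(sets)[-index_member]) keep <- keep[keep %in% keys[[j]]]
  idx[variant_key(idx) %in% keep, , drop = FALSE]
}

#' Exclude variants present in a site set
#'
#' Allele-aware removal of variants whose key belongs to the given set.
#' In the cascade this runs once against the control-panel union and once
#' against the known-variant database.
#'
#' @param vt variant table.
#' @param sites a [site_set()].
#' @return The retained subset of `vt`.
#' @export
exclude_sites <- function(vt, sites) {
  stopifnot(inherits(sites, "site_set"))
  vt[!(variant_key(vt) %in% sites$keys), , drop = FALSE]
}

#' Functional-consequence filter
#'
#' Discards SNVs whose consequence label is blacklisted for SNVs
#' (default intronic, intergenic, synonymous) and INDELs whose label is
#' blacklisted for INDELs (default intronic, intergenic). All other
#' labels — including UTR3 — are retained. Every variant must carry a
#' consequence label.
#'
#' @param vt variant table.
#' @param config a [cascade_config()].
#' @return The retained subset of `vt`.
#' @export
consequence_filter <- function(vt, config = cascade_config()) {
  if (nrow(vt) > 0 && any(is.na(vt$consequence)))
    stop("variant(s) without a consequence label")
  drop_ <- (vt$vtype == "SNV" & vt$consequence %in% config$consequence_blacklist_snv) |
           (vt$vtype == "INDEL" & vt$consequence %in% config$consequence_blacklist_indel)
  vt[!drop_, , drop = FALSE]
}

#' SNV score filter
#'
#' Keeps SNVs with both DS and QS defined and inside the inclusive
#' window `[snp_score_low, snp_score_high]` (default 20–210). Undefined
#' scores fail: the window cannot be certified.
#'
#' @param vt variant table of SNVs.
#' @param config a [cascade_config()].
#' @return The retained subset of `vt`.
#' @export
score_filter_snv <- function(vt, config = cascade_config()) {
  sc <- variant_scores(vt, config)
  keep <- !is.na(sc$ds) & !is.na(sc$qs) &
    sc$ds >= config$snp_score_low & sc$ds <= config$snp_score_high &
    sc$qs >= config$snp_score_low & sc$qs <= config$snp_score_high
  vt[keep, , drop = FALSE]
}

#' INDEL score filter
#'
#' Keeps INDELs with DS defined and strictly below `indel_ds_max`
#' (default 140), variant-allele Phred quality strictly above
#' `indel_phred_min` (10), caller site quality strictly above
#' `indel_snpq_min` (10), and at least `indel_min_reads_each` (3) reads
#' supporting each of the reference and variant alleles.
#'
#' @param vt variant table of INDELs.
#' @param config a [cascade_config()].
#' @return The retained subset of `vt`.
#' @export
score_filter_indel <- function(vt, config = cascade_config()) {
  sc <- variant_scores(vt, config)
  keep <- !is.na(sc$ds) & sc$ds < config$indel_ds_max &
    !is.na(vt$phred_alt) & vt$phred_alt > config$indel_phred_min &
    !is.na(vt$snp_quality) & vt$snp_quality > config$indel_snpq_min &
    !is.na(vt$depth_ref) & vt$depth_ref >= config$indel_min_reads_each &
    !is.na(vt$depth_alt) & vt$depth_alt >= config$indel_min_reads_each
  vt[keep, , drop = FALSE]
}

#' Gene-function filter
#'
#' Keeps variants whose gene symbol is on the allowlist; with a `NULL`
#' allowlist the filter is disabled and acts as identity. For funnel
#' accounting this filter and the score filters form one joint
#' "score and gene" stage.
#'
#' @param vt variant table.
#' @param allowlist character vector of gene symbols, or `NULL`.
#' @return The retained subset of `vt`.
#' @export
gene_function_filter <- function(vt, allowlist = NULL) {
  if (is.null(allowlist)) return(vt)
  vt[vt$gene %in% allowlist, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Full cascade

.stage_labels <- c("detected", "shared_in_family", "not_in_control_panel",
                   "not_in_dbsnp", "consequence", "score_and_gene")

#' Run the full variant-filtering cascade over a family collection
#'
#' Applies, per family: selection of heterozygous SNVs (all INDELs),
#' within-family sharing, control-panel exclusion, known-variant
#' exclusion, the consequence filter, and the joint score + gene stage.
#' Per-sample detected counts and per-family counts at every stage are
#' recorded, separately for SNVs and INDELs, and summarized as two
#' funnels (see [summarize_funnel()]).
#'
#' @param cohorts list of [family_cohort()] objects with variant sets.
#' @param control_sites [site_set()] of control-panel variant keys
#'   (union over panel individuals).
#' @param known_sites [site_set()] of known-variant database keys.
#' @param config a [cascade_config()].
#' @return Object of class `cascade_result`: list with `survivors` (named
#'   list of per-family variant tables), `funnel_snv` and `funnel_indel`
#'   ([funnel_table] objects), `per_sample_detected` and
#'   `per_family_counts` data frames.
#' @export
run_cascade <- function(cohorts, control_sites, known_sites,
                        config = cascade_config()) {
  per_sample <- list()
  per_family <- list()
  survivors <- list()
  for (cohort in cohorts) {
    fid <- cohort$family_id
    sets <- lapply(cohort$variant_sets, function(vt) {
      keep <- vt$vtype == "INDEL" | (!config$het_only | vt$zygosity == "het")
      vt[keep, , drop = FALSE]
    })
    det <- do.call(rbind, lapply(names(sets), function(m) {
      data.frame(family_id = fid, member_id = m,
                 snv = sum(sets[[m]]$vtype == "SNV"),
                 indel = sum(sets[[m]]$vtype == "INDEL"),
                 stringsAsFactors = FALSE)
    }))
    per_sample[[fid]] <- det

    cohort$variant_sets <- sets
    s2 <- shared_in_family(cohort, config$index_member)
    s3 <- exclude_sites(s2, control_sites)
    s4 <- exclude_sites(s3, known_sites)
    s5 <- consequence_filter(s4, config)
    s6_snv <- gene_function_filter(
      score_filter_snv(s5[s5$vtype == "SNV", , drop = FALSE], config),
      config$gene_allowlist)
    s6_indel <- gene_function_filter(
      score_filter_indel(s5[s5$vtype == "INDEL", , drop = FALSE], config),
      config$gene_allowlist)
    surv <- rbind(s6_snv, s6_indel)
    rownames(surv) <- NULL
    survivors[[fid]] <- surv

    cnt <- function(vt, what) sum(vt$vtype == what)
    per_family[[fid]] <- data.frame(
      family_id = fid,
      vtype = c("SNV", "INDEL"),
      shared_in_family = c(cnt(s2, "SNV"), cnt(s2, "INDEL")),
      not_in_control_panel = c(cnt(s3, "SNV"), cnt(s3, "INDEL")),
      not_in_dbsnp = c(cnt(s4, "SNV"), cnt(s4, "INDEL")),
      consequence = c(cnt(s5, "SNV"), cnt(s5, "INDEL")),
      score_and_gene = c(nrow(s6_snv), nrow(s6_indel)),
      stringsAsFactors = FALSE
    )
  }
  per_sample <- do.call(rbind, per_sample)
  per_family <- do.call(rbind, per_family)
  rownames(per_sample) <- rownames(per_family) <- NULL

  mk_funnel <- function(vt_class, col) {
    ps <- data.frame(family_id = per_sample$family_id,
                     member_id = per_sample$member_id,
                     count = per_sample[[col]], stringsAsFactors = FALSE)
    pf <- per_family[per_family$vtype == vt_class,
                     c("family_id", .stage_labels[-1]), drop = FALSE]
    summarize_funnel(ps, pf, stage_labels = .stage_labels)
  }
  structure(list(
    survivors = survivors,
    funnel_snv = mk_funnel("SNV", "snv"),
    funnel_indel = mk_funnel("INDEL", "indel"),
    per_sample_detected = per_sample,
    per_family_counts = per_family
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result> ", length(x$survivors), " families; survivors: ",
      sum(vapply(x$survivors, nrow, 0L)), " variants (",
      sum(vapply(x$survivors, function(v) sum(v$vtype == "SNV"), 0L)), " SNV, ",
      sum(vapply(x$survivors, function(v) sum(v$vtype == "INDEL"), 0L)),
      " INDEL)\n\nSNV funnel:\n", sep = "")
  print(x$funnel_snv)
  cat("\nINDEL funnel:\n")
  print(x$funnel_indel)
  invisible(x)
}
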