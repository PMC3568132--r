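# Shared fixtures and independent oracles used across test files.

# small variant table builder with sensible defaults
make_vt <- function(n = 1, chrom = "c1", pos = seq_len(n) * 100L,
                    ref = "A", alt = "G", vtype = NULL, zygosity = "het",
                    depth_ref = 10L, depth_alt = 10L,
                    phred_ref = 30, phred_alt = 30, snp_quality = 50,
                    consequence = "nonsynonymous", gene = "G0001",
                    db_flags = "") {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   zygosity = zygosity, depth_ref = depth_ref,
                   depth_alt = depth_alt, phred_ref = phred_ref,
                   phred_alt = phred_alt, snp_quality = snp_quality,
                   consequence = consequence, gene = gene,
                   db_flags = db_flags, stringsAsFactors = FALSE)
  if (!is.null(vtype)) df$vtype <- vtype
  variant_table(df)
}

# scaled-down synthetic configuration for fast, repeated cohort generation
small_synth_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    n_families = 2L,
    members_per_family = c(1L, 2L),
    snv_per_sample = c(60L, 90L),
    indel_per_sample = c(40L, 70L),
    gene_pool_size = 200L,
    read_model = list(n_reads = 200L, read_len = 78L, n_rate = 0.02,
                      poly_frac = 0.10, poly_base = "A")
  )
  do.call(synth_config, utils::modifyList(args, list(...), keep.null = TRUE))
}

# ---------------------------------------------------------------------------
# Independent cascade oracle: single-pass per-variant predicate evaluation,
# written with none of the package's stage filters.
oracle_cascade_keys <- function(cohort, control_sites, known_sites, config) {
  sets <- cohort$variant_sets
  idx <- sets[[config$index_member]]
  other_keys <- NULL
  if (length(sets) > 1) {
    others <- sets[-config$index_member]
    other_keys <- lapply(others, function(s)
      paste(s$chrom, s$pos, s$ref, s$alt, sep = ":"))
  }
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    v <- idx[i, ]
    key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    if (v$vtype == "SNV" && config$het_only && v$zygosity != "het") next
    if (!is.null(other_keys) &&
        !all(vapply(other_keys, function(k) key %in% k, TRUE))) next
    if (key %in% control_sites$keys) next
    if (key %in% known_sites$keys) next
    bl <- if (v$vtype == "SNV") config$consequence_blacklist_snv
          else config$consequence_blacklist_indel
    if (v$consequence %in% bl) next
    if (v$vtype == "SNV") {
      if (is.na(v$depth_ref) || v$depth_ref == 0) next
      if (is.na(v$phred_ref) || v$phred_ref == 0) next
      ds <- 100 * v$depth_alt / v$depth_ref
      qs <- 100 * v$phred_alt / v$phred_ref
      if (is.na(ds) || is.na(qs)) next
      if (ds < config$snp_score_low || ds > config$snp_score_high) next
      if (qs < config$snp_score_low || qs > config$snp_score_high) next
    } else {
      if (is.na(v$depth_ref) || v$depth_ref == 0) next
      ds <- 100 * v$depth_alt / v$depth_ref
      if (!(ds < config$indel_ds_max)) next
      if (is.na(v$phred_alt) || !(v$phred_alt > config$indel_phred_min)) next
      if (is.na(v$snp_quality) || !(v$snp_quality > config$indel_snpq_min)) next
      if (is.na(v$depth_alt) || v$depth_ref < config$indel_min_reads_each ||
          v$depth_alt < config$indel_min_reads_each) next
    }
    if (!is.null(config$gene_allowlist) &&
        !(v$gene %in% config$gene_allowlist)) next
    keep[i] <- TRUE
  }
  sort(paste(idx$chrom, idx$pos, idx$ref, idx$alt, sep = ":")[keep])
}

# ---------------------------------------------------------------------------
# Independent Fisher oracle: exhaustive enumeration over all tables with the
# observed margins, probabilities straight from binomial coefficients.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  N <- m + n
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
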