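# Synthetic-data generators.
#
# The generators emulate the statistical structure each pipeline stage
# assumes — raw reads with uncalled-base and mono-base contamination,
# per-sample heterozygous variant sets at exome scale with within-family
# sharing and database-membership structure, and case-control carrier
# cohorts — together with generation-time truth records that serve as
# independent oracles for the filters. All generators are pure functions
# of their configuration (seed included): the caller's RNG state is left
# untouched.

#' Synthetic-data configuration
#'
#' Defaults describe a seven-family exome study: three families with one
#' sequenced member and four with two, per-sample heterozygous SNV
#' counts drawn uniformly in 26,500–30,700 and INDEL counts in
#' 25,200–36,200 (the magnitude of real exome call sets after
#' heterozygote selection), about a third of a family's variants shared
#' between its two sequenced members, 87% of background variants present
#' in the known-variant database and 70% in the control panel.
#'
#' @param seed integer seed; identical configs give identical outputs.
#' @param n_families number of families.
#' @param members_per_family vector (recycled to `n_families`) of 1s and
#'   2s: sequenced members per family.
#' @param snv_per_sample,indel_per_sample `c(min, max)` ranges for
#'   per-sample background counts.
#' @param share_frac fraction of a two-member family's variants shared
#'   by both members.
#' @param frac_in_dbsnp,frac_in_control_panel probabilities that a
#'   background variant belongs to the known-variant database / control
#'   panel (drawn independently per variant).
#' @param consequence_probs_snv,consequence_probs_indel named probability
#'   vectors over consequence labels.
#' @param score_model list with per-type elements `snv` and `indel`,
#'   each `list(frac_noise, good_ds, good_qs)`: well-supported calls draw
#'   DS/QS uniformly inside the `good_*` windows; noise calls draw a
#'   low/high score mixture and thin read support, emulating artifact
#'   calls (much commoner among INDELs).
#' @param gene_pool_size number of background gene symbols.
#' @param allowlist_genes cancer-plausible gene symbols available for
#'   the gene filter and the implant.
#' @param implant `NULL`, or `list(gene, consequence, vtype, families)`
#'   describing one causal variant per designated family (`"all"` or a
#'   vector of family indices), inserted in every sequenced member with
#'   filter-passing evidence and no database membership.
#' @param read_model `list(n_reads, read_len, n_rate, poly_frac,
#'   poly_base)` for [gen_reads()].
#' @param casecontrol `list(n_cases, n_controls, carriers_cases,
#'   carriers_controls)` for [gen_case_control()].
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_families = 7L,
                         members_per_family = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
                         snv_per_sample = c(26500L, 30700L),
                         indel_per_sample = c(25200L, 36200L),
                         share_frac = 0.32,
                         frac_in_dbsnp = 0.87,
                         frac_in_control_panel = 0.70,
                         consequence_probs_snv = c(
                           intronic = 0.46, intergenic = 0.18,
                           synonymous = 0.12, nonsynonymous = 0.17,
                           UTR3 = 0.04, splicing = 0.02, stopgain = 0.01),
                         consequence_probs_indel = c(
                           intronic = 0.55, intergenic = 0.20, UTR3 = 0.05,
                           frameshift = 0.15, splicing = 0.05),
                         score_model = list(
                           snv = list(frac_noise = 0.10,
                                      good_ds = c(40, 160), good_qs = c(40, 160)),
                           indel = list(frac_noise = 0.70,
                                        good_ds = c(40, 130), good_qs = c(40, 160))),
                         gene_pool_size = 5000L,
                         allowlist_genes = c("FANCM", "CHEK2", "PALB2", "ATM",
                                             "BRIP1", "RAD51C"),
                         implant = list(gene = "FANCM",
                                        consequence = "stopgain",
                                        vtype = "SNV", families = "all"),
                         read_model = list(n_reads = 2000L, read_len = 78L,
                                           n_rate = 0.02, poly_frac = 0.05,
                                           poly_base = "A"),
                         casecontrol = list(n_cases = 3409L, n_controls = 3896L,
                                            carriers_cases = 10L,
                                            carriers_controls = 5L)) {
  members_per_family <- rep_len(as.integer(members_per_family), n_families)
  stopifnot(all(members_per_family %in% 1:2),
            share_frac >= 0, share_frac <= 1,
            frac_in_dbsnp >= 0, frac_in_dbsnp <= 1,
            frac_in_control_panel >= 0, frac_in_control_panel <= 1)
  structure(list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    members_per_family = members_per_family,
    snv_per_sample = snv_per_sample, indel_per_sample = indel_per_sample,
    share_frac = share_frac, frac_in_dbsnp = frac_in_dbsnp,
    frac_in_control_panel = frac_in_control_panel,
    consequence_probs_snv = consequence_probs_snv / sum(consequence_probs_snv),
    consequence_probs_indel = consequence_probs_indel / sum(consequence_probs_indel),
    score_model = score_model, gene_pool_size = as.integer(gene_pool_size),
    allowlist_genes = allowlist_genes, implant = implant,
    read_model = read_model, casecontrol = casecontrol
  ), class = "synth_config")
}

# ---------------------------------------------------------------------------
# Reads

#' Generate synthetic raw reads with truth
#'
#' Reads are uniform random sequence except that a configured fraction
#' are mono-base contamination and every position is independently
#' replaced by `N` at the configured rate. The truth table evaluates the
#' two read-QC rules directly on the base matrix at generation time, so
#' it serves as an independent oracle for [filter_reads()].
#'
#' @param config a [synth_config()].
#' @return List with `reads` (data frame `read_id`, `bases`, `quals`) and
#'   `truth` (data frame `read_id`, `n_count`, `max_frac`, `fail_n`,
#'   `fail_frac`; failures at the default thresholds 5 and 0.70).
#' @export
gen_reads <- function(config = synth_config()) {
  rm_ <- config$read_model
  with_seed(config$seed + 101L, {
    n <- rm_$n_reads; len <- rm_$read_len
    mat <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                  nrow = n, ncol = len)
    n_poly <- round(rm_$poly_frac * n)
    if (n_poly > 0) {
      poly_rows <- sample(n, n_poly)
      mat[poly_rows, ] <- rm_$poly_base
    }
    nmask <- matrix(runif(n * len) < rm_$n_rate, nrow = n)
    mat[nmask] <- "N"
    bases <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    quals <- vapply(seq_len(n), function(i)
      rawToChar(as.raw(sample(35:73, len, replace = TRUE))), "")
    n_count <- rowSums(mat == "N")
    top <- pmax(rowSums(mat == "A"), rowSums(mat == "C"),
                rowSums(mat == "G"), rowSums(mat == "T"))
    reads <- data.frame(read_id = sprintf("read_%05d", seq_len(n)),
                        bases = bases, quals = quals, stringsAsFactors = FALSE)
    truth <- data.frame(read_id = reads$read_id,
                        n_count = n_count, max_frac = top / len,
                        fail_n = n_count > 5L, fail_frac = top / len > 0.70,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Family cohorts

# draw evidence fields for n variants of one class mix
.draw_evidence <- function(n, model) {
  if (n == 0) {
    return(data.frame(depth_ref = integer(), depth_alt = integer(),
                      phred_ref = numeric(), phred_alt = numeric(),
                      snp_quality = numeric(), is_noise = logical()))
  }
  noise <- runif(n) < model$frac_noise
  ds <- numeric(n); qs <- numeric(n)
  g <- !noise
  ds[g] <- runif(sum(g), model$good_ds[1], model$good_ds[2])
  qs[g] <- runif(sum(g), model$good_qs[1], model$good_qs[2])
  # artifact calls: scores far below or far above the plausible window
  lowside <- runif(sum(noise)) < 0.5
  ds[noise] <- ifelse(lowside, runif(sum(noise), 0, 15),
                      runif(sum(noise), 220, 600))
  qs[noise] <- ifelse(runif(sum(noise)) < 0.5, runif(sum(noise), 0, 15),
                      runif(sum(noise), 220, 600))
  depth_ref <- integer(n)
  depth_ref[g] <- rpois(sum(g), 16) + 4L
  depth_ref[noise] <- rpois(sum(noise), 3)
  depth_alt <- as.integer(round(ds / 100 * depth_ref))
  phred_ref <- round(depth_ref * 3 + runif(n, 0, 10), 1)
  phred_alt <- round(qs / 100 * phred_ref, 1)
  snp_quality <- numeric(n)
  snp_quality[g] <- round(runif(sum(g), 30, 200), 1)
  snp_quality[noise] <- round(runif(sum(noise), 0, 60), 1)
  data.frame(depth_ref = depth_ref, depth_alt = depth_alt,
             phred_ref = phred_ref, phred_alt = phred_alt,
             snp_quality = snp_quality, is_noise = noise)
}

.random_alleles <- function(n, vtype) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  if (vtype == "SNV") {
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    return(data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE))
  }
  ins <- runif(n) < 0.5
  tail_ <- vapply(sample(1:3, n, replace = TRUE), function(k)
    paste(sample(bases, k, replace = TRUE), collapse = ""), "")
  data.frame(ref = ifelse(ins, ref, paste0(ref, tail_)),
             alt = ifelse(ins, paste0(ref, tail_), ref),
             stringsAsFactors = FALSE)
}

#' Generate synthetic family cohorts with exclusion sets and truth
#'
#' Draws per-sample background variant sets on a synthetic coordinate
#' system (chromosomes `c1`–`c22`), shares a configured fraction of each
#' two-member family's variants between both members (shared keys are
#' copied with independently drawn evidence fields), assigns
#' known-database and control-panel membership per variant, and inserts
#' one filter-passing causal variant per designated family. The site
#' sets returned are built from the assigned memberships; the truth
#' record lists the implanted keys.
#'
#' @param config a [synth_config()].
#' @return List with `cohorts` (list of [family_cohort()]),
#'   `control_sites` and `known_sites` ([site_set()]s), and `truth`
#'   (list with `implant_keys`, a named character vector by family).
#' @export
gen_family_cohorts <- function(config = synth_config()) {
  with_seed(config$seed + 202L, {
    chroms <- paste0("c", 1:22)
    gene_pool <- sprintf("G%04d", seq_len(config$gene_pool_size))
    all_db <- character(0); all_panel <- character(0)
    cohorts <- list(); implant_keys <- character(0)

    for (f in seq_len(config$n_families)) {
      fid <- sprintf("F%d", f)
      k <- config$members_per_family[f]
      member_ids <- sprintf("%s_%d", fid, seq_len(k))

      fam_sets <- setNames(vector("list", k), member_ids)
      for (vtype in c("SNV", "INDEL")) {
        rng <- if (vtype == "SNV") config$snv_per_sample else config$indel_per_sample
        model <- if (vtype == "SNV") config$score_model$snv else config$score_model$indel
        cons <- if (vtype == "SNV") config$consequence_probs_snv
                else config$consequence_probs_indel
        counts <- rng[1] + sample.int(rng[2] - rng[1] + 1L, k,
                                      replace = TRUE) - 1L
        n_shared <- if (k == 2) round(config$share_frac * min(counts)) else 0L
        n_total <- n_shared + sum(counts - n_shared)
        sites <- data.frame(
          chrom = sample(chroms, n_total, replace = TRUE),
          pos = sample.int(2e8L, n_total, replace = TRUE))
        sites <- cbind(sites, .random_alleles(n_total, vtype))
        key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
        dup <- duplicated(key)
        sites <- sites[!dup, , drop = FALSE]; key <- key[!dup]
        n_total <- nrow(sites)
        n_shared <- min(n_shared, n_total)
        sites$consequence <- sample(names(cons), n_total, replace = TRUE,
                                    prob = cons)
        use_allow <- runif(n_total) < 0.01
        sites$gene <- ifelse(use_allow,
                             sample(config$allowlist_genes, n_total, replace = TRUE),
                             sample(gene_pool, n_total, replace = TRUE))
        sites$in_db <- runif(n_total) < config$frac_in_dbsnp
        sites$in_panel <- runif(n_total) < config$frac_in_control_panel
        all_db <- c(all_db, key[sites$in_db])
        all_panel <- c(all_panel, key[sites$in_panel])

        shared_idx <- if (n_shared > 0) seq_len(n_shared) else integer(0)
        private_pool <- setdiff(seq_len(n_total), shared_idx)
        offset <- 0L
        for (m in seq_len(k)) {
          n_priv <- min(counts[m] - n_shared, length(private_pool) - offset)
          idx <- c(shared_idx, private_pool[seq_len(n_priv) + offset])
          offset <- offset + n_priv
          sv <- sites[idx, , drop = FALSE]
          ev <- .draw_evidence(nrow(sv), model)
          vt <- data.frame(
            chrom = sv$chrom, pos = sv$pos, ref = sv$ref, alt = sv$alt,
            vtype = vtype,
            zygosity = "het",
            ev[, c("depth_ref", "depth_alt", "phred_ref", "phred_alt",
                   "snp_quality")],
            consequence = sv$consequence, gene = sv$gene,
            db_flags = paste0(ifelse(sv$in_db, "dbsnp", ""),
                              ifelse(sv$in_db & sv$in_panel, ",", ""),
                              ifelse(sv$in_panel, "control_panel", "")),
            stringsAsFactors = FALSE)
          fam_sets[[m]] <- rbind(fam_sets[[m]], vt)
        }
      }

      do_implant <- !is.null(config$implant) &&
        (identical(config$implant$families, "all") ||
           f %in% config$implant$families)
      if (do_implant) {
        imp <- config$implant
        ikey_row <- data.frame(
          chrom = "c17", pos = 41000000L + f, ref = "C", alt = "T",
          vtype = imp$vtype, zygosity = "het",
          depth_ref = 12L, depth_alt = 10L,
          phred_ref = 40, phred_alt = 40, snp_quality = 60,
          consequence = imp$consequence, gene = imp$gene, db_flags = "",
          stringsAsFactors = FALSE)
        for (m in seq_len(k)) fam_sets[[m]] <- rbind(fam_sets[[m]], ikey_row)
        implant_keys[fid] <- variant_key(ikey_row)
      }

      members <- data.frame(
        member_id = c(member_ids, sprintf("%s_rel%d", fid, 1:3)),
        family_id = fid,
        affected = TRUE,
        diagnosis_age = round(runif(k + 3, 32, 58)),
        sequenced = c(rep(TRUE, k), rep(FALSE, 3)),
        available = TRUE, stringsAsFactors = FALSE)
      fam_sets <- lapply(fam_sets, variant_table)
      cohorts[[fid]] <- family_cohort(fid, members, fam_sets)
    }

    list(cohorts = cohorts,
         control_sites = site_set(unique(all_panel), "control_panel"),
         known_sites = site_set(unique(all_db), "dbsnp"),
         truth = list(implant_keys = implant_keys))
  })
}

# ---------------------------------------------------------------------------
# Case-control cohorts

#' Generate a case-control genotype cohort with fixed carrier counts
#'
#' Places exactly the configured number of heterozygous carriers in each
#' arm (hypergeometric placement: carrier individuals are a uniform
#' random subset), so [allele_table()] on the generated cohort
#' reproduces the configured counts by construction.
#'
#' @param config a [synth_config()].
#' @return List with `genotypes` (data frame `sample_id`, `group`,
#'   `carrier`) and `counts` (the realized carrier/sample counts).
#' @export
gen_case_control <- function(config = synth_config()) {
  cc <- config$casecontrol
  stopifnot(cc$carriers_cases <= cc$n_cases,
            cc$carriers_controls <= cc$n_controls)
  with_seed(config$seed + 303L, {
    case_carrier <- logical(cc$n_cases)
    case_carrier[sample(cc$n_cases, cc$carriers_cases)] <- TRUE
    ctrl_carrier <- logical(cc$n_controls)
    ctrl_carrier[sample(cc$n_controls, cc$carriers_controls)] <- TRUE
    genotypes <- data.frame(
      sample_id = c(sprintf("case_%05d", seq_len(cc$n_cases)),
                    sprintf("ctrl_%05d", seq_len(cc$n_controls))),
      group = rep(c("case", "control"), c(cc$n_cases, cc$n_controls)),
      carrier = c(case_carrier, ctrl_carrier),
      stringsAsFactors = FALSE)
    list(genotypes = genotypes,
         counts = list(n_cases = cc$n_cases, n_controls = cc$n_controls,
                       carriers_cases = sum(case_carrier),
                       carriers_controls = sum(ctrl_carrier)))
  })
}
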