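test_that("depth and quality scores are percent ratios, undefined at zero denominator", {
  expect_equal(depth_score(10, 10), 100)
  expect_equal(depth_score(21, 10), 210)
  expect_true(is.na(depth_score(3, 0)))
  expect_equal(quality_score(30, 30), 100)
  expect_equal(quality_score(60, 30), 200)
  expect_true(is.na(quality_score(15, 0)))
  expect_equal(depth_score(c(5, 0, NA), c(10, 0, 10)), c(50, NA, NA))
})

test_that("the score orientation switch swaps numerator and denominator", {
  vt <- make_vt(1, depth_ref = 10L, depth_alt = 5L,
                phred_ref = 40, phred_alt = 20)
  expect_equal(variant_scores(vt)$ds, 50)
  cfg <- cascade_config(score_orientation = "ref_over_alt")
  expect_equal(variant_scores(vt, cfg)$ds, 200)
  expect_equal(variant_scores(vt, cfg)$qs, 200)
})

test_that("family sharing keeps key-matched variants, identity for singletons", {
  members <- data.frame(member_id = c("m1", "m2"), family_id = "F1",
                        affected = TRUE, diagnosis_age = 45,
                        sequenced = TRUE, available = TRUE)
  vt1 <- make_vt(3, pos = c(100L, 200L, 300L))
  vt2 <- make_vt(2, pos = c(100L, 300L), depth_ref = 99L)  # differing evidence
  co <- family_cohort("F1", members, list(m1 = vt1, m2 = vt2))
  sh <- shared_in_family(co)
  expect_equal(sh$pos, c(100L, 300L))
  expect_equal(sh$depth_ref, c(10L, 10L))  # evidence from index member m1

  sh2 <- shared_in_family(co, index_member = 2L)
  expect_equal(sh2$depth_ref, c(99L, 99L))

  solo <- family_cohort("F2", members[1, ], list(m1 = vt1))
  expect_equal(shared_in_family(solo), vt1)
})

test_that("site exclusion is allele-aware and identity on empty sets", {
  vt <- make_vt(3, pos = c(1L, 2L, 3L), alt = c("G", "G", "G"))
  ss <- site_set(c("c1:1:A:G", "c1:2:A:T"), "panel")
  out <- exclude_sites(vt, ss)
  expect_equal(out$pos, c(2L, 3L))  # pos 2 kept: different alt allele in set
  expect_equal(exclude_sites(vt, site_set(character(), "empty")), vt)
})

test_that("consequence filtering uses per-type blacklists", {
  vt <- make_vt(6, ref = c("A", "A", "A", "A", "AT", "AT"),
                alt = c("G", "G", "G", "G", "A", "A"),
                consequence = c("synonymous", "UTR3", "intronic", "stopgain",
                                "intronic", "synonymous"))
  out <- consequence_filter(vt)
  # SNVs: synonymous and intronic dropped, UTR3 and stopgain kept;
  # INDELs: intronic dropped, synonymous-labelled kept (not blacklisted)
  expect_equal(out$consequence, c("UTR3", "stopgain", "synonymous"))
  expect_equal(out$vtype, c("SNV", "SNV", "INDEL"))

  vt$consequence[1] <- NA
  expect_error(consequence_filter(vt), "consequence")
})

test_that("SNV score window is inclusive and fails undefined scores", {
  vt <- make_vt(4,
                depth_ref = c(10L, 10L, 10L, 0L),
                depth_alt = c(2L, 21L, 1L, 5L),       # DS 20, 210, 10, NA
                phred_ref = c(10, 10, 10, 10),
                phred_alt = c(21, 2, 10, 10))         # QS 210, 20, 100, 100
  out <- score_filter_snv(vt)
  expect_equal(out$pos, vt$pos[1:2])
  low <- make_vt(1, depth_ref = 100L, depth_alt = 19L, phred_ref = 10,
                 phred_alt = 10)                      # DS 19, below window
  expect_equal(nrow(score_filter_snv(low)), 0L)
})

test_that("INDEL criteria: DS strictly below 140, qualities strictly above 10, 3 reads each", {
  base <- list(ref = "AT", alt = "A", depth_ref = 3L, depth_alt = 3L,
               phred_ref = 30, phred_alt = 11, snp_quality = 11)
  ok <- do.call(make_vt, c(list(n = 1), base))
  expect_equal(nrow(score_filter_indel(ok)), 1L)

  few_alt <- do.call(make_vt, c(list(n = 1), modifyList(base, list(depth_alt = 2L))))
  expect_equal(nrow(score_filter_indel(few_alt)), 0L)

  ds140 <- do.call(make_vt, c(list(n = 1), modifyList(base, list(
    depth_ref = 10L, depth_alt = 14L))))
  expect_equal(nrow(score_filter_indel(ds140)), 0L)

  phred10 <- do.call(make_vt, c(list(n = 1), modifyList(base, list(phred_alt = 10))))
  expect_equal(nrow(score_filter_indel(phred10)), 0L)

  snpq10 <- do.call(make_vt, c(list(n = 1), modifyList(base, list(snp_quality = 10))))
  expect_equal(nrow(score_filter_indel(snpq10)), 0L)
})

test_that("gene filtering honours the allowlist and the disabled state", {
  vt <- make_vt(2, gene = c("FANCM", "G0042"))
  expect_equal(gene_function_filter(vt, c("FANCM", "CHEK2"))$gene, "FANCM")
  expect_equal(gene_function_filter(vt, NULL), vt)
})

test_that("the cascade matches a per-variant brute-force oracle on random cohorts", {
  cfg <- cascade_config(gene_allowlist = NULL)
  for (seed in 1:30) {
    sim <- gen_family_cohorts(small_synth_config(seed = seed))
    res <- run_cascade(sim$cohorts, sim$control_sites, sim$known_sites, cfg)
    for (fid in names(sim$cohorts)) {
      got <- sort(variant_key(res$survivors[[fid]]))
      want <- oracle_cascade_keys(sim$cohorts[[fid]], sim$control_sites,
                                  sim$known_sites, cfg)
      expect_identical(got, want)
    }
  }
})

test_that("implanted causal variants survive unless placed in the known set", {
  sim <- gen_family_cohorts(small_synth_config(seed = 11L))
  cfg <- cascade_config()
  res <- run_cascade(sim$cohorts, sim$control_sites, sim$known_sites, cfg)
  for (fid in names(sim$truth$implant_keys)) {
    expect_true(sim$truth$implant_keys[[fid]] %in%
                  variant_key(res$survivors[[fid]]))
  }
  # adding the implant keys to the known-variant set removes them
  known2 <- site_set(c(sim$known_sites$keys, unname(sim$truth$implant_keys)),
                     "dbsnp+implants")
  res2 <- run_cascade(sim$cohorts, sim$control_sites, known2, cfg)
  for (fid in names(sim$truth$implant_keys)) {
    expect_false(sim$truth$implant_keys[[fid]] %in%
                   variant_key(res2$survivors[[fid]]))
  }
})

test_that("stage outputs are nested subsets and funnel counts weakly decrease", {
  sim <- gen_family_cohorts(small_synth_config(seed = 5L))
  res <- run_cascade(sim$cohorts, sim$control_sites, sim$known_sites,
                     cascade_config())
  for (fun in list(res$funnel_snv, res$funnel_indel)) {
    vals <- as.matrix(fun$per_family[, -1])
    expect_true(all(apply(vals, 1, function(r) all(diff(r) <= 0))))
    expect_true(all(diff(fun$percentages) <= 0))
    expect_equal(unname(fun$percentages[1]), 100)
  }
})

test_that("exclusion and consequence stages commute", {
  sim <- gen_family_cohorts(small_synth_config(seed = 9L))
  co <- sim$cohorts[[2]]
  vt <- shared_in_family(co)
  cfg <- cascade_config()
  a <- exclude_sites(exclude_sites(vt, sim$control_sites), sim$known_sites)
  b <- exclude_sites(exclude_sites(vt, sim$known_sites), sim$control_sites)
  expect_equal(a, b)
  x <- consequence_filter(exclude_sites(vt, sim$known_sites), cfg)
  y <- exclude_sites(consequence_filter(vt, cfg), sim$known_sites)
  expect_equal(x[order(variant_key(x)), ], y[order(variant_key(y)), ],
               ignore_attr = TRUE)
})

test_that("empty variant sets give all-zero stage counts", {
  members <- data.frame(member_id = "m1", family_id = "F1", affected = TRUE,
                        diagnosis_age = 50, sequenced = TRUE, available = TRUE)
  empty <- variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character()))
  co <- family_cohort("F1", members, list(m1 = empty))
  res <- run_cascade(list(co), site_set(label = "p"), site_set(label = "k"),
                     cascade_config())
  expect_true(all(as.matrix(res$funnel_snv$per_family[, -1]) == 0))
  expect_true(all(as.matrix(res$funnel_indel$per_family[, -1]) == 0))
  expect_equal(nrow(res$survivors$F1), 0L)
})

test_that("heterozygote selection drops homozygous SNVs but keeps all INDELs", {
  members <- data.frame(member_id = "m1", family_id = "F1", affected = TRUE,
                        diagnosis_age = 50, sequenced = TRUE, available = TRUE)
  vt <- make_vt(3, ref = c("A", "A", "AT"), alt = c("G", "G", "A"),
                pos = c(1L, 2L, 3L), zygosity = c("het", "hom", "hom"))
  co <- family_cohort("F1", members, list(m1 = vt))
  res <- run_cascade(list(co), site_set(label = "p"), site_set(label = "k"),
                     cascade_config())
  det <- res$per_sample_detected
  expect_equal(det$snv, 1L)
  expect_equal(det$indel, 1L)
})

test_that("funnel summaries follow the documented aggregation on a toy example", {
  per_sample <- data.frame(family_id = c("A", "A", "B"),
                           member_id = c("a1", "a2", "b1"),
                           count = c(100, 120, 80))
  per_family <- data.frame(family_id = c("A", "B"),
                           shared = c(40, 80), novel = c(10, 20))
  ft <- summarize_funnel(per_sample, per_family)
  # family A stage1 = 110, B = 80 -> average (110+80)/2 = 95
  expect_equal(unname(ft$averages), c(95, 60, 15))
  expect_equal(unname(ft$percentages),
               c(100, round(60 / 95 * 100, 2), round(15 / 95 * 100, 2)))

  one <- summarize_funnel(data.frame(family_id = "A", member_id = "a1",
                                     count = 42),
                          data.frame(family_id = "A", s2 = 42, s3 = 42))
  expect_true(all(one$percentages == 100))
  expect_true(all(one$averages == 42))
})
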