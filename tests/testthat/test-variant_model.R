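test_that("variant tables round-trip through the VCF dialect", {
  vt <- make_vt(3, pos = c(100L, 200L, 300L),
                ref = c("A", "C", "AT"), alt = c("G", "T", "A"),
                zygosity = c("het", "hom", "het"),
                depth_ref = c(10L, 7L, NA), depth_alt = c(8L, 7L, NA),
                phred_ref = c(30, 21.5, NA), phred_alt = c(60, 21.5, NA),
                snp_quality = c(99, 50.5, NA),
                consequence = c("nonsynonymous", "synonymous", "frameshift"),
                gene = c("FANCM", "", "G0007"),
                db_flags = c("dbsnp,control_panel", "dbsnp", ""))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(vt, path)
  back <- load_variant_table(path)
  expect_equal(back, vt)
})

test_that("variant tables round-trip through the TSV fallback", {
  vt <- make_vt(2, ref = c("A", "G"), alt = c("T", "GTC"),
                depth_ref = c(5L, NA), snp_quality = c(10, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(vt, path)
  expect_equal(load_variant_table(path), vt)
})

test_that("multi-allelic VCF records split into one call per alt allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=PQ,Number=R,Type=Float,Description=\"pq\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("c2", "500", ".", "G", "A,T", "77", ".", "VT=SNV;CSQ=nonsynonymous",
          "GT:AD:PQ", "0/1:10,8,3:30,24,9", sep = "\t")
  ), path)
  vt <- load_variant_table(path)
  expect_equal(nrow(vt), 2L)
  expect_equal(vt$chrom, c("c2", "c2"))
  expect_equal(vt$pos, c(500L, 500L))
  expect_equal(vt$ref, c("G", "G"))
  expect_equal(vt$alt, c("A", "T"))
  expect_equal(vt$depth_ref, c(10L, 10L))
  expect_equal(vt$depth_alt, c(8L, 3L))
  expect_equal(vt$phred_alt, c(24, 9))
  expect_equal(vt$snp_quality, c(77, 77))
})

test_that("a FORMAT file lacking the depth field is a field error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("c1", "10", ".", "A", "G", "50", ".", ".", "GT", "0/1", sep = "\t")
  ), path)
  expect_error(load_variant_table(path), "AD")
})

test_that("empty inputs yield empty variant tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  file.create(path)
  vt <- load_variant_table(path)
  expect_equal(nrow(vt), 0L)
  expect_true(all(c("chrom", "pos", "ref", "alt") %in% names(vt)))
})

test_that("variant identity is keyed by (chrom, pos, ref, alt)", {
  a <- make_vt(1, chrom = "c3", pos = 77L, ref = "A", alt = "G",
               depth_ref = 5L, gene = "X")
  b <- make_vt(1, chrom = "c3", pos = 77L, ref = "A", alt = "G",
               depth_ref = 50L, gene = "Y")
  c_ <- make_vt(1, chrom = "c3", pos = 77L, ref = "A", alt = "T")
  expect_identical(variant_key(a), variant_key(b))
  expect_false(variant_key(a) == variant_key(c_))
})

test_that("variant_table validates coordinates and allele shapes", {
  expect_error(variant_table(data.frame(chrom = "c1", pos = 0, ref = "A",
                                        alt = "G")), "1-based")
  expect_error(variant_table(data.frame(chrom = "c1", pos = 5, ref = "AT",
                                        alt = "G", vtype = "SNV")),
               "single-base")
  expect_error(variant_table(data.frame(chrom = "c1", pos = 5, ref = "A",
                                        alt = "G", depth_ref = -1)), ">= 0")
})

test_that("pedigree loading groups members into family cohorts", {
  ped <- data.frame(
    family_id = c("49", "694", "531", rep(c("2887", "3311", "RUL036",
                                            "RUL153"), each = 2)),
    member_id = c("07S240", "DAD_1", "I_1408", "F2887_13", "F2887_24",
                  "F3311_5", "F3311_43", "RUL036_2", "RUL036_7",
                  "RUL153_2", "RUL153_3"),
    affected = 1L, diagnosis_age = 45L, sequenced = 1L, available = 1L,
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cohorts <- load_pedigree(path)
  expect_length(cohorts, 7L)
  expect_equal(sum(vapply(cohorts, function(co) sum(co$members$sequenced), 0L)),
               11L)
  expect_equal(sum(vapply(cohorts, function(co)
    sum(co$members$sequenced) == 1, TRUE)), 3L)
})

test_that("pedigree integrity violations are rejected", {
  base <- data.frame(family_id = "F1", member_id = c("a", "b"),
                     affected = 1L, diagnosis_age = 40L,
                     sequenced = 1L, available = 1L, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")

  dup <- rbind(base, base[1, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_pedigree(path), "duplicate")

  two_fams <- base; two_fams$family_id <- c("F1", "F2")
  two_fams <- rbind(two_fams,
                    data.frame(family_id = "F2", member_id = "a",
                               affected = 1L, diagnosis_age = 40L,
                               sequenced = 1L, available = 1L))
  write.table(two_fams, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_pedigree(path), "more than one family")

  age_unaffected <- base; age_unaffected$affected <- c(1L, 0L)
  write.table(age_unaffected, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_pedigree(path), "diagnosis_age")

  three_seq <- rbind(base, data.frame(family_id = "F1", member_id = "c",
                                      affected = 1L, diagnosis_age = 40L,
                                      sequenced = 1L, available = 1L))
  write.table(three_seq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(cohorts <- load_pedigree(path), "3 sequenced")
  expect_length(cohorts, 1L)

  none_seq <- base; none_seq$sequenced <- 0L
  write.table(none_seq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(expect_length(load_pedigree(path), 0L), "no sequenced")
})

test_that("site sets deduplicate and key by allele", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t100\tA\tG", "c1\t100\tA\tG", "c1\t100\tA\tT"), path)
  ss <- load_site_set(path, "demo")
  expect_equal(length(ss), 2L)
  expect_setequal(ss$keys, c("c1:100:A:G", "c1:100:A:T"))

  writeLines(c("c1\t100\tA\tG", "garbage line"), path)
  expect_error(load_site_set(path), "line 2")

  file.create(path2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(length(load_site_set(path2)), 0L)
})

test_that("site sets round-trip through their TSV form", {
  ss <- site_set(c("c1:5:A:G", "c22:199999999:AT:A"), "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_set(ss, path)
  expect_setequal(load_site_set(path, "rt")$keys, ss$keys)
})
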