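test_that("expression matrices round-trip through TSV", {
  m <- matrix(c(-2.5, 0.25, 3, 1e-3, 7.125, -0.5), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  expect_equal(read_expression(path), m)

  m1 <- matrix(-2.5, 1, 1, dimnames = list("g1", "s1"))
  write_expression(m1, path)
  expect_equal(read_expression(path), m1)
})

test_that("malformed expression files are rejected with the culprit named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "gX\t1.0", "gX\t2.0"), path)
  expect_error(read_expression(path), "gX")
  writeLines(c("gene\ts1", "gA\tnot_a_number"), path)
  expect_error(read_expression(path), "non-numeric")
})

test_that("the paired-cohort fixture has 22 patients over 44 samples", {
  ann <- read_annotation(neostrat_fixture("table2_annotation.tsv"))
  expect_equal(nrow(ann), 44L)
  expect_equal(length(unique(ann$patient_id)), 22L)
  expect_true(all(table(ann$patient_id) == 2L))
  expect_true(all(ann$purity > 0 & ann$purity <= 1))
})

test_that("annotation bounds and missing tokens are enforced", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubtype\tnri", "s1\tTN\t1.2"), path)
  expect_error(read_annotation(path), "nri")
  writeLines(c("sample_id\tsubtype\tnri\tpcr", "s1\tTN\tNA\tNA"), path)
  ann <- read_annotation(path)
  expect_true(is.na(ann$nri) && is.na(ann$pcr) && is.na(ann$purity))
  writeLines(c("sample_id\tsubtype", "s1\tHER2"), path)
  expect_error(read_annotation(path), "subtype")
})

test_that("two-sample VCFs are parsed into per-sample VAFs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPRE\tPOST",
    "chr1\t100\t.\tA\tT\t.\tPASS\tGENE=TP53;EFFECT=coding\tGT:AD:DP\t./.:10,10:20\t./.:20,0:20",
    "chr1\t200\t.\tC\tG\t.\tPASS\tGENE=APC;EFFECT=coding\tGT:AD:DP\t./.:5,5:10\t./.:0,0:0"
  ), path)
  v <- read_paired_vcf(path)
  expect_equal(v$vaf_pre, c(0.5, 0.5))
  expect_equal(v$vaf_post[1], 0.0)
  expect_true(is.na(v$vaf_post[2]))  # DP = 0 means VAF missing
  expect_equal(v$gene, c("TP53", "APC"))
})

test_that("simulated variants survive a VCF round trip", {
  g <- simulate_paired_genomics(sim_config(n_probes = 400, n_chrom = 2,
                                           seed = 17))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_paired_vcf(g$variants, path)
  v <- read_paired_vcf(path)
  expect_equal(v$vaf_pre, g$variants$vaf_pre, tolerance = 1e-12)
  expect_equal(v$vaf_post, g$variants$vaf_post, tolerance = 1e-12)
  expect_equal(v$gene, g$variants$gene)
  expect_equal(v$effect_class, g$variants$effect_class)
})

test_that("SEG files round-trip and reject overlapping segments", {
  segs <- data.frame(sample = "d", chrom = c("chr1", "chr1", "chr2"),
                     start = c(1L, 1001L, 1L), end = c(1000L, 2000L, 500L),
                     n_probes = c(10L, 10L, 5L),
                     mean_delta = c(0, -1.25, 0.5),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(segs, path)
  expect_equal(read_seg(path), segs)
  expect_equal(length(readLines(path)), 4L)  # header + 3 data lines

  bad <- segs
  bad$start[2] <- 900L
  expect_error(write_seg(bad, path), "overlap")
})

test_that("cohort summary reproduces the printed pCR percentages", {
  ann <- read_annotation(neostrat_fixture("table1_cohort.tsv"))
  cs <- cohort_summary(ann)
  expect_equal(cs$subtypes$ERpos$n, 200L)
  expect_equal(cs$subtypes$TN$n, 117L)
  expect_equal(cs$subtypes$ERpos$pcr_yes, 7L)
  expect_equal(cs$subtypes$TN$pcr_yes, 46L)
  expect_equal(cs$subtypes$ERpos$pcr_pct, 3.5)
  expect_equal(round(cs$subtypes$TN$pcr_pct, 1), 39.3)
  # denominator switch: determined cases only
  cs2 <- cohort_summary(ann, pcr_denominator = "non_missing")
  expect_equal(cs2$subtypes$ERpos$pcr_pct, 100 * 7 / 190)
  # row order cannot matter
  set.seed(1)
  cs3 <- cohort_summary(ann[sample(nrow(ann)), ])
  expect_equal(cs3$subtypes, cs$subtypes)
})

test_that("an all-missing pCR column reports a missing percentage", {
  ann <- data.frame(sample_id = c("a", "b"), patient_id = c("a", "b"),
                    subtype = "TN", timepoint = "pre", nri = NA,
                    pcr = NA_character_, rfs_time = NA, rfs_event = NA,
                    purity = NA, stringsAsFactors = FALSE)
  cs <- cohort_summary(ann)
  expect_true(is.na(cs$subtypes$TN$pcr_pct))
})

test_that("paired-cohort counts split six TN and sixteen ER+ patients", {
  ann <- read_annotation(neostrat_fixture("table2_annotation.tsv"))
  cs <- cohort_summary(ann)
  expect_equal(cs$paired$TN, 6L)
  expect_equal(cs$paired$ERpos, 16L)
})
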