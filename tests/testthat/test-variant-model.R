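test_that("trim_alleles reduces alleles to parsimony", {
  # already minimal
  expect_equal(
    trim_alleles("chr1", 100, "A", "C"),
    tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "C")
  )
  # right-trim then left-trim, advancing pos per removed leading base
  expect_equal(
    trim_alleles("chr1", 100, "TCGA", "TCA"),
    tibble::tibble(chrom = "chr1", pos = 101L, ref = "CG", alt = "C")
  )
  # anchored deletion stays anchored (alt must keep >= 1 base)
  expect_equal(trim_alleles("chr1", 50, "AAG", "A")$ref, "AAG")
  # vectorized over rows
  out <- trim_alleles("chr1", c(10L, 20L), c("CT", "GGA"), c("CA", "GCA"))
  expect_equal(out$pos, c(11L, 21L))
  expect_equal(out$ref, c("T", "G"))
  expect_equal(out$alt, c("A", "C"))
})

test_that("trim_alleles rejects non-variants and malformed alleles", {
  expect_error(trim_alleles("chr1", 100, "AT", "AT"), "not a variant")
  expect_error(trim_alleles("chr1", 100, "", "A"), "non-empty")
  expect_error(trim_alleles("chr1", 100, "A", "X"), "A/C/G/T/N")
  expect_error(trim_alleles("chr1", 0, "A", "C"), "positive")
})

test_that("trim_alleles is idempotent and fixes SNVs", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    once <- trim_alleles("chrX", 500L, ref, alt)
    twice <- trim_alleles(once$chrom, once$pos, once$ref, once$alt)
    expect_identical(once, twice)
  }
  # SNV keys are fixed points
  snv <- trim_alleles("chr2", 42L, "G", "T")
  expect_identical(snv$pos, 42L)
  expect_identical(snv$ref, "G")
})

test_that("split_multiallelic expands alternates and skips symbolic alleles", {
  bi <- split_multiallelic(
    tibble::tibble(chrom = "chr1", pos = 10L, ref = "A", alt = "C")
  )
  expect_equal(nrow(bi), 1L)
  expect_equal(bi$alt, "C")

  multi <- split_multiallelic(tibble::tibble(
    chrom = "chr1", pos = 10L, ref = "A", alt = "C,G",
    alt_depth = list(c(7L, 3L)), sample_id = "S1"
  ))
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$alt, c("C", "G"))
  expect_equal(multi$alt_depth, c(7L, 3L))
  expect_equal(multi$sample_id, c("S1", "S1"))

  expect_warning(
    sym <- split_multiallelic(
      tibble::tibble(chrom = "chr1", pos = 10L, ref = "G", alt = "<DEL>")
    ),
    "symbolic"
  )
  expect_equal(nrow(sym), 0L)
})

test_that("read_caller_vcf extracts calls, splits alleles, flags pass status", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SAF,Number=A,Type=Integer,Description="F">',
    '##INFO=<ID=SAR,Number=A,Type=Integer,Description="R">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="MQ">',
    '##INFO=<ID=NM,Number=1,Type=Float,Description="NM">',
    '##FILTER=<ID=weak_evidence,Description="w">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="AF">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "S1",
      sep = "\t"
    ),
    paste("chr1", "100", ".", "A", "C", "60", "PASS",
      "SAF=5;SAR=6;MQ=59.2;NM=1.1", "DP:AD:AF", "1000:989,11:0.011",
      sep = "\t"
    ),
    paste("chr1", "200", ".", "TCGA", "TCA,T", "30", "weak_evidence",
      "SAF=3,2;SAR=2,2;MQ=55;NM=0.8", "DP:AD:AF",
      "900:880,5,4:0.0056,0.0044",
      sep = "\t"
    ),
    paste("chr1", "300", ".", "G", "<DEL>", ".", "PASS", "MQ=50",
      "DP:AD:AF", "800:790,10:0.0125",
      sep = "\t"
    )
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)

  expect_warning(calls <- read_caller_vcf(path, "mutect2"), "symbolic")
  expect_equal(nrow(calls), 3L) # biallelic + 2 split alts; symbolic dropped
  expect_equal(calls$sample_id, rep("S1", 3))
  expect_equal(calls$caller_id, rep("mutect2", 3))

  snv <- calls[calls$pos == 100L, ]
  expect_true(snv$passed)
  expect_equal(snv$alt_depth, 11L)
  expect_equal(snv$vaf, 0.011)
  expect_equal(snv$fwd_alt, 5L)
  expect_equal(snv$rev_alt, 6L)
  expect_equal(snv$mapping_quality, 59.2)

  # multiallelic: TCGA>TCA trims to 201 CG>C; TCGA>T trims to 200 TCGA>T
  trimmed <- calls[calls$pos == 201L, ]
  expect_equal(trimmed$ref, "CG")
  expect_equal(trimmed$alt, "C")
  expect_false(trimmed$passed)
  expect_equal(trimmed$alt_depth, 5L)
})

test_that("merge_calls builds one consensus record per key", {
  calls <- dplyr::bind_rows(
    make_call(caller_id = "mutect2", alt_depth = 210L),
    make_call(caller_id = "vardict", alt_depth = 200L),
    make_call(caller_id = "lofreq2", alt_depth = 190L),
    make_call(caller_id = "vardict", pos = 500L, alt = "T", alt_depth = 8L)
  )
  merged <- merge_calls(calls)
  expect_equal(nrow(merged), 2L)
  shared <- merged[merged$pos == 100L, ]
  expect_equal(shared$n_callers_passed, 3L)
  # representative metrics come from exactly one call, by priority
  expect_equal(shared$rep_caller, "mutect2")
  expect_equal(shared$rep_alt_depth, 210L)
  single <- merged[merged$pos == 500L, ]
  expect_equal(single$n_callers_passed, 1L)
  expect_equal(single$rep_caller, "vardict")
})

test_that("present-but-filtered calls count as evidence, not as passes", {
  calls <- dplyr::bind_rows(
    make_call(caller_id = "vardict", passed = TRUE),
    make_call(caller_id = "mutect2", passed = FALSE)
  )
  merged <- merge_calls(calls)
  expect_equal(merged$n_callers_passed, 1L)
  expect_true(merged$present_mutect2)
  expect_false(merged$passed_mutect2)
  expect_true(merged$passed_vardict)
  # representative must be a passing call when one exists
  expect_equal(merged$rep_caller, "vardict")
})

test_that("duplicate same-caller records keep the higher alt depth", {
  calls <- dplyr::bind_rows(
    make_call(caller_id = "vardict", alt_depth = 12L),
    make_call(caller_id = "vardict", alt_depth = 30L)
  )
  expect_warning(merged <- merge_calls(calls), "duplicate")
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$rep_alt_depth, 30L)
})

test_that("merged output cardinality equals distinct normalized keys", {
  set.seed(99)
  keys <- tibble::tibble(
    pos = sample(1:50, 30, replace = TRUE) * 10L,
    alt = sample(c("C", "T"), 30, replace = TRUE)
  )
  calls <- dplyr::bind_rows(lapply(seq_len(30), function(i) {
    make_call(
      caller_id = sample(c("mutect2", "vardict", "lofreq2"), 1),
      pos = keys$pos[i], alt = keys$alt[i]
    )
  }))
  merged <- suppressWarnings(merge_calls(calls))
  expect_equal(nrow(merged), nrow(dplyr::distinct(keys)))
})

test_that("pindel passes are excluded from the consensus count by default", {
  calls <- dplyr::bind_rows(
    make_call(caller_id = "vardict", ref = "ATTTTTTTTTTTTTTTTTTTTTTTTT", alt = "A"),
    make_call(caller_id = "pindel", ref = "ATTTTTTTTTTTTTTTTTTTTTTTTT", alt = "A")
  )
  merged <- merge_calls(calls)
  expect_equal(merged$n_callers_passed, 1L)
  expect_true(merged$passed_pindel)
  with_pindel <- merge_calls(calls,
    consensus_callers = c("mutect2", "vardict", "lofreq2", "pindel")
  )
  expect_equal(with_pindel$n_callers_passed, 2L)
})

test_that("merged records survive a TSV round trip", {
  calls <- dplyr::bind_rows(
    make_call(caller_id = "mutect2"),
    make_call(caller_id = "vardict", pos = 500L, alt = "T", alt_depth = 33L)
  )
  merged <- merge_calls(calls)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pipeline_tsv(merged, path)
  back <- read_pipeline_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(merged), tolerance = 1e-12)
})
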