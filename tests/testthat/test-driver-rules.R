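test_that("truncating consequence set is as configured", {
  expect_true(is_truncating("stop_gained"))
  expect_true(is_truncating("splice_donor"))
  expect_false(is_truncating("missense"))
  expect_false(is_truncating("inframe_indel"))
  # configurable set
  expect_true(is_truncating("missense", truncating = "missense"))
})

test_that("R1-R3 cover truncating and in-frame gene rules", {
  kb <- fixture_kb()
  ev <- annotation_evidence(dplyr::bind_rows(
    make_evidence(gene = "DNMT3A", consequence = "frameshift"),
    make_evidence(gene = "DNMT3A", consequence = "missense"),
    make_evidence(gene = "JAK2", consequence = "stop_gained"),
    make_evidence(gene = "PPM1D", consequence = "stop_gained", exon = 6L),
    make_evidence(gene = "PPM1D", consequence = "stop_gained", exon = 5L),
    make_evidence(gene = "PPM1D", consequence = "missense", exon = 6L),
    make_evidence(gene = "CHEK2", consequence = "inframe_indel"),
    make_evidence(gene = "CHEK2", consequence = "frameshift"),
    make_evidence(gene = "TET2", consequence = "inframe_indel")
  ))
  expect_equal(
    rule_R1_truncating_genes(ev, kb),
    c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  expect_equal(
    rule_R2_ppm1d(ev, kb),
    c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  expect_equal(
    rule_R3_chek2_inframe(ev, kb),
    c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  # PPM1D truncating with no exon annotation cannot match R2
  no_exon <- annotation_evidence(
    make_evidence(gene = "PPM1D", consequence = "stop_gained")
  )
  expect_false(rule_R2_ppm1d(no_exon, kb))
})

test_that("R4 COSMIC missense thresholds are >=10 overall / >=5 haem", {
  kb <- fixture_kb()
  ev <- annotation_evidence(dplyr::bind_rows(
    make_evidence(cosmic_total = 10L, cosmic_haem = 0L),
    make_evidence(cosmic_total = 9L, cosmic_haem = 4L),
    make_evidence(cosmic_total = 0L, cosmic_haem = 5L),
    make_evidence(consequence = "stop_gained", cosmic_total = 100L)
  ))
  expect_equal(rule_R4_cosmic_missense(ev, kb), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("R5, R6 and R10 are pure membership lookups", {
  kb <- fixture_kb()
  ev <- annotation_evidence(dplyr::bind_rows(
    make_evidence(chrom = "chr2", pos = 25234373L, ref = "C", alt = "T"),
    make_evidence(chrom = "chr2", pos = 25234374L, ref = "C", alt = "T"),
    make_evidence(oncokb = "oncogenic"),
    make_evidence(oncokb = "likely_oncogenic"),
    make_evidence(oncokb = "other"),
    make_evidence(clinvar = "pathogenic"),
    make_evidence(clinvar = "likely_pathogenic"),
    make_evidence(clinvar = "other")
  ))
  expect_equal(rule_R5_prior_ch(ev, kb)[1:2], c(TRUE, FALSE))
  expect_equal(rule_R6_oncokb(ev, kb)[3:5], c(TRUE, TRUE, FALSE))
  expect_equal(rule_R10_clinvar(ev, kb)[6:8], c(TRUE, TRUE, FALSE))
})

test_that("R7 requires a listed residue plus damaging evidence", {
  kb <- fixture_kb()
  ev <- annotation_evidence(dplyr::bind_rows(
    make_evidence(gene = "DNMT3A", protein_pos = 882L, sift = "deleterious"),
    make_evidence(
      gene = "DNMT3A", protein_pos = 882L,
      sift = "tolerated", polyphen = "benign"
    ),
    make_evidence(
      gene = "DNMT3A", protein_pos = 883L, sift = "deleterious"
    ),
    make_evidence(
      gene = "TP53", protein_pos = 273L, polyphen = "possibly_damaging"
    )
  ))
  expect_equal(rule_R7_same_residue(ev, kb), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("R8 hotspot proximity uses <=3 residues or <=9 nucleotides", {
  kb <- fixture_kb() # DNMT3A hotspot at aa 882 / cDNA 2645
  ev <- annotation_evidence(dplyr::bind_rows(
    make_evidence(gene = "DNMT3A", protein_pos = 885L, cdna_pos = 2700L),
    make_evidence(gene = "DNMT3A", protein_pos = 886L, cdna_pos = 2657L),
    make_evidence(gene = "DNMT3A", protein_pos = 886L, cdna_pos = 2654L),
    make_evidence(gene = "TET2", protein_pos = 882L, cdna_pos = 2645L),
    make_evidence(gene = "DNMT3A", consequence = "stop_gained", protein_pos = 882L)
  ))
  # 3 aa away matches; 4 aa + 12 nt does not; 9 nt matches; wrong gene and
  # non-missense never match
  expect_equal(rule_R8_hotspot_proximity(ev, kb), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  no_pos <- annotation_evidence(make_evidence(gene = "DNMT3A"))
  expect_false(rule_R8_hotspot_proximity(no_pos, kb))
})

test_that("R9 region rules cover SRSF2 95 and the SF3B1 ranges", {
  kb <- fixture_kb()
  ev <- annotation_evidence(dplyr::bind_rows(
    make_evidence(gene = "SRSF2", protein_pos = 95L),
    make_evidence(gene = "SRSF2", protein_pos = 96L),
    make_evidence(gene = "SF3B1", protein_pos = 622L),
    make_evidence(gene = "SF3B1", protein_pos = 626L),
    make_evidence(gene = "SF3B1", protein_pos = 700L),
    make_evidence(gene = "SF3B1", protein_pos = 705L),
    make_evidence(gene = "SF3B1", protein_pos = 742L),
    make_evidence(gene = "SF3B1", protein_pos = 739L)
  ))
  expect_equal(
    rule_R9_regions(ev, kb),
    c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  )
})

test_that("hotspot definition enforces count thresholds and damage evidence", {
  expect_true(is_hotspot(5L, 0L, 0L, 0L, TRUE))
  expect_true(is_hotspot(0L, 25L, 0L, 0L, TRUE))
  expect_true(is_hotspot(0L, 0L, 20L, 0L, TRUE))
  expect_true(is_hotspot(0L, 0L, 0L, 10L, TRUE))
  expect_false(is_hotspot(4L, 24L, 19L, 9L, TRUE))
  expect_false(is_hotspot(0L, 25L, 0L, 0L, FALSE))
  # the knowledge base refuses entries that fail the definition
  expect_error(
    knowledge_base(hotspots = tibble::tibble(
      gene = "DNMT3A", protein_pos = 882L, cdna_pos = 2645L,
      ch_report_count = 1L, cosmic_total = 1L, cosmic_haem = 1L,
      cosmic_myeloid = 1L, damaging = TRUE
    )),
    "hotspot definition"
  )
})

test_that("classify_driver records union semantics and provenance", {
  kb <- fixture_kb()
  ev <- dplyr::bind_rows(
    # DNMT3A frameshift that is also in the prior-CH list: R1 and R5
    make_evidence(
      chrom = "chr2", pos = 25234373L, ref = "C", alt = "T",
      gene = "DNMT3A", consequence = "frameshift"
    ),
    make_evidence(consequence = "synonymous"),
    make_evidence(gene = "SRSF2", protein_pos = 95L)
  )
  dc <- classify_driver(ev, kb)
  expect_equal(dc$matched_rules[1], "R1,R5")
  expect_true(dc$is_putative_driver[1])
  expect_false(dc$is_putative_driver[2])
  expect_equal(dc$matched_rules[2], "")
  expect_match(dc$matched_rules[3], "R9")
  # is_putative_driver is exactly "some rule matched"
  rule_cols <- grep("^rule_", names(dc), value = TRUE)
  expect_equal(
    dc$is_putative_driver,
    rowSums(as.matrix(dc[, rule_cols])) > 0
  )
})

test_that("driver calls are deterministic and monotone", {
  kb <- fixture_kb()
  ev <- dplyr::bind_rows(
    make_evidence(gene = "DNMT3A", consequence = "frameshift"),
    make_evidence(cosmic_total = 10L),
    make_evidence(gene = "SRSF2", protein_pos = 95L)
  )
  expect_identical(classify_driver(ev, kb), classify_driver(ev, kb))

  # removing any rule never adds a driver
  full <- classify_driver(ev, kb)
  rules <- chvarfilt:::driver_rule_set()
  for (drop in names(rules)) {
    reduced <- classify_driver(ev, kb, rules = rules[setdiff(names(rules), drop)])
    expect_true(all(full$is_putative_driver | !reduced$is_putative_driver))
  }

  # adding evidence never removes a match
  weaker <- classify_driver(make_evidence(cosmic_total = 9L), kb)
  stronger <- classify_driver(make_evidence(cosmic_total = 50L), kb)
  expect_false(weaker$is_putative_driver)
  expect_true(stronger$is_putative_driver)
})

test_that("unknown consequence labels coerce to other with a warning", {
  expect_warning(
    ev <- annotation_evidence(make_evidence(consequence = "weird_label")),
    "coerced"
  )
  expect_equal(ev$consequence, "other")
})
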