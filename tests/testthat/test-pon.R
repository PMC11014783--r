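test_that("bonferroni_threshold divides alpha by the panel size", {
  expect_equal(signif(bonferroni_threshold(0.05, 23650), 2), 2.1e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 100), "alpha")
})

test_that("bonferroni_threshold is monotone in both arguments", {
  alphas <- c(0.01, 0.02, 0.05, 0.1)
  expect_true(all(diff(sapply(alphas, bonferroni_threshold, panel_bp = 500)) > 0))
  panels <- c(100, 1000, 23650, 1e6)
  expect_true(all(diff(sapply(panels, function(p) bonferroni_threshold(0.05, p))) < 0))
})

test_that("panel_bp_from_bed merges overlapping intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t0\t100\tr1", "chr1\t50\t150\tr2", "chr2\t10\t20\tr3"
  ), path)
  expect_equal(panel_bp_from_bed(path), 150 + 10)
})

test_that("fisher_exact matches the enumeration oracle on random tables", {
  set.seed(7)
  for (i in 1:300) {
    tab <- as.integer(sample(0:15, 4, replace = TRUE))
    expect_equal(
      fisher_exact(tab[1], tab[2], tab[3], tab[4], "greater"),
      fisher_oracle_greater(tab[1], tab[2], tab[3], tab[4]),
      tolerance = 1e-12
    )
    expect_equal(
      fisher_exact(tab[1], tab[2], tab[3], tab[4], "two_sided"),
      fisher_oracle_two_sided(tab[1], tab[2], tab[3], tab[4]),
      tolerance = 1e-12
    )
  }
})

test_that("fisher_exact agrees with stats::fisher.test", {
  set.seed(8)
  for (i in 1:50) {
    tab <- as.integer(sample(0:30, 4, replace = TRUE))
    if (sum(tab) == 0) next
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(
      fisher_exact(tab[1], tab[2], tab[3], tab[4], "greater"),
      stats::fisher.test(m, alternative = "greater")$p.value,
      tolerance = 1e-9
    )
    expect_equal(
      fisher_exact(tab[1], tab[2], tab[3], tab[4], "two_sided"),
      stats::fisher.test(m, alternative = "two.sided")$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("fisher_exact handles degenerate tables", {
  expect_equal(fisher_exact(0, 100, 0, 1000, "greater"), 1)
  expect_equal(fisher_exact(0, 0, 0, 0, "greater"), 1)
  expect_equal(fisher_exact(0, 0, 0, 0, "two_sided"), 1)
  # equal proportions, one-sided: no evidence of excess
  expect_gt(fisher_exact(5, 95, 50, 950, "greater"), 0.5)
  expect_error(fisher_exact(-1, 5, 5, 5), "non-negative")
})

test_that("one-sided p-value is monotone in the PoN background", {
  # more pooled PoN alt reads (same pooled depth) can only weaken evidence
  p <- fisher_exact(20, 19980, 0:30, 540000 - 0:30, "greater")
  expect_true(all(diff(p) >= 0))
  # scaling sample counts up at fixed proportions can only strengthen it
  scale <- c(1, 2, 5, 10, 20)
  p2 <- fisher_exact(10 * scale, 990 * scale, 100, 99900, "greater")
  expect_true(all(diff(p2) <= 0))
})

test_that("pon_hard_filter implements the >2% in >=2 samples rule", {
  merged <- merge_calls(make_call())
  fail_pon <- make_pon(alt_counts = c(25, 30, 0, 0), depths = rep(1000, 4))
  v <- pon_hard_filter(merged, fail_pon)
  expect_false(v$passed)
  expect_match(v$reason, "2 PoN samples")

  one_hot <- make_pon(alt_counts = c(50, 0, 0, 0), depths = rep(1000, 4))
  expect_true(pon_hard_filter(merged, one_hot)$passed)

  clean <- make_pon(alt_counts = rep(0, 4))
  expect_true(pon_hard_filter(merged, clean)$passed)

  # zero-depth PoN sample contributes VAF 0, not NaN
  zero_dp <- make_pon(alt_counts = c(0, 25, 30), depths = c(0, 1000, 1000))
  expect_false(pon_hard_filter(merged, zero_dp)$passed)
})

test_that("uncovered sites pass the PoN filters with a logged reason", {
  merged <- merge_calls(make_call(pos = 999L))
  pon <- make_pon(pos = 100L, alt_counts = c(0, 0))
  h <- pon_hard_filter(merged, pon)
  expect_true(h$passed)
  expect_match(h$reason, "no PoN coverage")
  f <- pon_fisher_filter(merged, pon)
  expect_true(f$passed)
  expect_match(f$reason, "no PoN coverage")
  # fail-closed configuration
  f2 <- pon_fisher_filter(merged, pon, pon_config(missing_pon = "fail"))
  expect_false(f2$passed)
})

test_that("pon_fisher_filter separates signal from background error", {
  # strong signal: 200/20000 in sample vs 3/500000 pooled
  merged <- merge_calls(make_call(alt_depth = 200L, total_depth = 20000L))
  pon <- make_pon(alt_counts = c(1, 1, 1, 0, 0), depths = rep(100000, 5))
  v <- pon_fisher_filter(merged, pon)
  expect_true(v$passed)
  expect_lt(v$p_value, bonferroni_threshold(0.05, 23650))
  expect_equal(v$threshold, 0.05 / 23650)
  # cross-check the p-value against the enumeration oracle
  expect_equal(
    v$p_value, fisher_oracle_greater(200, 19800, 3, 499997),
    tolerance = 1e-12
  )

  # proportion equal to the PoN background: p ~ 1, fails
  merged_bg <- merge_calls(make_call(alt_depth = 20L, total_depth = 20000L))
  pon_bg <- make_pon(alt_counts = rep(20, 5), depths = rep(20000, 5))
  v_bg <- pon_fisher_filter(merged_bg, pon_bg)
  expect_false(v_bg$passed)
  expect_gte(v_bg$p_value, v_bg$threshold)
})

test_that("pon_size_sweep at full size reproduces the full-PoN result", {
  set.seed(21)
  model <- sim_site_error_model(n_sites = 20, seed = 21)
  pon <- simulate_pon(model, n_pon = 6, depth = 5000, seed = 22)
  truth <- tibble::tibble(
    chrom = model$chrom, pos = model$pos, ref = model$ref, alt = model$alt,
    sample_alt = rbinom(20, 5000, 0.002), sample_depth = 5000L
  )
  sw <- pon_size_sweep(pon, truth, sizes = c(1, 6), seed = 5)
  full <- pon_fisher_filter(
    merge_calls(dplyr::bind_rows(lapply(seq_len(20), function(i) {
      make_call(
        pos = model$pos[i], ref = model$ref[i], alt = model$alt[i],
        alt_depth = truth$sample_alt[i], total_depth = 5000L
      )
    }))),
    pon
  )
  expect_identical(
    sw$prop_removed[sw$size == 6],
    mean(!full$passed)
  )
})

test_that("pon_size_sweep matches exhaustive subset enumeration", {
  set.seed(31)
  model <- sim_site_error_model(n_sites = 8, seed = 31)
  pon <- simulate_pon(model, n_pon = 5, depth = 2000, seed = 32)
  truth <- tibble::tibble(
    chrom = model$chrom, pos = model$pos, ref = model$ref, alt = model$alt,
    sample_alt = rbinom(8, 2000, 0.005), sample_depth = 2000L
  )
  cfg <- pon_config()
  sw <- pon_size_sweep(pon, truth, sizes = 1:5, config = cfg, seed = 3)

  # independent oracle: loop over every subset, compute every p by lchoose sums
  samples <- sort(unique(pon$pon_sample_id))
  oracle <- sapply(1:5, function(k) {
    subs <- utils::combn(samples, k, simplify = FALSE)
    mean(sapply(subs, function(ss) {
      sub <- pon[pon$pon_sample_id %in% ss, ]
      agg <- stats::aggregate(cbind(alt_count, depth) ~ pos, data = sub, FUN = sum)
      agg <- agg[match(truth$pos, agg$pos), ]
      removed <- mapply(function(a, dp, pa, pd) {
        fisher_oracle_greater(a, dp - a, pa, pd - pa) >= cfg$threshold
      }, truth$sample_alt, truth$sample_depth, agg$alt_count, agg$depth)
      mean(removed)
    }))
  })
  expect_equal(sw$prop_removed, unname(oracle), tolerance = 1e-12)
})

test_that("pon_size_sweep rejects bad inputs", {
  pon <- make_pon(alt_counts = c(0, 0, 0))
  truth <- tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    sample_alt = 50L, sample_depth = 20000L
  )
  expect_error(pon_size_sweep(pon, truth[0, ]), "empty truth")
  expect_error(pon_size_sweep(pon, truth, sizes = 9), "within")
  # size 1 on an all-zero PoN: clear true variants are never removed
  sw <- pon_size_sweep(pon, truth, sizes = 1, seed = 2)
  expect_equal(sw$prop_removed, 0)
})
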