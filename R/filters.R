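#' Default thresholds for the false-positive filter suite
#'
#' Every cutoff of the post-calling artifact filters, config-exposed. The
#' defaults implement the published CH filtering criteria: alternate allele
#' depth < 5 fails; VAF must strictly exceed 0.1%; indels longer than 20 bp
#' need support from at least two callers; recurrence above 6% of the cohort
#' fails outright and above 3% fails unless previously reported in
#' large-scale CH studies. The VarScan2-style sub-criteria (read position,
#' strand fraction, mismatch-quality-sum difference, incomplete-read
#' fraction) and the VarDict-only low-VAF/low-quality expression are
#' reconstructed from the cited tools' documented behaviour and fully
#' configurable.
#'
#' @param min_alt_depth Minimum alt read depth (pass requires `>=`).
#' @param min_vaf VAF floor; pass requires `vaf > min_vaf` (strict).
#' @param max_singlecaller_indel_bp Longest indel tolerated with support
#'   from a single caller.
#' @param recurrence_known Cohort occurrence fraction above which any
#'   variant fails.
#' @param recurrence_novel Occurrence fraction above which a variant fails
#'   unless previously reported.
#' @param varscan List of VarScan-style sub-thresholds.
#' @param vardict List of constants for the VarDict-singleton expression.
#' @return A list of class `fp_thresholds`.
#' @export
fp_thresholds <- function(min_alt_depth = 5L,
                          min_vaf = 0.001,
                          max_singlecaller_indel_bp = 20L,
                          recurrence_known = 0.06,
                          recurrence_novel = 0.03,
                          varscan = list(
                            min_readpos = 0.10,
                            strand_frac = c(0.10, 0.90),
                            max_mmqs_diff = 50,
                            max_incomplete_read_fraction = 0.90
                          ),
                          vardict = list(
                            max_af_dp = 6,
                            mq1 = 55, nm1 = 1,
                            mq2 = 60, nm2 = 2,
                            min_dp = 10, min_qual = 45
                          )) {
  structure(
    list(
      min_alt_depth = min_alt_depth, min_vaf = min_vaf,
      max_singlecaller_indel_bp = max_singlecaller_indel_bp,
      recurrence_known = recurrence_known, recurrence_novel = recurrence_novel,
      varscan = varscan, vardict = vardict
    ),
    class = "fp_thresholds"
  )
}

verdict_tbl <- function(filter_id, passed, reason) {
  tibble(filter_id = filter_id, passed = passed, reason = reason)
}

#' Minimum alternate-depth filter
#'
#' @param alt_depth Alt-supporting read counts.
#' @param min_alt_depth Pass requires `alt_depth >= min_alt_depth`.
#' @return Verdict tibble (`filter_id`, `passed`, `reason`).
#' @export
min_alt_depth_filter <- function(alt_depth, min_alt_depth = 5L) {
  passed <- !is.na(alt_depth) & alt_depth >= min_alt_depth
  verdict_tbl(
    "min_alt_depth", passed,
    ifelse(passed, "sufficient alt depth",
      sprintf("alt depth %s < %d", alt_depth, min_alt_depth)
    )
  )
}

#' Minimum VAF filter
#'
#' Pass requires the VAF to strictly exceed the floor (`vaf > min_vaf`); the
#' boundary value itself fails.
#'
#' @param vaf Variant allele fractions.
#' @param min_vaf VAF floor (default 0.001, i.e. 0.1%).
#' @return Verdict tibble.
#' @export
min_vaf_filter <- function(vaf, min_vaf = 0.001) {
  passed <- !is.na(vaf) & vaf > min_vaf
  verdict_tbl(
    "min_vaf", passed,
    ifelse(passed, "above VAF floor",
      sprintf("VAF %s <= %g", signif(vaf, 3), min_vaf)
    )
  )
}

#' Strand-support filter
#'
#' Fails variants with alt evidence from only one strand; both-zero strand
#' counts also fail (no strand evidence at all). Absent counts leave the
#' filter inapplicable: the variant passes with reason `"not evaluable"`.
#'
#' @param fwd_alt,rev_alt Strand-split alt read counts (may be `NA`).
#' @return Verdict tibble.
#' @export
strand_support_filter <- function(fwd_alt, rev_alt) {
  n <- max(length(fwd_alt), length(rev_alt))
  fwd_alt <- rep_len(fwd_alt, n)
  rev_alt <- rep_len(rev_alt, n)
  evaluable <- !is.na(fwd_alt) & !is.na(rev_alt)
  single <- evaluable & xor(fwd_alt == 0, rev_alt == 0)
  none <- evaluable & fwd_alt == 0 & rev_alt == 0
  passed <- !evaluable | (!single & !none)
  reason <- rep("alt reads on both strands", n)
  reason[!evaluable] <- "not evaluable: strand counts absent"
  reason[single] <- "alt evidence from a single strand only"
  reason[none] <- "no strand evidence"
  verdict_tbl("strand_support", passed, reason)
}

#' Long-indel multi-caller filter
#'
#' Indels longer than `max_singlecaller_indel_bp` (default 20 bp, strict)
#' are typically misaligned reads when supported by a single caller and
#' fail; with support from two or more callers they pass. SNVs always pass.
#'
#' @param ref,alt Trimmed alleles.
#' @param n_callers_passed Consensus pass count per variant.
#' @param max_singlecaller_indel_bp Length cutoff.
#' @return Verdict tibble.
#' @export
long_indel_filter <- function(ref, alt, n_callers_passed,
                              max_singlecaller_indel_bp = 20L) {
  len <- abs(nchar(ref) - nchar(alt))
  fails <- len > max_singlecaller_indel_bp & n_callers_passed < 2L
  verdict_tbl(
    "long_indel", !fails,
    ifelse(fails,
      sprintf(
        "%d bp indel (> %d) with single-caller support",
        len, max_singlecaller_indel_bp
      ),
      "not a long single-caller indel"
    )
  )
}

#' VarScan-style false-positive filter
#'
#' Re-implements the read-level heuristics of VarScan2's fpfilter as four
#' independent sub-criteria: median variant position within supporting reads
#' too close to the ends, alt strand fraction outside a central band,
#' mismatch-quality-sum difference too high, and too many alt reads not
#' fully spanning the variant (the incomplete-read-count criterion). Absent
#' metrics skip the corresponding sub-criterion and are recorded in the
#' reason.
#'
#' @param median_readpos_fraction Median relative variant position in
#'   supporting reads, in `[0, 1]`.
#' @param fwd_alt,rev_alt Strand-split alt read counts.
#' @param mmqs_diff Mismatch-quality-sum difference (alt minus ref reads).
#' @param incomplete_read_fraction Fraction of alt reads not fully spanning
#'   the variant.
#' @param thresholds The `varscan` element of [fp_thresholds()].
#' @return Verdict tibble.
#' @export
varscan_fp_filter <- function(median_readpos_fraction = NA_real_,
                              fwd_alt = NA_integer_, rev_alt = NA_integer_,
                              mmqs_diff = NA_real_,
                              incomplete_read_fraction = NA_real_,
                              thresholds = fp_thresholds()$varscan) {
  n <- max(
    length(median_readpos_fraction), length(fwd_alt), length(rev_alt),
    length(mmqs_diff), length(incomplete_read_fraction)
  )
  rp <- rep_len(median_readpos_fraction, n)
  fa <- rep_len(fwd_alt, n)
  ra <- rep_len(rev_alt, n)
  mq <- rep_len(mmqs_diff, n)
  irc <- rep_len(incomplete_read_fraction, n)

  strand_frac <- ifelse(!is.na(fa) & !is.na(ra) & (fa + ra) > 0,
    fa / (fa + ra), NA_real_
  )
  fail_rp <- !is.na(rp) & rp < thresholds$min_readpos
  fail_sf <- !is.na(strand_frac) &
    (strand_frac < thresholds$strand_frac[1] | strand_frac > thresholds$strand_frac[2])
  fail_mq <- !is.na(mq) & mq > thresholds$max_mmqs_diff
  fail_irc <- !is.na(irc) & irc > thresholds$max_incomplete_read_fraction

  fails <- fail_rp | fail_sf | fail_mq | fail_irc
  n_skipped <- is.na(rp) + is.na(strand_frac) + is.na(mq) + is.na(irc)
  why <- mapply(function(a, b, c2, d, sk) {
    parts <- c(
      if (a) "read position" else NULL,
      if (b) "strand fraction" else NULL,
      if (c2) "mismatch quality sum" else NULL,
      if (d) "incomplete reads" else NULL
    )
    if (length(parts)) {
      paste("failed:", paste(parts, collapse = ", "))
    } else if (sk == 4L) {
      "not evaluable: all metrics absent"
    } else if (sk > 0L) {
      sprintf("passed evaluable sub-criteria (%d skipped)", sk)
    } else {
      "passed all sub-criteria"
    }
  }, fail_rp, fail_sf, fail_mq, fail_irc, n_skipped)
  verdict_tbl("varscan_fp", !fails, why)
}

#' VarDict-singleton low-VAF/low-quality filter
#'
#' Applies only to variants passed exclusively by VarDictJava. Such a call
#' fails when its allele support is weak (`vaf * depth < 6`) *and* any of
#' the quality clauses holds: mapping quality < 55 with > 1 mean mismatches,
#' mapping quality < 60 with > 2 mean mismatches, depth < 10, or caller
#' quality < 45. Missing quality fields make the corresponding clause false.
#'
#' @param vardict_only Logical: was the variant passed only by VarDict?
#' @param vaf,total_depth,mapping_quality,mean_mismatches,qual Metrics of
#'   the VarDict call.
#' @param constants The `vardict` element of [fp_thresholds()].
#' @return Verdict tibble.
#' @export
vardict_singleton_filter <- function(vardict_only, vaf, total_depth,
                                     mapping_quality = NA_real_,
                                     mean_mismatches = NA_real_,
                                     qual = NA_real_,
                                     constants = fp_thresholds()$vardict) {
  n <- max(length(vardict_only), length(vaf), length(total_depth))
  vardict_only <- rep_len(vardict_only, n)
  vaf <- rep_len(vaf, n)
  total_depth <- rep_len(total_depth, n)
  mapping_quality <- rep_len(mapping_quality, n)
  mean_mismatches <- rep_len(mean_mismatches, n)
  qual <- rep_len(qual, n)

  tf <- function(x) !is.na(x) & x # NA clause -> FALSE
  weak <- tf(vaf * total_depth < constants$max_af_dp)
  c1 <- tf(mapping_quality < constants$mq1) & tf(mean_mismatches > constants$nm1)
  c2 <- tf(mapping_quality < constants$mq2) & tf(mean_mismatches > constants$nm2)
  c3 <- tf(total_depth < constants$min_dp)
  c4 <- tf(qual < constants$min_qual)
  fails <- vardict_only & weak & (c1 | c2 | c3 | c4)
  reason <- rep("passed low-VAF/low-quality expression", n)
  reason[!vardict_only] <- "not applicable: not a VarDict-only call"
  reason[fails] <- "VarDict-only call with weak support and low quality"
  verdict_tbl("vardict_singleton", !fails, reason)
}

#' Cohort recurrence filter
#'
#' Variants carried by more than `recurrence_known` of all samples fail
#' outright (cohort-wide artifacts masquerading as hotspots); those above
#' `recurrence_novel` fail unless previously identified in large-scale CH
#' sequencing studies. Cohorts of fewer than two samples are not evaluable
#' and pass.
#'
#' @param occurrence_fraction Per-variant fraction of cohort samples
#'   carrying the variant (computed before filtering, see
#'   [cohort_occurrence()]).
#' @param previously_reported Logical: is the variant in the prior-CH list?
#' @param n_cohort_samples Total number of samples in the cohort.
#' @param thresholds An [fp_thresholds()].
#' @return Verdict tibble.
#' @export
recurrence_filter <- function(occurrence_fraction, previously_reported,
                              n_cohort_samples,
                              thresholds = fp_thresholds()) {
  n <- max(length(occurrence_fraction), length(previously_reported))
  f <- rep_len(occurrence_fraction, n)
  rep_known <- rep_len(previously_reported, n)
  rep_known[is.na(rep_known)] <- FALSE
  if (n_cohort_samples < 2L) {
    return(verdict_tbl(
      "recurrence", rep(TRUE, n),
      rep("not evaluable: cohort has fewer than 2 samples", n)
    ))
  }
  fail_known <- f > thresholds$recurrence_known
  fail_novel <- f > thresholds$recurrence_novel & !rep_known
  passed <- !(fail_known | fail_novel)
  reason <- rep("below recurrence cutoffs", n)
  reason[fail_novel] <- sprintf(
    "in %.1f%% of samples (> %.0f%%) and not previously reported",
    100 * f[fail_novel], 100 * thresholds$recurrence_novel
  )
  reason[fail_known] <- sprintf(
    "in %.1f%% of samples (> %.0f%%)",
    100 * f[fail_known], 100 * thresholds$recurrence_known
  )
  verdict_tbl("recurrence", passed, reason)
}

#' Cohort-wide occurrence of each variant
#'
#' Counts, per variant key, the fraction of cohort samples in which the
#' variant was called at all (pre-filtering; a sample counts once per key
#' regardless of VAF).
#'
#' @param merged Merged variant table for the whole cohort.
#' @param n_samples Total cohort size; defaults to the number of distinct
#'   `sample_id`s in `merged`.
#' @return Tibble with `variant_id`, `n_samples_with`, `occurrence_fraction`.
#' @export
cohort_occurrence <- function(merged, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- n_distinct(merged$sample_id)
  merged %>%
    mutate(variant_id = variant_id(chrom, pos, ref, alt)) %>%
    group_by(variant_id) %>%
    summarise(n_samples_with = n_distinct(sample_id), .groups = "drop") %>%
    mutate(occurrence_fraction = n_samples_with / n_samples)
}

#' Apply the full false-positive filter suite
#'
#' Evaluates every configured filter for every merged variant — the PoN hard
#' and Fisher filters (when PoN counts are supplied), the read-metric
#' filters, and the cohort recurrence filter — with no short-circuiting, and
#' returns the complete verdict list together with the per-variant overall
#' conjunction. Each filter is a pure predicate of its inputs, so the result
#' is independent of evaluation order.
#'
#' @param merged Cohort merged variant table ([merge_calls()]).
#' @param pon_counts Long PoN count table, or `NULL` (PoN filters then
#'   report `"not evaluable"` and pass).
#' @param metrics Optional read-metrics table with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `median_readpos_fraction`, `mmqs_diff`,
#'   `incomplete_read_fraction` (strand counts are taken from `merged`).
#' @param prior_ch Character vector of previously reported variant ids
#'   (`variant_id()` form), or a data frame with key columns.
#' @param thresholds An [fp_thresholds()].
#' @param pon_cfg A [pon_config()].
#' @param n_cohort_samples Cohort size for the recurrence filter; defaults
#'   to the samples present in `merged`.
#' @return A list with `verdicts` (long tibble: one row per variant per
#'   filter, ordered by `filter_id`) and `overall` (per-variant `passed` and
#'   comma-separated `failing_filters`).
#' @export
apply_all_filters <- function(merged, pon_counts = NULL, metrics = NULL,
                              prior_ch = NULL,
                              thresholds = fp_thresholds(),
                              pon_cfg = pon_config(),
                              n_cohort_samples = NULL) {
  merged <- mutate(merged, variant_id = variant_id(chrom, pos, ref, alt))
  keys <- select(merged, sample_id, variant_id, chrom, pos, ref, alt)
  prior_ids <- prior_ch_ids(prior_ch)

  with_keys <- function(v) bind_cols(keys, v)

  verdicts <- list(
    with_keys(min_alt_depth_filter(merged$rep_alt_depth, thresholds$min_alt_depth)),
    with_keys(min_vaf_filter(merged$rep_vaf, thresholds$min_vaf)),
    with_keys(strand_support_filter(merged$fwd_alt, merged$rev_alt)),
    with_keys(long_indel_filter(
      merged$ref, merged$alt, merged$n_callers_passed,
      thresholds$max_singlecaller_indel_bp
    ))
  )

  # read-metric filter: join optional metrics by sample + key
  if (!is.null(metrics) && nrow(metrics)) {
    metrics <- metrics %>%
      mutate(variant_id = variant_id(chrom, pos, ref, alt)) %>%
      select(sample_id, variant_id,
        dplyr::any_of(c(
          "median_readpos_fraction", "mmqs_diff",
          "incomplete_read_fraction"
        ))
      )
    mm <- left_join(select(merged, sample_id, variant_id, fwd_alt, rev_alt),
      metrics,
      by = c("sample_id", "variant_id")
    )
  } else {
    # no metrics table: every VarScan sub-criterion is inapplicable
    # (the standalone strand filter still covers strand support)
    mm <- tibble(
      median_readpos_fraction = rep(NA_real_, nrow(merged)),
      mmqs_diff = NA_real_, incomplete_read_fraction = NA_real_,
      fwd_alt = NA_integer_, rev_alt = NA_integer_
    )
  }
  get0_na <- function(tb, col) if (col %in% names(tb)) tb[[col]] else rep(NA_real_, nrow(tb))
  verdicts <- c(verdicts, list(with_keys(varscan_fp_filter(
    get0_na(mm, "median_readpos_fraction"), mm$fwd_alt, mm$rev_alt,
    get0_na(mm, "mmqs_diff"), get0_na(mm, "incomplete_read_fraction"),
    thresholds$varscan
  ))))

  pindel_passed <- if ("passed_pindel" %in% names(merged)) {
    isTRUE_vec(merged$passed_pindel)
  } else {
    rep(FALSE, nrow(merged))
  }
  vardict_only <- merged$passed_vardict &
    !(merged$passed_mutect2 | merged$passed_lofreq2 | pindel_passed)
  verdicts <- c(verdicts, list(with_keys(vardict_singleton_filter(
    vardict_only, merged$rep_vaf, merged$rep_total_depth,
    merged$rep_mapping_quality, merged$rep_mean_mismatches, merged$rep_qual,
    thresholds$vardict
  ))))

  if (is.null(n_cohort_samples)) n_cohort_samples <- n_distinct(merged$sample_id)
  occ <- cohort_occurrence(merged, n_cohort_samples)
  of <- occ$occurrence_fraction[match(merged$variant_id, occ$variant_id)]
  verdicts <- c(verdicts, list(with_keys(recurrence_filter(
    of, merged$variant_id %in% prior_ids, n_cohort_samples, thresholds
  ))))

  if (!is.null(pon_counts)) {
    ph <- pon_hard_filter(merged, pon_counts, pon_cfg)
    pf <- pon_fisher_filter(merged, pon_counts, pon_cfg)
    verdicts <- c(verdicts, list(
      select(ph, sample_id, variant_id, chrom, pos, ref, alt, filter_id, passed, reason),
      select(pf, sample_id, variant_id, chrom, pos, ref, alt, filter_id, passed, reason)
    ))
  } else {
    verdicts <- c(verdicts, list(
      with_keys(verdict_tbl("pon_hard", TRUE, "not evaluable: no PoN table")),
      with_keys(verdict_tbl("pon_fisher", TRUE, "not evaluable: no PoN table"))
    ))
  }

  long <- bind_rows(verdicts) %>% arrange(filter_id, sample_id, variant_id)
  overall <- long %>%
    group_by(sample_id, variant_id) %>%
    summarise(
      # failing_filters must read the per-filter column, so compute it first
      failing_filters = paste(sort(filter_id[!passed]), collapse = ","),
      passed = all(passed),
      .groups = "drop"
    )
  list(verdicts = long, overall = overall)
}

isTRUE_vec <- function(x) !is.na(x) & x

prior_ch_ids <- function(prior_ch) {
  if (is.null(prior_ch)) {
    return(character())
  }
  if (is.data.frame(prior_ch)) {
    return(variant_id(prior_ch$chrom, prior_ch$pos, prior_ch$ref, prior_ch$alt))
  }
  as.character(prior_ch)
}
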