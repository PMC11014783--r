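#' Exact Clopper-Pearson binomial confidence interval
#'
#' Computed by beta-quantile inversion of the binomial tails. Endpoints are
#' forced to 0 when `x = 0` and to 1 when `x = n`; `n = 0` yields an absent
#' (`NA`) interval. Vectorized.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' clopper_pearson(5, 10)
#' @export
clopper_pearson <- function(x, n, confidence = 0.95) {
  m <- max(length(x), length(n))
  x <- rep_len(x, m)
  n <- rep_len(n, m)
  if (any(x < 0 | x > n, na.rm = TRUE)) stop("x must satisfy 0 <= x <= n")
  alpha <- 1 - confidence
  lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  lower[n == 0] <- NA_real_
  upper[n == 0] <- NA_real_
  tibble(lower = lower, upper = upper)
}

#' VAF binning function
#'
#' Builds a binning function over strictly increasing edges. Bins are
#' lower-inclusive / upper-exclusive, except the last bin which includes its
#' upper edge. The defaults reproduce the standard CH reporting bins:
#' below 0.1%, 0.1-0.4%, 0.4-1%, 1-5%, and above 5% VAF (0.05 itself falls
#' in the top bin by the lower-inclusive convention).
#'
#' @param edges Strictly increasing numeric vector of bin edges.
#' @return A function mapping VAFs to a factor of bin labels.
#' @examples
#' vaf_bins()(c(0.0005, 0.004, 0.05))
#' @export
vaf_bins <- function(edges = c(0, 0.001, 0.004, 0.01, 0.05, 1)) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  pct <- function(x) {
    out <- 100 * x
    ifelse(out == round(out), sprintf("%g%%", out), sprintf("%g%%", out))
  }
  k <- length(edges) - 1L
  labels <- sprintf("%s-%s", pct(edges[-length(edges)]), pct(edges[-1]))
  if (edges[1] == 0) labels[1] <- sprintf("<%s", pct(edges[2]))
  if (edges[length(edges)] >= 1) labels[k] <- sprintf(">%s", pct(edges[k]))
  function(vaf) {
    idx <- findInterval(vaf, edges, rightmost.closed = TRUE)
    idx[idx < 1L | idx > k] <- NA_integer_
    factor(labels[idx], levels = labels)
  }
}

#' Per-bin confusion counts, sensitivity and PPV
#'
#' Joins the pipeline's positive calls against a truth set by
#' (sample, variant key) and tallies true positives, false negatives and
#' false positives per VAF bin. True positives and false negatives are
#' binned by the truth's expected VAF; false positives (which have no truth
#' VAF by definition) by their observed representative VAF. Undefined
#' ratios (0/0) are reported as `NA`, never as 0.
#'
#' @param passed Tibble of positive calls: `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `rep_vaf`.
#' @param truth Truth set: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `expected_vaf`.
#' @param binning A binning function from [vaf_bins()].
#' @param confidence Confidence level for Clopper-Pearson intervals.
#' @return Tibble with one row per bin: `tp`, `fp`, `fn`, `sensitivity`,
#'   `ppv` and their confidence bounds.
#' @export
confusion_by_bin <- function(passed, truth, binning = vaf_bins(),
                             confidence = 0.95) {
  pid <- paste(passed$sample_id, variant_id(passed$chrom, passed$pos, passed$ref, passed$alt))
  tid <- paste(truth$sample_id, variant_id(truth$chrom, truth$pos, truth$ref, truth$alt))
  if (anyDuplicated(tid)) stop("truth set contains duplicate (sample, key) pairs")

  is_tp <- tid %in% pid
  fp_rows <- !pid %in% tid

  bins_truth <- binning(truth$expected_vaf)
  bins_fp <- binning(passed$rep_vaf[fp_rows])
  lv <- levels(bins_truth)

  tab <- tibble(
    bin = factor(lv, levels = lv),
    tp = as.integer(table(bins_truth[is_tp])[lv]),
    fn = as.integer(table(bins_truth[!is_tp])[lv]),
    fp = as.integer(table(bins_fp)[lv])
  )
  tab[is.na(tab)] <- 0L
  tab$sensitivity <- ifelse(tab$tp + tab$fn > 0, tab$tp / (tab$tp + tab$fn), NA_real_)
  tab$ppv <- ifelse(tab$tp + tab$fp > 0, tab$tp / (tab$tp + tab$fp), NA_real_)
  ci_s <- clopper_pearson(tab$tp, tab$tp + tab$fn, confidence)
  ci_p <- clopper_pearson(tab$tp, tab$tp + tab$fp, confidence)
  tab$sens_lower <- ci_s$lower
  tab$sens_upper <- ci_s$upper
  tab$ppv_lower <- ci_p$lower
  tab$ppv_upper <- ci_p$upper
  tab
}

#' Bona fide truth set from orthogonal sequencing support
#'
#' Admits a variant into the truth set when it meets the primary-platform
#' criteria — VAF above the floor, alternate depth strictly above
#' `min_alt_depth`, passed by at least one caller, passed a reduced set of
#' post-calling filters, and passed the PoN Fisher test — and shows
#' supporting evidence (alt reads strictly above `min_alt_orthogonal`) on
#' the orthogonal platform. Variants uncovered by the orthogonal platform
#' are excluded and counted separately in the `n_uncovered` attribute.
#'
#' @param merged Primary-platform merged variant table.
#' @param verdicts Long verdict table from [apply_all_filters()].
#' @param orthogonal_counts Tibble `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `alt_count` from the orthogonal platform (absent rows =
#'   uncovered).
#' @param min_alt_orthogonal Orthogonal alt-read support must exceed this.
#' @param min_vaf Primary VAF must exceed this.
#' @param min_alt_depth Primary alt depth must exceed this.
#' @param reduced_filters Filter ids making up the reduced filter set.
#' @return Truth-set tibble (`sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `expected_vaf`, `source = "orthogonal"`), with attribute `n_uncovered`.
#' @export
define_bona_fide_orthogonal <- function(merged, verdicts, orthogonal_counts,
                                        min_alt_orthogonal = 5L,
                                        min_vaf = 0.001, min_alt_depth = 5L,
                                        reduced_filters = c("varscan_fp", "strand_support")) {
  merged <- mutate(merged, variant_id = variant_id(chrom, pos, ref, alt))
  need <- c(reduced_filters, "pon_fisher")
  filt_ok <- verdicts %>%
    filter(filter_id %in% need) %>%
    group_by(sample_id, variant_id) %>%
    summarise(ok = all(passed), .groups = "drop")

  cand <- merged %>%
    filter(
      rep_vaf > min_vaf,
      rep_alt_depth > min_alt_depth,
      n_callers_passed >= 1L
    ) %>%
    left_join(filt_ok, by = c("sample_id", "variant_id")) %>%
    filter(!is.na(ok) & ok)

  orth <- mutate(orthogonal_counts,
    variant_id = variant_id(chrom, pos, ref, alt)
  )
  cand <- left_join(cand,
    select(orth, sample_id, variant_id, orth_alt = alt_count),
    by = c("sample_id", "variant_id")
  )
  uncovered <- is.na(cand$orth_alt)
  out <- cand %>%
    filter(!is.na(orth_alt) & orth_alt > min_alt_orthogonal) %>%
    mutate(expected_vaf = rep_vaf, source = "orthogonal") %>%
    select(sample_id, chrom, pos, ref, alt, expected_vaf, source)
  attr(out, "n_uncovered") <- sum(uncovered)
  out
}

#' Classify replicate concordance
#'
#' Given the processed results of two technical replicates, classifies every
#' variant passed in at least one replicate: `"replicated"` when passed in
#' both, otherwise by the first applicable reason for its failure in the
#' counterpart, with precedence `min_vaf` (the 0.1% VAF cut-off), then
#' `pon_filter` (PoN hard or Fisher), then `other_allele_at_site` (the
#' counterpart called a different alternate allele at the same position),
#' then `other`.
#'
#' @param res_a,res_b Per-replicate result lists with elements `merged` and
#'   `filters` (the list returned by [apply_all_filters()]), processed with
#'   identical configuration.
#' @return Tibble with `sample_id`, `variant_id`, `passed_a`, `passed_b`,
#'   `classification`, `detail`.
#' @export
replicate_concordance <- function(res_a, res_b) {
  passed_ids <- function(res) {
    ov <- res$filters$overall
    paste(ov$sample_id[ov$passed], ov$variant_id[ov$passed])
  }
  pa <- passed_ids(res_a)
  pb <- passed_ids(res_b)
  universe <- union(pa, pb)
  if (!length(universe)) {
    return(tibble(
      sample_id = character(), variant_id = character(),
      passed_a = logical(), passed_b = logical(),
      classification = character(), detail = character()
    ))
  }
  parts <- do.call(rbind, strsplit(universe, " ", fixed = TRUE))
  out <- tibble(
    sample_id = parts[, 1], variant_id = parts[, 2],
    passed_a = universe %in% pa, passed_b = universe %in% pb
  )

  classify_one <- function(sample, vid, counterpart) {
    vv <- counterpart$filters$verdicts
    row <- vv[vv$sample_id == sample & vv$variant_id == vid, , drop = FALSE]
    if (nrow(row)) {
      failing <- row$filter_id[!row$passed]
      if ("min_vaf" %in% failing) {
        return(c("min_vaf", "below VAF cut-off in counterpart"))
      }
      if (any(c("pon_hard", "pon_fisher") %in% failing)) {
        return(c("pon_filter", "failed PoN filter in counterpart"))
      }
      if (length(failing)) {
        return(c("other", paste0("failed: ", paste(failing, collapse = ","))))
      }
      return(c("other", "passed filters in counterpart but not flagged as passed"))
    }
    # not called at all in counterpart: another allele at the same site?
    key <- strsplit(vid, ":", fixed = TRUE)[[1]]
    mm <- counterpart$merged
    same_site <- mm$sample_id == sample & mm$chrom == key[1] &
      mm$pos == as.integer(key[2])
    if (any(same_site & variant_id(mm$chrom, mm$pos, mm$ref, mm$alt) != vid)) {
      return(c("other_allele_at_site", "different alternate allele called at site"))
    }
    c("other", "not called in counterpart")
  }

  cls <- matrix("", nrow(out), 2)
  for (i in seq_len(nrow(out))) {
    if (out$passed_a[i] && out$passed_b[i]) {
      cls[i, ] <- c("replicated", "passed in both replicates")
    } else {
      counterpart <- if (out$passed_a[i]) res_b else res_a
      cls[i, ] <- classify_one(out$sample_id[i], out$variant_id[i], counterpart)
    }
  }
  out$classification <- cls[, 1]
  out$detail <- cls[, 2]
  out
}

#' Pearson VAF correlation split at a VAF threshold
#'
#' Computes the correlation between replicate VAF measurements separately
#' for pairs whose mean VAF lies below and at-or-above the split (default
#' 0.2% VAF). Strata with fewer than two pairs yield `NA`.
#'
#' @param vaf_a,vaf_b Paired VAF measurements from two replicates.
#' @param split Mean-VAF threshold separating the strata.
#' @return A list with `corr_below`, `corr_above`, and the per-stratum pair
#'   counts.
#' @export
vaf_correlation_split <- function(vaf_a, vaf_b, split = 0.002) {
  stopifnot(length(vaf_a) == length(vaf_b))
  mean_vaf <- (vaf_a + vaf_b) / 2
  below <- mean_vaf < split
  cor_or_na <- function(sel) {
    if (sum(sel) < 2L) {
      return(NA_real_)
    }
    stats::cor(vaf_a[sel], vaf_b[sel], method = "pearson")
  }
  list(
    corr_below = cor_or_na(below),
    corr_above = cor_or_na(!below),
    n_below = sum(below),
    n_above = sum(!below)
  )
}

#' Per-bin PPV improvement from filtering
#'
#' Compares the positive predictive value of the pre-filter call set
#' (consensus-passed variants) against the post-filter set in each VAF bin
#' and reports whether filtering improved it. In bins where the pre-filter
#' PPV is already 1 (no false positives existed — as in the top VAF bin,
#' where the intrinsic error range produces none), the requirement is that
#' it stays 1; bins emptied by filtering count as improved only if they
#' contained no truth variants.
#'
#' @param pre,post Positive call sets (as for [confusion_by_bin()]).
#' @param truth Truth set.
#' @param binning Binning function.
#' @param min_positives Bins with fewer pre-filter positives are not
#'   assessed.
#' @return Tibble per bin: counts, `ppv_pre`, `ppv_post`, `assessed`,
#'   `improved`.
#' @export
ppv_improvement <- function(pre, post, truth, binning = vaf_bins(),
                            min_positives = 10L) {
  cb_pre <- confusion_by_bin(pre, truth, binning)
  cb_post <- confusion_by_bin(post, truth, binning)
  out <- tibble(
    bin = cb_pre$bin,
    positives_pre = cb_pre$tp + cb_pre$fp,
    positives_post = cb_post$tp + cb_post$fp,
    truth_n = cb_pre$tp + cb_pre$fn,
    ppv_pre = cb_pre$ppv,
    ppv_post = cb_post$ppv
  )
  out$assessed <- out$positives_pre >= min_positives
  out$improved <- ifelse(!out$assessed, NA,
    ifelse(out$positives_post == 0,
      out$truth_n == 0,
      ifelse(out$ppv_pre < 1,
        out$ppv_post > out$ppv_pre,
        out$ppv_post == 1
      )
    )
  )
  out
}
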