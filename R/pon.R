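#' Panel-wide Bonferroni significance threshold
#'
#' The PoN Fisher test is corrected for multiple testing across every base
#' pair of the capture panel: the family-wise error rate `alpha` is divided
#' by the panel size in base pairs. For a 23 650 bp panel at `alpha = 0.05`
#' this gives the 2.1e-6 threshold used throughout.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param panel_bp Panel capture size in base pairs (positive integer).
#' @return The per-site significance threshold `alpha / panel_bp`.
#' @examples
#' bonferroni_threshold(0.05, 23650)
#' @export
bonferroni_threshold <- function(alpha, panel_bp) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(panel_bp) || panel_bp < 1) {
    stop("panel_bp must be a positive integer")
  }
  alpha / panel_bp
}

#' Derive the panel size in base pairs from a BED file
#'
#' Reads a 0-based half-open BED file, merges overlapping intervals, and
#' returns the total number of covered base pairs.
#'
#' @param path Path to a BED file of panel capture regions.
#' @return Total merged interval length in base pairs.
#' @export
panel_bp_from_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
}

#' PoN configuration
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param panel_bp Panel capture size in base pairs (default 23650).
#' @param sidedness `"greater"` (default: a variant passes when its alt
#'   fraction significantly exceeds the PoN background) or `"two_sided"`.
#' @param vaf_threshold Hard-filter VAF cutoff (default 0.02).
#' @param min_samples Hard-filter minimum number of PoN samples above the
#'   cutoff (default 2).
#' @param missing_pon What to do at sites without PoN coverage: `"pass"`
#'   (default; the PoN covers the whole panel, so a missing site is outside
#'   it) or `"fail"` (fail closed).
#' @return A list of class `pon_config`.
#' @export
pon_config <- function(alpha = 0.05, panel_bp = 23650,
                       sidedness = c("greater", "two_sided"),
                       vaf_threshold = 0.02, min_samples = 2L,
                       missing_pon = c("pass", "fail")) {
  sidedness <- match.arg(sidedness)
  missing_pon <- match.arg(missing_pon)
  structure(
    list(
      alpha = alpha, panel_bp = panel_bp, sidedness = sidedness,
      threshold = bonferroni_threshold(alpha, panel_bp),
      vaf_threshold = vaf_threshold, min_samples = as.integer(min_samples),
      missing_pon = missing_pon
    ),
    class = "pon_config"
  )
}

#' Pool per-sample PoN counts by site
#'
#' @param pon_counts Long PoN count table with columns `chrom`, `pos`, `ref`,
#'   `alt`, `pon_sample_id`, `alt_count`, `depth`.
#' @return A tibble keyed by variant with `pooled_alt`, `pooled_depth`,
#'   `n_samples`, and `n_over_*` helper columns computed on demand elsewhere.
#' @export
pon_pooled_counts <- function(pon_counts) {
  validate_pon_counts(pon_counts)
  pon_counts %>%
    mutate(variant_id = variant_id(chrom, pos, ref, alt)) %>%
    group_by(variant_id, chrom, pos, ref, alt) %>%
    summarise(
      pooled_alt = sum(alt_count),
      pooled_depth = sum(depth),
      n_samples = n(),
      .groups = "drop"
    )
}

validate_pon_counts <- function(pon_counts) {
  req <- c("chrom", "pos", "ref", "alt", "pon_sample_id", "alt_count", "depth")
  missing <- setdiff(req, names(pon_counts))
  if (length(missing)) {
    stop("PoN count table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(pon_counts$alt_count > pon_counts$depth | pon_counts$alt_count < 0)
  if (length(bad)) {
    stop(sprintf(
      "PoN row %d: alt_count must satisfy 0 <= alt_count <= depth", bad[1L]
    ))
  }
  invisible(pon_counts)
}

#' Hard PoN VAF filter
#'
#' Fails a variant observed with VAF above `vaf_threshold` in at least
#' `min_samples` PoN samples (default: >2% in two or more), replicating the
#' Mutect2-style panel-of-normals filter. PoN samples with zero depth
#' contribute VAF 0; variants without PoN coverage pass with reason
#' `"no PoN coverage"` (or fail, per `config$missing_pon`).
#'
#' @param merged Merged variant table (needs `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param pon_counts Long PoN count table (see [pon_pooled_counts()]).
#' @param config A [pon_config()].
#' @return A verdict tibble: one row per merged variant with `filter_id =
#'   "pon_hard"`, `passed`, `reason`, `n_over` (PoN samples above the cutoff).
#' @export
pon_hard_filter <- function(merged, pon_counts, config = pon_config()) {
  validate_pon_counts(pon_counts)
  over <- pon_counts %>%
    mutate(
      variant_id = variant_id(chrom, pos, ref, alt),
      .vaf = ifelse(depth > 0, alt_count / depth, 0)
    ) %>%
    group_by(variant_id) %>%
    summarise(n_over = sum(.vaf > config$vaf_threshold), .groups = "drop")

  out <- merged %>%
    mutate(variant_id = variant_id(chrom, pos, ref, alt)) %>%
    select(sample_id, variant_id, chrom, pos, ref, alt) %>%
    left_join(over, by = "variant_id")
  covered <- !is.na(out$n_over)
  fails <- covered & out$n_over >= config$min_samples
  out$filter_id <- "pon_hard"
  out$passed <- ifelse(covered, !fails, config$missing_pon == "pass")
  out$reason <- ifelse(!covered, "no PoN coverage",
    ifelse(fails,
      sprintf(
        "VAF > %.3g in %d PoN samples (min %d)",
        config$vaf_threshold, out$n_over, config$min_samples
      ),
      "below PoN recurrence cutoff"
    )
  )
  as_tibble(out)
}

#' One- or two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Exact hypergeometric test comparing the alternate/reference allele split
#' in a sample against the pooled PoN. `sidedness = "greater"` tests whether
#' the sample's alt proportion exceeds the PoN proportion (upper
#' hypergeometric tail); `"two_sided"` sums the probabilities of all tables
#' as or less probable than the observed one (the `fisher.test` convention).
#' All arguments are vectorized. A table of four zeros yields p = 1.
#'
#' @param sample_alt,sample_ref Alt / ref read counts in the sample.
#' @param pon_alt,pon_ref Pooled alt / ref read counts across PoN samples.
#' @param sidedness `"greater"` or `"two_sided"`.
#' @return Numeric vector of exact p-values.
#' @export
fisher_exact <- function(sample_alt, sample_ref, pon_alt, pon_ref,
                         sidedness = c("greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  n <- max(length(sample_alt), length(sample_ref), length(pon_alt), length(pon_ref))
  a <- rep_len(as.numeric(sample_alt), n)
  b <- rep_len(as.numeric(sample_ref), n)
  cc <- rep_len(as.numeric(pon_alt), n)
  d <- rep_len(as.numeric(pon_ref), n)
  if (any(c(a, b, cc, d) < 0, na.rm = TRUE)) stop("counts must be non-negative")

  N <- a + b + cc + d
  K <- a + cc # total alt reads (white balls)
  k <- a + b # sample margin (draws)

  if (sidedness == "greater") {
    # P[X >= a], X ~ Hypergeometric(K alt, N-K ref, k draws)
    p <- phyper(a - 1, K, N - K, k, lower.tail = FALSE)
  } else {
    p <- vapply(seq_len(n), function(i) {
      if (N[i] == 0) {
        return(1)
      }
      support <- max(0, k[i] - (N[i] - K[i])):min(k[i], K[i])
      dens <- dhyper(support, K[i], N[i] - K[i], k[i])
      obs <- dhyper(a[i], K[i], N[i] - K[i], k[i])
      sum(dens[dens <= obs * (1 + 1e-7)])
    }, numeric(1))
  }
  p[N == 0] <- 1
  pmin(p, 1)
}

#' PoN Fisher exact error filter
#'
#' For each merged variant, tests whether the sample's alt-allele proportion
#' significantly exceeds the proportion in the pooled PoN samples, at the
#' panel-wide Bonferroni-corrected threshold. A variant passes when
#' `p < alpha / panel_bp`; otherwise its read support is indistinguishable
#' from the site's background sequencing error and it fails.
#'
#' @inheritParams pon_hard_filter
#' @return A verdict tibble with `filter_id = "pon_fisher"`, `passed`,
#'   `reason`, `p_value`, `threshold`, and the counts used.
#' @export
pon_fisher_filter <- function(merged, pon_counts, config = pon_config()) {
  pooled <- pon_pooled_counts(pon_counts)
  out <- merged %>%
    mutate(variant_id = variant_id(chrom, pos, ref, alt)) %>%
    select(
      sample_id, variant_id, chrom, pos, ref, alt,
      rep_alt_depth, rep_total_depth
    ) %>%
    left_join(
      select(pooled, variant_id, pooled_alt, pooled_depth),
      by = "variant_id"
    )
  covered <- !is.na(out$pooled_depth)
  sample_ref <- pmax(out$rep_total_depth - out$rep_alt_depth, 0)
  pon_ref <- pmax(out$pooled_depth - out$pooled_alt, 0)
  p <- rep(NA_real_, nrow(out))
  if (any(covered)) {
    p[covered] <- fisher_exact(
      out$rep_alt_depth[covered], sample_ref[covered],
      out$pooled_alt[covered], pon_ref[covered],
      sidedness = config$sidedness
    )
  }
  out$filter_id <- "pon_fisher"
  out$p_value <- p
  out$threshold <- config$threshold
  out$passed <- ifelse(covered, p < config$threshold, config$missing_pon == "pass")
  out$reason <- ifelse(!covered, "no PoN coverage",
    ifelse(out$passed,
      "alt fraction exceeds PoN background",
      sprintf("not significantly above PoN background (p = %.3g)", p)
    )
  )
  as_tibble(out)
}

#' Sweep the PoN size and measure truth-variant attrition
#'
#' For each panel-of-normals size, draws subsets of the available PoN samples
#' (full enumeration when the number of combinations is small, seeded uniform
#' sampling beyond `max_combinations`), re-pools the counts, reruns the
#' Fisher filter on a set of known true variants, and reports the mean
#' proportion of true variants *removed* (p >= threshold). At `size =
#' n_pon` the single full-PoN proportion is reproduced exactly.
#'
#' @param pon_counts Long PoN count table.
#' @param truth Table of true variants with sample-level read support:
#'   columns `chrom`, `pos`, `ref`, `alt`, `sample_alt`, `sample_depth`.
#' @param sizes Integer vector of PoN sizes to evaluate.
#' @param config A [pon_config()].
#' @param max_combinations Cap on subsets per size (default 10000).
#' @param seed Seed for subset sampling beyond the cap.
#' @return A tibble with `size`, `n_subsets`, and `prop_removed`.
#' @export
pon_size_sweep <- function(pon_counts, truth, sizes = NULL,
                           config = pon_config(), max_combinations = 10000,
                           seed = 1L) {
  validate_pon_counts(pon_counts)
  if (!nrow(truth)) stop("empty truth set")
  stopifnot(all(c("chrom", "pos", "ref", "alt", "sample_alt", "sample_depth")
  %in% names(truth)))
  samples <- sort(unique(pon_counts$pon_sample_id))
  n_pon <- length(samples)
  if (is.null(sizes)) sizes <- seq_len(n_pon)
  if (any(sizes < 1L | sizes > n_pon)) {
    stop("sizes must lie within [1, number of PoN samples]")
  }

  truth <- mutate(truth, variant_id = variant_id(chrom, pos, ref, alt))
  # site x PoN-sample count matrices aligned to the truth variants
  wide <- pon_counts %>%
    mutate(variant_id = variant_id(chrom, pos, ref, alt)) %>%
    filter(variant_id %in% truth$variant_id)
  alt_m <- matrix(0, nrow = nrow(truth), ncol = n_pon,
    dimnames = list(truth$variant_id, samples)
  )
  dep_m <- alt_m
  ri <- match(wide$variant_id, truth$variant_id)
  ci <- match(wide$pon_sample_id, samples)
  alt_m[cbind(ri, ci)] <- wide$alt_count
  dep_m[cbind(ri, ci)] <- wide$depth

  sample_alt <- truth$sample_alt
  sample_ref <- pmax(truth$sample_depth - truth$sample_alt, 0)
  thr <- config$threshold

  prop_removed_for <- function(cols) {
    pooled_alt <- rowSums(alt_m[, cols, drop = FALSE])
    pooled_dep <- rowSums(dep_m[, cols, drop = FALSE])
    p <- fisher_exact(
      sample_alt, sample_ref, pooled_alt,
      pmax(pooled_dep - pooled_alt, 0), sidedness = config$sidedness
    )
    mean(p >= thr)
  }

  set.seed(seed)
  res <- lapply(sizes, function(k) {
    n_comb <- choose(n_pon, k)
    if (n_comb <= max_combinations) {
      subsets <- utils::combn(n_pon, k, simplify = FALSE)
    } else {
      subsets <- replicate(max_combinations, sort(sample.int(n_pon, k)),
        simplify = FALSE
      )
    }
    props <- vapply(subsets, prop_removed_for, numeric(1))
    tibble(size = k, n_subsets = length(subsets), prop_removed = mean(props))
  })
  bind_rows(res)
}
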