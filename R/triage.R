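#' Possible-germline flag
#'
#' Flags variants whose population allele frequency suggests a germline
#' origin. Only the population-frequency heuristic is applied by default:
#' VAF-based germline inference (~50%/100%) is deliberately not used because
#' high-VAF CH is legitimate.
#'
#' @param gnomad_af Population allele frequencies (`NA` when absent).
#' @param threshold Flag when `gnomad_af > threshold` (default 0.005).
#' @return Logical vector; absent frequencies are never flagged.
#' @export
germline_flag <- function(gnomad_af, threshold = 0.005) {
  !is.na(gnomad_af) & gnomad_af > threshold
}

#' Manual-review heuristics
#'
#' Emits the reasons a variant should be routed to manual review rather
#' than passed outright:
#'
#' * `complex_indel_single_caller` — a length-changing event in which both
#'   alleles span more than one base, supported by a single caller;
#' * `recurrent_not_reported` — present in two or more cohort samples but
#'   absent from both the prior-CH and tumor knowledge lists.
#'
#' @param merged Cohort merged variant table.
#' @param kb A [knowledge_base()].
#' @return Tibble keyed like `merged` with a `review_reasons` column
#'   (comma-separated, empty string when none).
#' @export
review_flags <- function(merged, kb) {
  merged <- mutate(merged, variant_id = variant_id(chrom, pos, ref, alt))
  occ <- cohort_occurrence(merged)
  n_with <- occ$n_samples_with[match(merged$variant_id, occ$variant_id)]

  complex_indel <- nchar(merged$ref) > 1L & nchar(merged$alt) > 1L &
    nchar(merged$ref) != nchar(merged$alt) & merged$n_callers_passed == 1L

  known_ids <- c(
    prior_ch_ids(kb$prior_ch_variants),
    prior_ch_ids(kb$tumor_variants)
  )
  recurrent_novel <- n_with >= 2L & !(merged$variant_id %in% known_ids)

  reasons <- mapply(function(a, b) {
    paste(c(
      if (a) "complex_indel_single_caller" else NULL,
      if (b) "recurrent_not_reported" else NULL
    ), collapse = ",")
  }, complex_indel, recurrent_novel)

  tibble(
    sample_id = merged$sample_id, variant_id = merged$variant_id,
    review_reasons = as.character(reasons)
  )
}

#' Triage variants into pass / review / fail
#'
#' Combines filter verdicts, the germline flag, and the review heuristics
#' into the pipeline's three mutually exclusive output sets. FAIL dominates
#' REVIEW dominates PASS: any failing filter or a germline flag fails the
#' variant; otherwise any review reason routes it to review; otherwise it
#' passes. Driver calls are never blocked by triage — they are reported for
#' all three buckets downstream.
#'
#' @param overall Per-variant overall verdict from [apply_all_filters()]
#'   (`sample_id`, `variant_id`, `passed`, `failing_filters`).
#' @param germline Logical vector aligned with `overall` rows (or a tibble
#'   with `sample_id`, `variant_id`, `germline`).
#' @param review Review-reason tibble from [review_flags()].
#' @return A tibble with `sample_id`, `variant_id`, `bucket` (`"PASS"`,
#'   `"REVIEW"`, `"FAIL"`), `reasons` and `failing_filters`.
#' @export
triage_variants <- function(overall, germline = NULL, review = NULL) {
  out <- as_tibble(overall)
  if (is.null(germline)) {
    out$germline <- FALSE
  } else if (is.data.frame(germline)) {
    out <- left_join(out, germline, by = c("sample_id", "variant_id"))
    out$germline[is.na(out$germline)] <- FALSE
  } else {
    out$germline <- isTRUE_vec(rep_len(germline, nrow(out)))
  }
  if (is.null(review)) {
    out$review_reasons <- ""
  } else {
    out <- left_join(out, review, by = c("sample_id", "variant_id"))
    out$review_reasons[is.na(out$review_reasons)] <- ""
  }

  fail <- !out$passed | out$germline
  review_only <- !fail & nzchar(out$review_reasons)
  out$bucket <- ifelse(fail, "FAIL", ifelse(review_only, "REVIEW", "PASS"))
  out$reasons <- mapply(function(f, g, ff, rr, b) {
    paste(c(
      if (f && nzchar(ff)) paste0("failed_filters:", ff) else NULL,
      if (g) "possible_germline" else NULL,
      if (b != "FAIL" && nzchar(rr)) rr else NULL
    ), collapse = ";")
  }, !out$passed, out$germline, out$failing_filters, out$review_reasons, out$bucket)
  select(out, sample_id, variant_id, bucket, reasons, failing_filters)
}
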