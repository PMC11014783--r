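#' Merge per-caller call sets into consensus variant records
#'
#' Combines the calls of several variant callers for the same sample(s) into
#' one record per distinct (sample, variant key), counting how many callers
#' passed the variant and selecting representative depth/VAF metrics from a
#' single contributing call by caller priority.
#'
#' Duplicate calls from the same caller for the same key are resolved by
#' keeping the higher-alt-depth one (with a warning), tolerating caller
#' quirks. Calls present but caller-filtered are retained in the per-caller
#' `present_*` evidence flags without counting toward `n_callers_passed`.
#' Pindel is excluded from the consensus count by default (it is not a core
#' caller for short events); include it via `consensus_callers`.
#'
#' @param calls A call table as returned by [read_caller_vcf()] (rows from
#'   several callers bound together); alleles must already be trimmed.
#' @param priority Caller priority for representative metrics, best first.
#' @param consensus_callers Callers whose passes count toward
#'   `n_callers_passed`.
#' @return A tibble with one row per (sample_id, chrom, pos, ref, alt):
#'   `n_callers_passed`, per-caller `passed_*` and `present_*` flags,
#'   representative `rep_caller`, `rep_vaf`, `rep_alt_depth`,
#'   `rep_total_depth`, strand counts `fwd_alt`/`rev_alt` and quality fields
#'   from the representative call.
#' @export
merge_calls <- function(calls,
                        priority = c("mutect2", "lofreq2", "vardict", "pindel"),
                        consensus_callers = c("mutect2", "vardict", "lofreq2")) {
  if (!nrow(calls)) {
    return(empty_merged_table(priority))
  }
  stopifnot(all(c(
    "sample_id", "caller_id", "chrom", "pos", "ref", "alt", "passed"
  ) %in% names(calls)))
  for (cc in setdiff(names(empty_call_table()), names(calls))) {
    calls[[cc]] <- NA
  }
  calls <- mutate(calls, variant_id = variant_id(chrom, pos, ref, alt))

  # same caller, same key: keep the higher-alt-depth record
  dup <- calls %>%
    group_by(sample_id, caller_id, variant_id) %>%
    mutate(.ncall = n()) %>%
    ungroup()
  if (any(dup$.ncall > 1L)) {
    warning(sprintf(
      "dropping %d duplicate call(s) from the same caller (kept max alt depth)",
      sum(dup$.ncall > 1L) - n_distinct(dup$variant_id[dup$.ncall > 1L])
    ), call. = FALSE)
    calls <- dup %>%
      group_by(sample_id, caller_id, variant_id) %>%
      slice_max(alt_depth, n = 1L, with_ties = FALSE) %>%
      ungroup() %>%
      select(-".ncall")
  }

  calls <- calls %>%
    mutate(.prio = match(caller_id, priority)) %>%
    arrange(sample_id, variant_id, desc(passed), .prio)

  flags <- calls %>%
    group_by(sample_id, variant_id) %>%
    summarise(
      n_callers_passed = sum(passed & caller_id %in% consensus_callers),
      .groups = "drop"
    )
  for (cl in priority) {
    pf <- calls %>%
      group_by(sample_id, variant_id) %>%
      summarise(
        .passed = any(passed & caller_id == cl),
        .present = any(caller_id == cl),
        .groups = "drop"
      )
    names(pf)[names(pf) == ".passed"] <- paste0("passed_", cl)
    names(pf)[names(pf) == ".present"] <- paste0("present_", cl)
    flags <- left_join(flags, pf, by = c("sample_id", "variant_id"))
  }

  rep_call <- calls %>%
    distinct(sample_id, variant_id, .keep_all = TRUE) %>%
    select(
      sample_id, variant_id, chrom, pos, ref, alt,
      rep_caller = caller_id, rep_vaf = vaf, rep_alt_depth = alt_depth,
      rep_total_depth = total_depth, fwd_alt, rev_alt, rep_qual = qual,
      rep_mapping_quality = mapping_quality, rep_mean_mismatches = mean_mismatches
    )

  inner_join(rep_call, flags, by = c("sample_id", "variant_id")) %>%
    arrange(sample_id, chrom, pos, ref, alt)
}

empty_merged_table <- function(priority = c("mutect2", "lofreq2", "vardict", "pindel")) {
  out <- tibble(
    sample_id = character(), variant_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    rep_caller = character(), rep_vaf = numeric(), rep_alt_depth = integer(),
    rep_total_depth = integer(), fwd_alt = integer(), rev_alt = integer(),
    rep_qual = numeric(), rep_mapping_quality = numeric(),
    rep_mean_mismatches = numeric(), n_callers_passed = integer()
  )
  for (cl in priority) {
    out[[paste0("passed_", cl)]] <- logical()
    out[[paste0("present_", cl)]] <- logical()
  }
  out
}
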