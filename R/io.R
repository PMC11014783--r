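#' Write a call table as a VCF v4.2 file
#'
#' Serializes one sample's calls from a single caller into a minimal,
#' deterministic VCF v4.2 file carrying per-sample `DP`/`AD`/`AF` FORMAT
#' fields, strand counts and quality metrics in INFO, and the caller pass
#' status in FILTER (`PASS`, or `lowconf` for present-but-filtered calls).
#' Byte-stable for identical inputs.
#'
#' @param calls Call table rows ([read_caller_vcf()] schema) for one
#'   (sample, caller).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path) {
  stopifnot(n_distinct(calls$sample_id) <= 1, n_distinct(calls$caller_id) <= 1)
  sample_id <- if (nrow(calls)) calls$sample_id[1] else "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=chvarfilt-simulator",
    '##INFO=<ID=SAF,Number=A,Type=Integer,Description="Alt reads on forward strand">',
    '##INFO=<ID=SAR,Number=A,Type=Integer,Description="Alt reads on reverse strand">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mean mapping quality">',
    '##INFO=<ID=NM,Number=1,Type=Float,Description="Mean mismatches per read">',
    '##FILTER=<ID=lowconf,Description="Present but failed caller-native filters">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id
    )
  )
  body <- character(0)
  if (nrow(calls)) {
    calls <- arrange(calls, chrom, pos, ref, alt)
    num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
    info <- sprintf(
      "SAF=%s;SAR=%s;MQ=%s;NM=%s",
      num(calls$fwd_alt), num(calls$rev_alt),
      num(calls$mapping_quality), num(calls$mean_mismatches)
    )
    fmt <- sprintf(
      "%s:%s,%s:%s",
      num(calls$total_depth),
      num(calls$total_depth - calls$alt_depth), num(calls$alt_depth),
      num(signif(calls$vaf, 6))
    )
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t%s\t%s\t%s\tDP:AD:AF\t%s",
      calls$chrom, calls$pos, calls$ref, calls$alt,
      num(calls$qual), ifelse(calls$passed, "PASS", "lowconf"), info, fmt
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read tab-separated interchange tables
#'
#' Plain TSV writers/readers for the pipeline's interchange formats
#' (merged variants, PoN counts, metrics, annotations, truth sets).
#' `write_pipeline_tsv` writes without quoting or row names;
#' `read_pipeline_tsv` keeps chromosome names as character.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_pipeline_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pipeline_tsv
#' @export
read_pipeline_tsv <- function(path) {
  out <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  if ("chrom" %in% names(out)) out$chrom <- as.character(out$chrom)
  out
}

#' Emit a simulated cohort as an on-disk fixture bundle
#'
#' Writes per-caller VCFs (one per sample and caller), the PoN count table,
#' read-metrics table, annotation table and truth set of a simulated cohort
#' to a directory. All files are byte-stable under a fixed simulation seed.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
emit_fixtures <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- list(vcfs = character(0))
  for (sid in sort(unique(cohort$calls$sample_id))) {
    for (cl in sort(unique(cohort$calls$caller_id))) {
      sel <- cohort$calls$sample_id == sid & cohort$calls$caller_id == cl
      p <- file.path(dir, sprintf("%s.%s.vcf", sid, cl))
      write_caller_vcf(cohort$calls[sel, , drop = FALSE], p)
      paths$vcfs <- c(paths$vcfs, p)
    }
  }
  paths$pon <- write_pipeline_tsv(cohort$pon_counts, file.path(dir, "pon_counts.tsv"))
  paths$metrics <- write_pipeline_tsv(cohort$metrics, file.path(dir, "metrics.tsv"))
  paths$annotations <- write_pipeline_tsv(
    cohort$annotations, file.path(dir, "annotations.tsv")
  )
  paths$truth <- write_pipeline_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(paths)
}
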