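#' Read one caller's VCF into a normalized call table
#'
#' Reads a VCF v4.2 file produced by (or emulating) a somatic variant caller,
#' splits multi-allelic records, trims alleles to parsimony, and returns one
#' row per (alternate allele) call. The caller's native pass status is taken
#' from the FILTER column: `PASS` or `.` means passed, anything else means
#' present-but-filtered. Symbolic alleles are skipped with a warning.
#'
#' Expected fields (all optional except depth): per-sample `DP` (total depth)
#' and `AD` (allelic depths, Number=R); per-sample `AF` or a VAF derived as
#' `AD[alt]/DP`; INFO `SAF`/`SAR` (strand-split alt read counts, Number=A),
#' `MQ` (mean mapping quality) and `NM` (mean per-read mismatches).
#'
#' @param path Path to the VCF file.
#' @param caller_id One of `"mutect2"`, `"vardict"`, `"lofreq2"`, `"pindel"`.
#' @param sample_id Sample identifier; defaults to the VCF's first sample
#'   name, or the file name when the VCF carries no sample column.
#' @return A tibble of calls with columns `sample_id`, `caller_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `passed`, `total_depth`, `alt_depth`, `vaf`,
#'   `fwd_alt`, `rev_alt`, `qual`, `mapping_quality`, `mean_mismatches`.
#' @export
read_caller_vcf <- function(path, caller_id, sample_id = NULL) {
  caller_id <- match.arg(caller_id, c("mutect2", "vardict", "lofreq2", "pindel"))
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  nrec <- length(rr)
  if (is.null(sample_id)) {
    smp <- colnames(vcf)
    sample_id <- if (length(smp)) smp[1L] else basename(path)
  }
  if (nrec == 0L) {
    return(empty_call_table())
  }

  alt_list <- as.list(lapply(rr$ALT, as.character))
  n_alt <- lengths(alt_list)
  g <- VariantAnnotation::geno(vcf)
  info <- VariantAnnotation::info(vcf)

  get_geno_scalar <- function(field) {
    if (field %in% names(g)) as.vector(g[[field]][, 1L]) else rep(NA, nrec)
  }
  get_geno_list <- function(field) {
    if (field %in% names(g)) lapply(seq_len(nrec), function(i) g[[field]][[i, 1L]]) else NULL
  }
  get_info_list <- function(field) {
    if (field %in% names(info)) as.list(info[[field]]) else NULL
  }

  dp <- suppressWarnings(as.integer(get_geno_scalar("DP")))
  ad <- get_geno_list("AD")
  af <- get_geno_list("AF")
  saf <- get_info_list("SAF")
  sar <- get_info_list("SAR")
  mq <- if ("MQ" %in% names(info)) as.numeric(info$MQ) else rep(NA_real_, nrec)
  nm <- if ("NM" %in% names(info)) as.numeric(info$NM) else rep(NA_real_, nrec)

  filt <- VariantAnnotation::fixed(vcf)$FILTER
  passed_rec <- is.na(filt) | filt %in% c("PASS", ".", "")
  qual_rec <- as.numeric(VariantAnnotation::qual(vcf))

  idx <- rep.int(seq_len(nrec), n_alt)
  j <- sequence(n_alt)

  pick <- function(lst, i, k, default = NA_real_) {
    if (is.null(lst)) return(default)
    v <- lst[[i]]
    if (length(v) >= k && !is.null(v)) as.numeric(v[k]) else default
  }
  alt_depth <- mapply(function(i, k) pick(ad, i, k + 1L), idx, j)
  vaf <- mapply(function(i, k) pick(af, i, k), idx, j)
  fwd <- mapply(function(i, k) pick(saf, i, k), idx, j)
  rev <- mapply(function(i, k) pick(sar, i, k), idx, j)

  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = as.character(rr$REF)[idx],
    alt = unlist(alt_list, use.names = FALSE),
    passed = passed_rec[idx],
    total_depth = dp[idx],
    alt_depth = as.integer(round(alt_depth)),
    vaf = as.numeric(vaf),
    fwd_alt = as.integer(round(fwd)),
    rev_alt = as.integer(round(rev)),
    qual = qual_rec[idx],
    mapping_quality = mq[idx],
    mean_mismatches = nm[idx]
  )

  symbolic <- grepl("[<>\\[\\]*]", out$alt, perl = TRUE)
  if (any(symbolic)) {
    warning(sprintf(
      "%s: skipped %d symbolic allele record(s)", basename(path), sum(symbolic)
    ), call. = FALSE)
    out <- out[!symbolic, , drop = FALSE]
  }
  if (!nrow(out)) {
    return(empty_call_table())
  }

  key <- trim_alleles(out$chrom, out$pos, out$ref, out$alt)
  out$chrom <- key$chrom
  out$pos <- key$pos
  out$ref <- key$ref
  out$alt <- key$alt
  out$vaf <- ifelse(is.na(out$vaf) & out$total_depth > 0,
    out$alt_depth / out$total_depth, out$vaf
  )
  out$sample_id <- sample_id
  out$caller_id <- caller_id
  out[, names(empty_call_table())]
}

empty_call_table <- function() {
  tibble(
    sample_id = character(), caller_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(), passed = logical(),
    total_depth = integer(), alt_depth = integer(), vaf = numeric(),
    fwd_alt = integer(), rev_alt = integer(), qual = numeric(),
    mapping_quality = numeric(), mean_mismatches = numeric()
  )
}
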