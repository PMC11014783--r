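#' Parsimony-trim variant alleles
#'
#' Normalizes a genomic change to its minimal (parsimonious) representation,
#' emulating the allele-trimming step of `bcftools norm`: shared trailing
#' bases are removed first, then shared leading bases are removed while both
#' alleles retain at least one base, advancing the position by one per removed
#' leading base. Reference-aware left-alignment is *not* performed (it would
#' require the genome); inputs are expected to be pre-normalized or trim-only.
#'
#' @param chrom Contig name(s).
#' @param pos 1-based position(s).
#' @param ref,alt Reference / alternate allele strings (A/C/G/T/N).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt` holding the
#'   trimmed keys, one row per input.
#' @examples
#' trim_alleles("chr1", 100, "TCGA", "TCA") # -> chr1:101 CG>C
#' @export
trim_alleles <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)

  if (any(is.na(ref) | is.na(alt) | !nzchar(ref) | !nzchar(alt))) {
    stop("empty or missing allele: ref and alt must be non-empty strings")
  }
  if (any(!grepl("^[ACGTN]+$", ref)) || any(!grepl("^[ACGTN]+$", alt))) {
    stop("alleles must consist of A/C/G/T/N bases only")
  }
  if (any(ref == alt)) {
    stop("ref equals alt: not a variant")
  }
  if (any(pos < 1L | is.na(pos))) {
    stop("pos must be a positive integer")
  }

  # SNVs (the vast majority) are already minimal
  todo <- which(nchar(ref) > 1L | nchar(alt) > 1L)
  for (i in todo) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # right-trim shared suffix while both alleles keep >= 1 base
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # left-trim shared prefix while both alleles keep > 1 base
    p <- pos[i]
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      p <- p + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
    pos[i] <- p
  }
  if (any(ref == alt)) {
    stop("ref equals alt after trimming: not a variant")
  }
  tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Stable string identifier for a variant key
#'
#' @param chrom,pos,ref,alt Components of a (trimmed) variant key.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Split multi-allelic records into per-allele keys
#'
#' Expands a table of VCF-style records (possibly multi-allelic) into one row
#' per alternate allele, trimming each allele independently. Symbolic alleles
#' (`<DEL>`, breakends, `*`) are skipped with a warning. Per-allele depths are
#' apportioned from per-allele fields when present; scalar per-record fields
#' are repeated.
#'
#' @param records A data frame with columns `chrom`, `pos`, `ref` and `alt`,
#'   where `alt` is either a character vector (comma-separated alternates) or
#'   a list column. An optional list column `alt_depth` carries per-allele
#'   alt-supporting read counts aligned with `alt`; any other columns are
#'   repeated per allele.
#' @return A tibble with one row per (record, alternate allele), alleles
#'   trimmed, plus an `alt_index` column giving the allele's ordinal in the
#'   source record.
#' @export
split_multiallelic <- function(records) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(records)))
  alts <- records$alt
  if (!is.list(alts)) alts <- strsplit(as.character(alts), ",", fixed = TRUE)
  ads <- if ("alt_depth" %in% names(records) && is.list(records$alt_depth)) {
    records$alt_depth
  } else if ("alt_depth" %in% names(records)) {
    as.list(records$alt_depth)
  } else {
    NULL
  }

  out <- vector("list", nrow(records))
  other_cols <- setdiff(names(records), c("chrom", "pos", "ref", "alt", "alt_depth"))
  for (i in seq_len(nrow(records))) {
    aa <- alts[[i]]
    symbolic <- grepl("[<>\\[\\]*]", aa, perl = TRUE)
    if (any(symbolic)) {
      warning(sprintf(
        "skipping symbolic allele(s) %s at %s:%d",
        paste(aa[symbolic], collapse = ","), records$chrom[i], records$pos[i]
      ), call. = FALSE)
    }
    keep <- which(!symbolic)
    if (!length(keep)) next
    key <- trim_alleles(records$chrom[i], records$pos[i], records$ref[i], aa[keep])
    key$alt_index <- keep
    if (!is.null(ads)) {
      ad <- ads[[i]]
      key$alt_depth <- if (length(ad) >= max(keep)) ad[keep] else rep(ad[1L], length(keep))
    }
    for (cc in other_cols) key[[cc]] <- records[[cc]][i]
    out[[i]] <- key
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), alt_index = integer()
    ))
  }
  bind_rows(out)
}
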