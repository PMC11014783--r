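#' Validate and coerce an annotation-evidence table
#'
#' Ensures the per-variant annotation table carries the columns the driver
#' rules read, filling absent optional columns with `NA` and coercing
#' unknown consequence labels to `"other"` with a warning.
#'
#' @param ev Data frame with (a subset of) the annotation-evidence columns:
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `protein_pos`,
#'   `cdna_pos`, `exon`, `cosmic_total`, `cosmic_haem`, `cosmic_myeloid`,
#'   `oncokb`, `clinvar`, `ch_source1_count`, `ch_source2_count`, `sift`,
#'   `polyphen`, `gnomad_af`.
#' @return The completed tibble.
#' @export
annotation_evidence <- function(ev) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "gene", "consequence") %in% names(ev)))
  ev <- as_tibble(ev)
  int_cols <- c(
    "protein_pos", "cdna_pos", "exon", "cosmic_total", "cosmic_haem",
    "cosmic_myeloid", "ch_source1_count", "ch_source2_count"
  )
  chr_cols <- c("oncokb", "clinvar", "sift", "polyphen")
  for (cc in int_cols) if (!cc %in% names(ev)) ev[[cc]] <- NA_integer_
  for (cc in chr_cols) if (!cc %in% names(ev)) ev[[cc]] <- "absent"
  if (!"gnomad_af" %in% names(ev)) ev$gnomad_af <- NA_real_
  for (cc in chr_cols) ev[[cc]][is.na(ev[[cc]])] <- "absent"

  unknown <- !ev$consequence %in% annotation_consequences()
  if (any(unknown)) {
    warning(sprintf(
      "%d unknown consequence label(s) coerced to 'other' (e.g. '%s')",
      sum(unknown), ev$consequence[unknown][1]
    ), call. = FALSE)
    ev$consequence[unknown] <- "other"
  }
  bad <- !is.na(ev$protein_pos) & ev$protein_pos < 1
  if (any(bad)) stop("protein_pos must be >= 1 when present")
  ev
}

#' Computational damage evidence
#'
#' "Potentially damaging" means SIFT calls the variant deleterious or
#' PolyPhen calls it probably or possibly damaging.
#'
#' @param sift,polyphen Prediction labels (`"absent"` when missing).
#' @return Logical vector.
#' @export
damaging_evidence <- function(sift, polyphen) {
  sift %in% "deleterious" |
    polyphen %in% c("probably_damaging", "possibly_damaging")
}

#' Driver rules R1-R10
#'
#' Each rule is a pure predicate over an annotation-evidence table `ev`
#' (see [annotation_evidence()]) and a [knowledge_base()] `kb`, returning a
#' logical vector. The cascade is a pure disjunction: a variant is a
#' putative CH driver when any rule matches.
#'
#' * R1 — truncating mutation in a truncating-rule gene
#'   (DNMT3A/TET2/TP53/ASXL1/CHEK2 by default).
#' * R2 — truncating mutation in exon 6 of PPM1D.
#' * R3 — in-frame indel in an in-frame-rule gene (CHEK2).
#' * R4 — missense present in COSMIC >= 10 times overall or >= 5 times in
#'   the haematopoietic-and-lymphoid category.
#' * R5 — variant previously reported as CH (key in the prior-CH list).
#' * R6 — OncoKB oncogenic or likely oncogenic.
#' * R7 — missense at the same residue as a previously reported CH variant,
#'   with damaging evidence.
#' * R8 — missense within 3 amino acids or 9 (cDNA) nucleotides of a CH
#'   hotspot.
#' * R9 — missense inside a configured hotspot region (SRSF2 95; SF3B1
#'   622-626, 662-666, 700-704, 740-742).
#' * R10 — ClinVar pathogenic or likely pathogenic.
#'
#' @param ev Annotation-evidence tibble.
#' @param kb A [knowledge_base()].
#' @return Logical vector, one element per row of `ev`.
#' @name driver_rules
NULL

#' @rdname driver_rules
#' @export
rule_R1_truncating_genes <- function(ev, kb) {
  is_truncating(ev$consequence) & ev$gene %in% kb$truncating_genes
}

#' @rdname driver_rules
#' @export
rule_R2_ppm1d <- function(ev, kb) {
  is_truncating(ev$consequence) & ev$gene %in% "PPM1D" &
    !is.na(ev$exon) & ev$exon == kb$ppm1d_truncating_exon
}

#' @rdname driver_rules
#' @export
rule_R3_chek2_inframe <- function(ev, kb) {
  ev$consequence == "inframe_indel" & ev$gene %in% kb$inframe_genes
}

#' @rdname driver_rules
#' @export
rule_R4_cosmic_missense <- function(ev, kb) {
  ge <- function(x, k) !is.na(x) & x >= k
  ev$consequence == "missense" &
    (ge(ev$cosmic_total, 10L) | ge(ev$cosmic_haem, 5L))
}

#' @rdname driver_rules
#' @export
rule_R5_prior_ch <- function(ev, kb) {
  if (!nrow(kb$prior_ch_variants)) {
    return(rep(FALSE, nrow(ev)))
  }
  ids <- variant_id(
    kb$prior_ch_variants$chrom, kb$prior_ch_variants$pos,
    kb$prior_ch_variants$ref, kb$prior_ch_variants$alt
  )
  variant_id(ev$chrom, ev$pos, ev$ref, ev$alt) %in% ids
}

#' @rdname driver_rules
#' @export
rule_R6_oncokb <- function(ev, kb) {
  ev$oncokb %in% c("oncogenic", "likely_oncogenic")
}

#' @rdname driver_rules
#' @export
rule_R7_same_residue <- function(ev, kb) {
  if (!nrow(kb$prior_ch_residues)) {
    return(rep(FALSE, nrow(ev)))
  }
  res_ids <- paste(kb$prior_ch_residues$gene, kb$prior_ch_residues$protein_pos)
  ev$consequence == "missense" &
    !is.na(ev$protein_pos) &
    paste(ev$gene, ev$protein_pos) %in% res_ids &
    damaging_evidence(ev$sift, ev$polyphen)
}

#' @rdname driver_rules
#' @export
rule_R8_hotspot_proximity <- function(ev, kb) {
  hs <- kb$hotspots
  if (!nrow(hs)) {
    return(rep(FALSE, nrow(ev)))
  }
  vapply(seq_len(nrow(ev)), function(i) {
    if (ev$consequence[i] != "missense") {
      return(FALSE)
    }
    h <- hs[hs$gene == ev$gene[i], , drop = FALSE]
    if (!nrow(h)) {
      return(FALSE)
    }
    near_aa <- !is.na(ev$protein_pos[i]) &
      any(!is.na(h$protein_pos) & abs(ev$protein_pos[i] - h$protein_pos) <= 3)
    near_nt <- !is.na(ev$cdna_pos[i]) &
      any(!is.na(h$cdna_pos) & abs(ev$cdna_pos[i] - h$cdna_pos) <= 9)
    isTRUE(near_aa) || isTRUE(near_nt)
  }, logical(1))
}

#' @rdname driver_rules
#' @export
rule_R9_regions <- function(ev, kb) {
  rr <- kb$region_rules
  if (!nrow(rr)) {
    return(rep(FALSE, nrow(ev)))
  }
  vapply(seq_len(nrow(ev)), function(i) {
    if (ev$consequence[i] != "missense" || is.na(ev$protein_pos[i])) {
      return(FALSE)
    }
    g <- rr[rr$gene == ev$gene[i], , drop = FALSE]
    any(ev$protein_pos[i] >= g$start & ev$protein_pos[i] <= g$end)
  }, logical(1))
}

#' @rdname driver_rules
#' @export
rule_R10_clinvar <- function(ev, kb) {
  ev$clinvar %in% c("pathogenic", "likely_pathogenic")
}

driver_rule_set <- function() {
  list(
    R1 = rule_R1_truncating_genes, R2 = rule_R2_ppm1d,
    R3 = rule_R3_chek2_inframe, R4 = rule_R4_cosmic_missense,
    R5 = rule_R5_prior_ch, R6 = rule_R6_oncokb,
    R7 = rule_R7_same_residue, R8 = rule_R8_hotspot_proximity,
    R9 = rule_R9_regions, R10 = rule_R10_clinvar
  )
}

#' Classify CH putative drivers
#'
#' Evaluates every driver rule R1-R10 (no short-circuiting) on each
#' annotated variant and records which rules matched. A variant is a
#' putative driver when at least one rule matches; the per-rule match
#' columns are the rule provenance and reproduce the decision when
#' re-evaluated.
#'
#' @param ev Annotation-evidence table (see [annotation_evidence()]).
#' @param kb A [knowledge_base()].
#' @param rules Named list of rule predicates; defaults to the full R1-R10
#'   cascade. Removing a rule can never add a driver (pure disjunction).
#' @return A tibble with the variant keys, one logical column per rule,
#'   `matched_rules` (comma-separated, in fixed R1..R10 order) and
#'   `is_putative_driver`.
#' @examples
#' kb <- default_knowledge_base()
#' ev <- annotation_evidence(tibble::tibble(
#'   chrom = "chr17", pos = 76736877, ref = "C", alt = "A",
#'   gene = "SRSF2", consequence = "missense", protein_pos = 95
#' ))
#' classify_driver(ev, kb)$matched_rules
#' @export
classify_driver <- function(ev, kb, rules = driver_rule_set()) {
  ev <- annotation_evidence(ev)
  out <- select(ev, chrom, pos, ref, alt, gene, consequence)
  if ("sample_id" %in% names(ev)) out$sample_id <- ev$sample_id
  for (rn in names(rules)) {
    out[[paste0("rule_", rn)]] <- rules[[rn]](ev, kb)
  }
  rule_cols <- paste0("rule_", names(rules))
  m <- as.matrix(out[, rule_cols, drop = FALSE])
  out$matched_rules <- apply(m, 1L, function(x) {
    paste(names(rules)[x], collapse = ",")
  })
  out$is_putative_driver <- rowSums(m) > 0
  out
}
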