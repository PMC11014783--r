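#' Consequence classes counted as protein-truncating
#'
#' @return Character vector of truncating consequence labels.
#' @export
truncating_consequences <- function() {
  c("stop_gained", "frameshift", "splice_acceptor", "splice_donor")
}

#' Is a consequence protein-truncating?
#'
#' @param consequence Consequence labels (see [annotation_consequences()]).
#' @param truncating Set of consequences counted as truncating; start-lost
#'   and stop-lost are excluded by default, following standard CH annotation
#'   practice.
#' @return Logical vector.
#' @export
is_truncating <- function(consequence, truncating = truncating_consequences()) {
  consequence %in% truncating
}

#' Valid consequence labels for annotation evidence
#' @return Character vector.
#' @export
annotation_consequences <- function() {
  c(
    "stop_gained", "frameshift", "splice_acceptor", "splice_donor",
    "missense", "inframe_indel", "synonymous", "other"
  )
}

#' Hotspot definition predicate
#'
#' A position qualifies as a CH hotspot when it was reported at least five
#' times in the prior CH datasets, or is present in COSMIC at least 25 times
#' overall, at least 20 times in the haematopoietic-and-lymphoid category,
#' or at least 10 times in the myeloid category — and, in every case, has
#' computational evidence of being damaging (SIFT/PolyPhen).
#'
#' @param ch_report_count Occurrences across the prior CH datasets.
#' @param cosmic_total,cosmic_haem,cosmic_myeloid COSMIC occurrence counts.
#' @param damaging Logical: damaging by SIFT or PolyPhen.
#' @return Logical vector.
#' @export
is_hotspot <- function(ch_report_count, cosmic_total, cosmic_haem,
                       cosmic_myeloid, damaging) {
  cnt <- function(x) !is.na(x) & x
  (cnt(ch_report_count >= 5) | cnt(cosmic_total >= 25) |
    cnt(cosmic_haem >= 20) | cnt(cosmic_myeloid >= 10)) & isTRUE_vec(damaging)
}

#' Assemble a CH knowledge base
#'
#' Bundles the curated inputs that drive the putative-driver rule cascade:
#' gene sets for truncating and in-frame rules, the PPM1D truncating exon,
#' prior-CH variant and residue lists, hotspot entries, and missense hotspot
#' regions. Hotspot entries are validated against [is_hotspot()] at load and
#' rejected when they do not satisfy the definition.
#'
#' The real COSMIC/OncoKB/ClinVar/prior-CH exports are user-supplied (they
#' are licensed resources); [default_knowledge_base()] builds a small
#' illustrative bundle for tests and examples.
#'
#' @param truncating_genes Genes whose truncating mutations are drivers.
#' @param ppm1d_truncating_exon Exon of PPM1D whose truncating mutations are
#'   drivers (default 6).
#' @param inframe_genes Genes whose in-frame indels are drivers.
#' @param prior_ch_variants Data frame of previously reported CH variants
#'   (`chrom`, `pos`, `ref`, `alt`, optional per-source counts).
#' @param prior_ch_residues Data frame (`gene`, `protein_pos`) of residues
#'   with previously reported CH variants.
#' @param hotspots Data frame (`gene`, `protein_pos`, `cdna_pos`,
#'   `ch_report_count`, `cosmic_total`, `cosmic_haem`, `cosmic_myeloid`,
#'   `damaging`).
#' @param region_rules Data frame (`gene`, `start`, `end`) of inclusive
#'   protein-position ranges; defaults to SRSF2 95 and SF3B1 622-626,
#'   662-666, 700-704, 740-742.
#' @param tumor_variants Optional data frame of variants reported in tumor
#'   datasets (used by the review heuristics).
#' @return A list of class `knowledge_base`.
#' @export
knowledge_base <- function(truncating_genes = c("DNMT3A", "TET2", "TP53", "ASXL1", "CHEK2"),
                           ppm1d_truncating_exon = 6L,
                           inframe_genes = "CHEK2",
                           prior_ch_variants = NULL,
                           prior_ch_residues = NULL,
                           hotspots = NULL,
                           region_rules = default_region_rules(),
                           tumor_variants = NULL) {
  empty_keys <- tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character()
  )
  if (is.null(prior_ch_variants)) prior_ch_variants <- empty_keys
  if (is.null(tumor_variants)) tumor_variants <- empty_keys
  if (is.null(prior_ch_residues)) {
    prior_ch_residues <- tibble(gene = character(), protein_pos = integer())
  }
  if (is.null(hotspots)) {
    hotspots <- tibble(
      gene = character(), protein_pos = integer(), cdna_pos = integer(),
      ch_report_count = integer(), cosmic_total = integer(),
      cosmic_haem = integer(), cosmic_myeloid = integer(), damaging = logical()
    )
  }
  if (nrow(hotspots)) {
    ok <- is_hotspot(
      hotspots$ch_report_count, hotspots$cosmic_total,
      hotspots$cosmic_haem, hotspots$cosmic_myeloid, hotspots$damaging
    )
    if (any(!ok)) {
      stop(sprintf(
        "%d hotspot entr%s do not satisfy the hotspot definition (first: %s %s)",
        sum(!ok), if (sum(!ok) == 1) "y" else "ies",
        hotspots$gene[!ok][1], hotspots$protein_pos[!ok][1]
      ))
    }
  }
  if (nrow(region_rules) && any(region_rules$start > region_rules$end)) {
    stop("region_rules: every range must have start <= end")
  }
  structure(
    list(
      truncating_genes = truncating_genes,
      ppm1d_truncating_exon = as.integer(ppm1d_truncating_exon),
      inframe_genes = inframe_genes,
      prior_ch_variants = as_tibble(prior_ch_variants),
      prior_ch_residues = as_tibble(prior_ch_residues),
      hotspots = as_tibble(hotspots),
      region_rules = as_tibble(region_rules),
      tumor_variants = as_tibble(tumor_variants)
    ),
    class = "knowledge_base"
  )
}

#' Default missense hotspot regions (SRSF2 and SF3B1)
#' @return Tibble (`gene`, `start`, `end`), inclusive protein positions.
#' @export
default_region_rules <- function() {
  tibble(
    gene = c("SRSF2", "SF3B1", "SF3B1", "SF3B1", "SF3B1"),
    start = c(95L, 622L, 662L, 700L, 740L),
    end = c(95L, 626L, 666L, 704L, 742L)
  )
}

#' Small illustrative knowledge base for tests and examples
#'
#' A synthetic stand-in for the licensed COSMIC/OncoKB/ClinVar/prior-CH
#' exports: a handful of well-known CH hotspot residues with plausible (not
#' authoritative) counts, enough to exercise every rule of the driver
#' cascade.
#'
#' @return A [knowledge_base()].
#' @export
default_knowledge_base <- function() {
  hotspots <- tibble(
    gene = c("DNMT3A", "JAK2", "SRSF2", "IDH2"),
    protein_pos = c(882L, 617L, 95L, 140L),
    cdna_pos = c(2645L, 1849L, 284L, 419L),
    ch_report_count = c(120L, 80L, 25L, 6L),
    cosmic_total = c(900L, 5000L, 400L, 700L),
    cosmic_haem = c(850L, 4900L, 390L, 650L),
    cosmic_myeloid = c(800L, 4800L, 380L, 600L),
    damaging = TRUE
  )
  prior_vars <- tibble(
    chrom = c("chr2", "chr9", "chr17"),
    pos = c(25234373L, 5073770L, 7675088L),
    ref = c("C", "G", "C"),
    alt = c("T", "T", "T"),
    ch_source1_count = c(120L, 80L, 10L),
    ch_source2_count = c(95L, 60L, 4L)
  )
  residues <- tibble(
    gene = c("DNMT3A", "JAK2", "TP53", "TET2"),
    protein_pos = c(882L, 617L, 273L, 1872L)
  )
  knowledge_base(
    prior_ch_variants = prior_vars,
    prior_ch_residues = residues,
    hotspots = hotspots
  )
}

#' Read knowledge-base component tables from TSV files
#'
#' @param hotspots_path,prior_variants_path,prior_residues_path,tumor_variants_path
#'   Paths to TSV files matching the [knowledge_base()] schemas (missing
#'   paths leave the component empty).
#' @param ... Passed on to [knowledge_base()] (gene sets, regions, ...).
#' @return A validated [knowledge_base()].
#' @export
read_knowledge_base <- function(hotspots_path = NULL,
                                prior_variants_path = NULL,
                                prior_residues_path = NULL,
                                tumor_variants_path = NULL, ...) {
  rd <- function(p) if (is.null(p)) NULL else as_tibble(read.delim(p, sep = "\t"))
  knowledge_base(
    hotspots = rd(hotspots_path),
    prior_ch_variants = rd(prior_variants_path),
    prior_ch_residues = rd(prior_residues_path),
    tumor_variants = rd(tumor_variants_path),
    ...
  )
}
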