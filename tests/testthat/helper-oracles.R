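# Independent oracles and fixture builders shared across the suite.

# Brute-force one-sided Fisher p-value: explicit hypergeometric tail sum
# from binomial coefficients (no d/p/qhyper calls).
fisher_oracle_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c # alt-read margin
  k <- a + b # sample margin
  if (N == 0) {
    return(1)
  }
  support <- max(0, k - (N - K)):min(k, K)
  logp <- lchoose(K, support) + lchoose(N - K, k - support) - lchoose(N, k)
  sum(exp(logp[support >= a]))
}

# Two-sided by the sum-of-no-more-probable-tables convention.
fisher_oracle_two_sided <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  k <- a + b
  if (N == 0) {
    return(1)
  }
  support <- max(0, k - (N - K)):min(k, K)
  p <- exp(lchoose(K, support) + lchoose(N - K, k - support) - lchoose(N, k))
  obs <- p[support == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Clopper-Pearson by direct inversion of the binomial tail conditions.
cp_oracle <- function(x, n, confidence = 0.95) {
  alpha <- 1 - confidence
  lower <- if (x == 0) 0 else {
    stats::uniroot(
      function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
      c(1e-12, 1 - 1e-12), tol = 1e-12
    )$root
  }
  upper <- if (x == n) 1 else {
    stats::uniroot(
      function(p) stats::pbinom(x, n, p) - alpha / 2,
      c(1e-12, 1 - 1e-12), tol = 1e-12
    )$root
  }
  c(lower = lower, upper = upper)
}

# Minimal call-row builder with sensible defaults.
make_call <- function(sample_id = "S1", caller_id = "vardict",
                      chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      passed = TRUE, total_depth = 20000L, alt_depth = 200L,
                      vaf = alt_depth / total_depth,
                      fwd_alt = ceiling(alt_depth / 2),
                      rev_alt = alt_depth - ceiling(alt_depth / 2),
                      qual = 100, mapping_quality = 60, mean_mismatches = 0.5) {
  tibble::tibble(
    sample_id = sample_id, caller_id = caller_id, chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt, passed = passed,
    total_depth = as.integer(total_depth), alt_depth = as.integer(alt_depth),
    vaf = vaf, fwd_alt = as.integer(fwd_alt), rev_alt = as.integer(rev_alt),
    qual = qual, mapping_quality = mapping_quality,
    mean_mismatches = mean_mismatches
  )
}

# PoN table with one row per (site, PoN sample) from per-sample alt counts.
make_pon <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                     alt_counts, depths = rep(20000L, length(alt_counts))) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    pon_sample_id = sprintf("PoN%02d", seq_along(alt_counts)),
    alt_count = as.integer(alt_counts), depth = as.integer(depths)
  )
}

# Annotation-evidence row with neutral defaults; override what a test needs.
make_evidence <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                          gene = "DNMT3A", consequence = "missense", ...) {
  base <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, consequence = consequence
  )
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

# A tiny knowledge base exercising every driver rule with known thresholds.
fixture_kb <- function() {
  knowledge_base(
    prior_ch_variants = tibble::tibble(
      chrom = "chr2", pos = 25234373L, ref = "C", alt = "T"
    ),
    prior_ch_residues = tibble::tibble(
      gene = c("DNMT3A", "TP53"), protein_pos = c(882L, 273L)
    ),
    hotspots = tibble::tibble(
      gene = c("DNMT3A", "JAK2"),
      protein_pos = c(882L, 617L),
      cdna_pos = c(2645L, 1849L),
      ch_report_count = c(5L, 0L),
      cosmic_total = c(0L, 0L),
      cosmic_haem = c(0L, 0L),
      cosmic_myeloid = c(0L, 10L),
      damaging = TRUE
    )
  )
}

empty_call_table_for_test <- function() chvarfilt:::empty_call_table()
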