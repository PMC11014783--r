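---
title: "Methods: consensus calling, PoN error filtering and driver annotation for clonal hematopoiesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus calling, PoN error filtering and driver annotation for clonal hematopoiesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chvarfilt)
library(dplyr)
```

## The problem

Clonal hematopoiesis (CH) is the clonal expansion of blood stem and
progenitor cells carrying acquired somatic mutations. Most CH clones sit at
low variant allele fractions (VAF), often well below 2%, where the signal of
a real mutation overlaps the intrinsic error rate of deep targeted
sequencing. Even after UMI-based consensus error correction, per-site error
rates in a targeted panel span roughly 0.02%–5% alt fraction, so a naive
caller either drowns real low-VAF clones in artifacts (high sensitivity, low
positive predictive value) or filters so hard that it misses them.

`chvarfilt` implements the post-calling half of a CH calling workflow: it
consumes per-caller somatic VCFs (Mutect2-, VarDictJava-, LoFreq2- and
optionally Pindel-like), merges them into consensus records, removes
artifacts with a panel-of-normals (PoN) statistical error model plus a suite
of rule-based filters, annotates putative CH drivers from curated knowledge
sources, and triages every variant into **pass**, **review**, or **fail**.
A seeded simulator generates complete synthetic cohorts so that every stage
is testable without any external data.

## The statistical core: PoN Fisher exact error filtering

The PoN is a set of technical control samples (here 27 by default) sequenced
on the same panel. For a variant with $a$ alt and $b$ ref reads in the test
sample, and $c$ alt / $d$ ref reads pooled across all PoN samples at the
same site, the filter computes the one-sided Fisher exact (hypergeometric)
p-value for the sample's alt proportion exceeding the PoN proportion:

$$
P = \Pr\left[X \ge a\right],\qquad
X \sim \mathrm{Hypergeom}(a{+}c,\; b{+}d,\; a{+}b).
$$

A variant is kept only when $P < \alpha / L$, where $L$ is the panel size in
base pairs — a Bonferroni correction over every position at which a test
could be run. With $\alpha = 0.05$ and a 23,650 bp panel this threshold is
$2.1\times10^{-6}$. Because every site is tested against its *own* pooled
background, the filter adapts to the site-specific error structure of the
panel instead of applying one global VAF cutoff.

Two further PoN decisions:

* **Hard PoN filter.** Variants seen at VAF > 2% in two or more individual
  PoN samples fail outright, replicating the classic panel-of-normals
  filter.
* **Sidedness.** The test defaults to one-sided "greater": a variant passes
  only when its alt fraction significantly *exceeds* the background. A
  two-sided variant is available (`pon_config(sidedness = "two_sided")`);
  the one-sided form is the default because the filtering question is
  directional — excess over background — and a two-sided test would also
  reject sites where the sample has significantly *fewer* alt reads than
  the PoN, which is not evidence of a somatic variant.

Missing PoN coverage at a site passes with a recorded `"no PoN coverage"`
reason (configurable to fail closed): a complete PoN covers the whole
panel, so a missing site indicates a position outside it.

## The false-positive filter suite

Each filter is a pure predicate evaluated for every variant (no
short-circuiting), so the verdict set is independent of evaluation order and
every variant carries one verdict per filter, including explicit
`"not applicable"` / `"not evaluable"` outcomes. Defaults:

| filter | rule (fails when) | default |
|---|---|---|
| `min_alt_depth` | alt reads < threshold | 5 |
| `min_vaf` | VAF ≤ threshold (strict `>` to pass) | 0.001 |
| `strand_support` | alt reads on one strand only (or none) | — |
| `long_indel` | indel > threshold bp with single-caller support | 20 bp |
| `varscan_fp` | any read-metric sub-criterion fails | see below |
| `vardict_singleton` | weak VarDict-only call with low quality | see below |
| `recurrence` | > 6% of cohort; or > 3% and never reported | 0.06 / 0.03 |
| `pon_hard` | VAF > 2% in ≥ 2 PoN samples | 0.02 / 2 |
| `pon_fisher` | p ≥ α / panel_bp | 0.05 / 23,650 |

The VarScan-style read-metric sub-criteria (median read position ≥ 0.10,
alt strand fraction within [0.10, 0.90], mismatch-quality-sum difference
≤ 50, incomplete-read fraction ≤ 0.90) reconstruct the documented behaviour
of the cited fpfilter tool; the tool itself names no thresholds in the
source description, so every value is config-exposed via `fp_thresholds()`
and recorded in the run manifest. The incomplete-read-count criterion is
implemented as a configurable maximum fraction of alt reads not fully
spanning the variant, since no formal definition exists. When no metrics
table is supplied at all, the whole filter reports `"not evaluable"` rather
than silently passing judgment; strand support is still enforced by its own
filter.

The VarDict-singleton expression applies only to variants passed
exclusively by VarDictJava and fails them when allele support is weak
(`vaf × depth < 6`) *and* any quality clause holds (MQ < 55 with > 1 mean
mismatches; MQ < 60 with > 2; depth < 10; QUAL < 45). Missing quality
fields make a clause false, never true.

Cohort recurrence is computed *before* filtering and counts each sample
once per variant key regardless of VAF, because the quantity it targets —
panel-wide recurrent artifacts — is a property of the raw call landscape.
The 6% ceiling reflects the most recurrent genuine CH hotspot; anything
above it is overwhelmingly artifact, while the 3% rule additionally demands
prior literature support for moderately recurrent variants.

## Driver classification

`classify_driver()` evaluates ten pure rules (R1–R10) as a disjunction over
annotation evidence joined with a user-supplied knowledge base: truncating
mutations in DNMT3A/TET2/TP53/ASXL1/CHEK2; truncating mutations in PPM1D
exon 6; in-frame indels in CHEK2; missense with COSMIC support (≥ 10
overall or ≥ 5 haematopoietic); presence in prior CH datasets; OncoKB
oncogenic/likely-oncogenic; missense at a previously reported CH residue
with damaging SIFT/PolyPhen evidence; missense within 3 amino acids or 9
cDNA nucleotides of a CH hotspot; missense in the SRSF2 (95) and SF3B1
(622–626, 662–666, 700–704, 740–742) hotspot regions; and ClinVar
pathogenic/likely-pathogenic. Hotspot entries must satisfy the hotspot
definition (≥ 5 CH reports, or COSMIC ≥ 25 overall / ≥ 20 haem / ≥ 10
myeloid, plus damaging evidence) and are validated at knowledge-base load.

Decisions where the published rules leave room:

* *Truncating* = {stop gained, frameshift, splice acceptor, splice donor};
  start-/stop-lost are excluded by default (standard CH practice) and the
  set is configurable.
* *Potentially damaging* = SIFT deleterious OR PolyPhen
  probably/possibly damaging.
* R7 accepts any prior CH variant at the residue (the prior variant need
  not itself be missense); R8's nucleotide distance is cDNA-based, since
  hotspots are transcript-defined.
* Rules are evaluated in fixed order R1→R10 for reproducible provenance,
  but the semantics are order-free: removing any rule can only remove
  drivers, and strengthening evidence can only add matches.

The shipped `default_knowledge_base()` is a small synthetic illustration;
real COSMIC/OncoKB/ClinVar/prior-CH exports are licensed resources and must
be supplied by the user as TSVs (`read_knowledge_base()`).

## Triage

FAIL dominates REVIEW dominates PASS. A variant fails when any filter fails
or when it looks germline (gnomAD AF > 0.005 by default; VAF-based germline
inference is deliberately **off** because high-VAF CH is legitimate). A
surviving variant is routed to review when it is a complex indel (both
alleles > 1 bp, length-changing) with single-caller support, or when it
recurs in ≥ 2 samples without any prior CH/tumor literature support — the
two empirical review heuristics. Driver calls are reported for all three
buckets; review never blocks annotation.

## Benchmarking

Sensitivity and PPV are tallied per VAF bin (default edges 0, 0.1%, 0.4%,
1%, 5%, 100%; lower-inclusive, upper-exclusive, top bin closed). True and
false negatives are binned by the truth's expected VAF; false positives by
their observed VAF (they have no truth VAF by definition). Ratios with zero
denominators are reported as `NA`, never 0. Uncertainty uses exact
Clopper–Pearson intervals computed by beta-quantile inversion, with
endpoints forced to 0 at $x=0$ and 1 at $x=n$.

Replicate concordance classifies variants passed in exactly one of two
technical replicates by the first applicable reason in the counterpart:
`min_vaf` → `pon_filter` → `other_allele_at_site` → `other`. The VAF floor
takes precedence because it is the most mechanical cause of low-VAF
non-replication (small absolute changes in alt reads near the floor).

## The synthetic world

`simulate_cohort()` draws, per panel site, a per-allele error rate from a
two-component mixture: 98% background sites log-uniform on
[1e-5, 2e-4] and 2% artifact-prone sites log-uniform on [2e-4, 5e-2] — the
intrinsic error span of deep UMI-consensus panels. Depths are Poisson
around 20,000×; alt reads are binomial at the site rate (or the true VAF);
strands split binomially. Caller emulation is deliberately threshold-based,
not a reimplementation: VarDict passes at ≥ 3 alt reads, LoFreq at ≥ 5 reads
and VAF ≥ 5e-4, Mutect2 at ≥ 8 reads and VAF ≥ 2e-3. These floors reproduce
the qualitative discordance pattern of real callers at depth (VarDict
dominates singleton low-VAF calls; Mutect2 is least sensitive below 1%).

The default cohort is 40 samples and 27 PoN controls; each sample carries
one true variant at each VAF of {0.2%, 0.5%, 1%, 5%, 20%} at its own
dedicated loci. Two stated-world choices matter for interpreting a green
end-to-end test:

* **Truth loci are clean.** True variants sit at loci whose per-allele
  background error equals the floor of the background range (1e-5,
  `truth_site_error=`). An allele with mid-range background error would be
  called in many cohort samples and would be — by the pipeline's own
  recurrence definition — indistinguishable from a recurrent artifact. Real
  CH drivers survive the recurrence filter for exactly this reason. The
  simulator therefore does not model true variants at error-prone alleles,
  and the end-to-end test says nothing about recovering such variants.
* **Truth variants are known drivers.** The cohort's knowledge base lists
  every simulated true variant as previously reported, as clinical driver
  mutations are in practice; thus only the 6% recurrence ceiling applies to
  them. Novel (unreported) true variants that drift above 3% cohort
  occurrence through background noise would be removed — a real property of
  the filter, not a simulator artifact.

Dilution series are simulated at count level: a source variant at VAF $v$
diluted 1:$r$ has expected VAF $v/(1+r)$; read-level (BAM) mixing is out of
scope. The simulator also does not model sequencing-platform error motifs,
UMI family structure, or mapping artifacts; read-level metrics are drawn at
neutral values, so the VarScan-style filter is exercised but never the
limiting factor in synthetic benchmarks.

## Numerical and design choices

* Fisher p-values come from hypergeometric tail sums (`phyper`); tests
  cross-check them against an independent `lchoose` enumeration oracle for
  every 2×2 table with total ≤ 60 (tolerance 1e-9) and against
  `stats::fisher.test`. Two-sided p-values use the standard
  sum-of-no-more-probable-tables convention with the `(1 + 10^{-7})`
  tie tolerance.
* Allele normalization is parsimony trimming only (suffix first, then
  prefix while both alleles keep ≥ 1 base, advancing the position).
  Reference-aware left-alignment needs the genome and is documented as
  upstream; inputs are "pre-normalized or trim-only".
* Representative metrics for a merged variant come from the
  highest-priority *passing* caller, default order mutect2 > lofreq2 >
  vardict > pindel (Mutect2 depths are assembly-realigned and most
  comparable across sites); the order is configurable. Pindel passes are
  excluded from the consensus count by default.
* Duplicate same-caller records for one key keep the higher alt depth with
  a warning, tolerating caller quirks rather than aborting a run.
* The PoN-size sweep enumerates subsets exhaustively while
  $\binom{n}{k} \le$ `max_combinations` (default 10,000) and switches to
  seeded uniform sampling beyond that, because mid-range subset counts
  (e.g. $\binom{27}{13} \approx 2\times10^7$) are not desk-scale.
* For simulated panels the Bonferroni family is the set of modeled sites
  (`panel_bp = nrow(model)`), since each simulated site stands for one
  testable panel position.
* In PPV-improvement checks, a bin whose pre-filter PPV is already 1
  (no false positives existed — as in the top VAF bin, where the stated
  error range produces none) is required to *stay* at 1; a bin emptied by
  filtering counts as improved only if it contained no truth.

## A worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(sim_cohort_config(seed = 1))
res <- ch_pipeline(
  cohort$calls, cohort$pon_counts, cohort$annotations, cohort$metrics,
  kb = cohort$kb, pon_cfg = pon_config(panel_bp = nrow(cohort$model))
)
passed <- dplyr::inner_join(
  res$merged, dplyr::filter(res$triage, bucket == "PASS"),
  by = c("sample_id", "variant_id")
)
confusion_by_bin(passed, cohort$truth)
ppv_improvement(res$merged, passed, cohort$truth)
```

The same computation, from files, is available through `run_pipeline()` and
the `inst/cli/chvarfilt` script; `scripts/acceptance.R` re-runs it from
scratch under a caller-chosen seed.

## Known limitations

* No BAM/FASTQ handling: pileup metrics, UMI consensus and alignment are
  upstream; the package consumes their tabular outputs.
* The caller emulators are detection-threshold caricatures; they cannot be
  used to study caller-specific artifact modes.
* Recurrence filtering assumes a cohort of unrelated samples; longitudinal
  designs (same subject resequenced) inflate occurrence fractions and need
  a per-subject collapse before filtering.
* The germline heuristic is population-frequency only; rare germline
  variants absent from gnomAD will not be flagged.
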