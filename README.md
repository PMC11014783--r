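# chvarfilt

Post-variant-calling toolkit for detecting **clonal hematopoiesis (CH)** in
deep targeted sequencing. CH mutations are usually present at low variant
allele fractions (VAF), often below 1%, where real clones and sequencing
artifacts occupy the same read-count range. `chvarfilt` takes the outputs of
several somatic variant callers and turns them into a defensible CH call
set for researchers running UMI-consensus targeted panels: epidemiologists
tracking clonal trajectories, hematology labs benchmarking assays, and
pipeline developers who need a fully testable post-calling stage.

## What it does

* **Consensus merging** — reads one VCF per caller per sample
  (Mutect2-, VarDictJava-, LoFreq2-, optionally Pindel-like), trims alleles
  to parsimony, splits multi-allelic records, and merges calls into one
  record per variant with an `n_callers_passed` count and representative
  depth/VAF metrics chosen by caller priority.
* **Panel-of-normals error model** — the statistical core. For a variant
  with `a` alt / `b` ref reads in the sample and `c` alt / `d` ref reads
  pooled across the PoN controls, the one-sided Fisher exact test

  `P = Pr[X >= a],  X ~ Hypergeom(a+c, b+d, a+b)`

  keeps the variant only when `P < alpha / panel_bp` — a Bonferroni
  correction over every base pair of the capture panel (`0.05 / 23650 =
  2.1e-6` for the default panel). A hard filter additionally removes
  variants at VAF > 2% in two or more individual PoN samples.
* **False-positive filter suite** — order-free pure predicates: minimum alt
  depth (5), strict VAF floor (0.1%), single-strand evidence, long indels
  (> 20 bp) without multi-caller support, VarScan-style read-metric
  sub-criteria, a VarDict-only low-VAF/low-quality expression, and cohort
  recurrence rules (> 6% of samples, or > 3% without prior CH literature
  support).
* **Driver classification** — ten deterministic rules over VEP-style
  annotations and a curated knowledge base (truncating events in CH genes,
  COSMIC-supported missense, hotspot proximity within 3 aa / 9 nt, SRSF2
  95 and SF3B1 region rules, OncoKB/ClinVar classes, prior CH reports),
  with per-rule provenance.
* **Triage** — every variant lands in exactly one of `pass`, `review`
  (complex single-caller indels; recurrent never-reported variants), or
  `fail` (failing filters or possible germline by population frequency).
* **Benchmarking** — VAF-binned sensitivity/PPV with exact Clopper–Pearson
  intervals, truth-set construction from orthogonal-platform support,
  replicate-concordance classification, VAF-correlation splits, and a
  PoN-size sweep.
* **Synthetic cohorts** — a seeded simulator (sites with log-uniform
  background and artifact-prone error rates, binomial reads at 20,000×,
  threshold-based caller emulation) that emits VCFs and all auxiliary
  tables, so the whole pipeline is testable offline.

## Worked example

Simulate the default cohort (40 samples, 27 PoN controls, 20,000× depth,
true variants at VAFs 0.2–20%), run the pipeline, and benchmark the PASS
set against the simulator's truth:

```r
library(chvarfilt)
library(dplyr)

cohort <- simulate_cohort(sim_cohort_config(seed = 1))
res <- ch_pipeline(
  cohort$calls, cohort$pon_counts, cohort$annotations, cohort$metrics,
  kb = cohort$kb, pon_cfg = pon_config(panel_bp = nrow(cohort$model))
)
table(res$triage$bucket)
#>  FAIL  PASS
#> 14901   200

passed <- inner_join(
  res$merged, filter(res$triage, bucket == "PASS"),
  by = c("sample_id", "variant_id")
)
confusion_by_bin(passed, cohort$truth)
#>         bin tp fp fn sensitivity ppv sens_lower sens_upper
#> 1     <0.1%  0  0  0          NA  NA         NA         NA
#> 2 0.1%-0.4% 40  0  0           1   1  0.9119027          1
#> 3   0.4%-1% 40  0  0           1   1  0.9119027          1
#> 4     1%-5% 40  0  0           1   1  0.9119027          1
#> 5       >5% 80  0  0           1   1  0.9549360          1
```

Of the 15,101 variants passed by at least one emulated caller, the filters
remove the ~14,900 artifact calls (recurrent panel noise and PoN-matched
background) while recovering all 200 true variants; the confidence bounds
are exact Clopper–Pearson intervals. All 200 passing variants are
classified as putative drivers here because the simulated truth set is, by
construction, listed in the cohort knowledge base (`matched_rules = "R5"`).

File-based runs use `run_pipeline()` (three-way TSV outputs, a per-filter
report, driver calls, and a JSON manifest) or the thin CLI at
`inst/cli/chvarfilt` (`simulate`, `run`, `validate`, `benchmark`
subcommands). The methods vignette
(`vignettes/ch-variant-filtering.Rmd`) documents the model, every
threshold, and what the synthetic world does and does not establish.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
against the installed package: it simulates the default cohort, executes
the full merge → PoN → filter → driver → triage pipeline, prints the
per-bin sensitivity/PPV table and the pre- vs post-filter PPV comparison,
runs the PoN-size sweep across the Fisher-filter transition zone, and
writes the machine-readable report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
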