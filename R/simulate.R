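#' Per-site sequencing error model
#'
#' Draws a seeded per-site alt-read error rate for a synthetic targeted
#' panel. Rates follow a two-component mixture reflecting deep targeted
#' panels: most sites carry a low background error (log-uniform over
#' `background_range`), while a small artifact-prone fraction carries
#' elevated rates (log-uniform over `artifact_range`, spanning roughly
#' 0.02%-5% alt fraction — the intrinsic error range observed across such
#' panels). Sites are laid out on a synthetic nine-gene CH panel.
#'
#' @param n_sites Number of panel sites.
#' @param background_range Background error-rate range (log-uniform).
#' @param artifact_fraction Fraction of artifact-prone sites.
#' @param artifact_range Artifact-prone error-rate range (log-uniform).
#' @param seed Integer seed; fixed seed gives identical models.
#' @return A tibble of sites: `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `error_rate`, `artifact_prone`.
#' @export
sim_site_error_model <- function(n_sites = 2000L,
                                 background_range = c(1e-5, 2e-4),
                                 artifact_fraction = 0.02,
                                 artifact_range = c(2e-4, 5e-2),
                                 seed = 1L) {
  stopifnot(n_sites >= 1, artifact_fraction >= 0, artifact_fraction <= 1)
  set.seed(seed)
  genes <- c(
    "DNMT3A", "TET2", "ASXL1", "TP53", "CHEK2",
    "JAK2", "SRSF2", "SF3B1", "PPM1D"
  )
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  artifact <- runif(n_sites) < artifact_fraction
  log_unif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))
  rate <- ifelse(artifact,
    log_unif(n_sites, artifact_range),
    log_unif(n_sites, background_range)
  )
  tibble(
    chrom = "chr1",
    pos = seq_len(n_sites) * 10L,
    ref = ref,
    alt = unname(alt),
    gene = rep_len(genes, n_sites),
    error_rate = rate,
    artifact_prone = artifact
  )
}

#' Simulate a panel-of-normals count table
#'
#' For every site and PoN sample, draws a sequencing depth (Poisson around
#' the mean) and an alt read count (binomial at the site's error rate).
#'
#' @param model Site table from [sim_site_error_model()].
#' @param n_pon Number of PoN samples.
#' @param depth Mean per-site depth.
#' @param seed Integer seed.
#' @return Long PoN count table: `chrom`, `pos`, `ref`, `alt`,
#'   `pon_sample_id`, `alt_count`, `depth`.
#' @export
simulate_pon <- function(model, n_pon = 27L, depth = 20000, seed = 1L) {
  set.seed(seed)
  n <- nrow(model)
  out <- vector("list", n_pon)
  for (j in seq_len(n_pon)) {
    dp <- rpois(n, depth)
    ac <- rbinom(n, dp, model$error_rate)
    out[[j]] <- tibble(
      chrom = model$chrom, pos = model$pos, ref = model$ref, alt = model$alt,
      pon_sample_id = sprintf("PoN%02d", j), alt_count = ac, depth = dp
    )
  }
  bind_rows(out)
}

#' Emulated caller detection thresholds
#'
#' Threshold-based caller emulation (not a reimplementation): each caller
#' passes a site when the alt read count and observed VAF clear its floor.
#' Defaults reproduce the qualitative caller-discordance pattern of deep CH
#' panels — VarDict calls nearly every low-level event, LoFreq needs a few
#' more reads, Mutect2 is the least sensitive below 1% VAF.
#'
#' @param vardict,lofreq2,mutect2 Per-caller lists with `min_alt` and
#'   `min_vaf`.
#' @return Named list of caller floors.
#' @export
caller_emulation <- function(vardict = list(min_alt = 3L, min_vaf = 0),
                             lofreq2 = list(min_alt = 5L, min_vaf = 5e-4),
                             mutect2 = list(min_alt = 8L, min_vaf = 2e-3)) {
  list(vardict = vardict, lofreq2 = lofreq2, mutect2 = mutect2)
}

#' Simulate one sample's multi-caller call sets
#'
#' Draws per-site depths and alt reads (binomial at the site error rate, or
#' at the true VAF for sites carrying a true variant — a true variant
#' colliding with an artifact-prone site takes precedence, with a message),
#' splits alt reads across strands, and emits per-caller calls wherever a
#' caller's floor is met. Read-level metrics are drawn at neutral values so
#' the read-metric filters are exercised but not the limiting factor.
#'
#' @param model Site table from [sim_site_error_model()].
#' @param true_variants Tibble `chrom`, `pos`, `ref`, `alt`, `vaf` of true
#'   variants for this sample (keys need not be model sites).
#' @param depth Mean per-site depth.
#' @param callers A [caller_emulation()].
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return List with `calls` (per-caller call rows, [read_caller_vcf()]
#'   schema), `metrics` (read-metrics rows for called sites), and `truth`
#'   (this sample's truth entries).
#' @export
simulate_sample <- function(model, true_variants = NULL, depth = 20000,
                            callers = caller_emulation(), seed = 1L,
                            sample_id = "S1") {
  set.seed(seed)
  sites <- select(model, chrom, pos, ref, alt, error_rate)
  sites$p <- sites$error_rate
  sites$is_true <- FALSE
  if (!is.null(true_variants) && nrow(true_variants)) {
    tv_id <- variant_id(
      true_variants$chrom, true_variants$pos,
      true_variants$ref, true_variants$alt
    )
    site_id <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)
    hit <- match(tv_id, site_id)
    coll <- which(!is.na(hit))
    if (length(coll)) {
      if (any(model$artifact_prone[hit[coll]])) {
        message(sprintf(
          "%d true variant(s) collide with artifact-prone sites; true VAF takes precedence",
          sum(model$artifact_prone[hit[coll]])
        ))
      }
      sites$p[hit[coll]] <- true_variants$vaf[coll]
      sites$is_true[hit[coll]] <- TRUE
    }
    new <- which(is.na(hit))
    if (length(new)) {
      sites <- bind_rows(sites, tibble(
        chrom = true_variants$chrom[new], pos = true_variants$pos[new],
        ref = true_variants$ref[new], alt = true_variants$alt[new],
        error_rate = 0, p = true_variants$vaf[new], is_true = TRUE
      ))
    }
  }

  n <- nrow(sites)
  total <- rpois(n, depth)
  alt_n <- rbinom(n, total, sites$p)
  fwd <- rbinom(n, alt_n, 0.5)
  vaf_obs <- ifelse(total > 0, alt_n / total, 0)

  call_rows <- list()
  for (cl in names(callers)) {
    floor_cfg <- callers[[cl]]
    pass <- total > 0 & alt_n >= floor_cfg$min_alt & vaf_obs >= floor_cfg$min_vaf
    if (!any(pass)) next
    idx <- which(pass)
    call_rows[[cl]] <- tibble(
      sample_id = sample_id, caller_id = cl,
      chrom = sites$chrom[idx], pos = sites$pos[idx],
      ref = sites$ref[idx], alt = sites$alt[idx],
      passed = TRUE,
      total_depth = total[idx], alt_depth = alt_n[idx],
      vaf = vaf_obs[idx], fwd_alt = fwd[idx], rev_alt = alt_n[idx] - fwd[idx],
      qual = round(pmin(30 + 4000 * vaf_obs[idx], 250), 1),
      mapping_quality = round(60 - abs(stats::rnorm(length(idx), 0, 0.5)), 2),
      mean_mismatches = round(abs(stats::rnorm(length(idx), 0.5, 0.2)), 2)
    )
  }
  calls <- if (length(call_rows)) bind_rows(call_rows) else empty_call_table()

  called <- unique(calls[, c("chrom", "pos", "ref", "alt")])
  metrics <- if (nrow(called)) {
    tibble(
      sample_id = sample_id,
      chrom = called$chrom, pos = called$pos,
      ref = called$ref, alt = called$alt,
      median_readpos_fraction = round(runif(nrow(called), 0.35, 0.65), 3),
      mmqs_diff = round(abs(stats::rnorm(nrow(called), 5, 5)), 1),
      incomplete_read_fraction = round(runif(nrow(called), 0, 0.2), 3)
    )
  } else {
    tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(),
      median_readpos_fraction = numeric(), mmqs_diff = numeric(),
      incomplete_read_fraction = numeric()
    )
  }

  truth <- sites %>%
    filter(is_true) %>%
    mutate(sample_id = sample_id, expected_vaf = p, source = "simulated") %>%
    select(sample_id, chrom, pos, ref, alt, expected_vaf, source)

  list(calls = calls, metrics = metrics, truth = truth)
}

#' Cohort simulation configuration
#'
#' The default cohort emulates the conditions the pipeline targets: 40
#' blood samples and 27 PoN controls sequenced to a mean consensus depth of
#' 20 000x on a synthetic panel, with each sample carrying one true variant
#' at each VAF of the grid (0.2%, 0.5%, 1%, 5%, 20%) at its own dedicated
#' sites, so no true variant recurs across samples.
#'
#' @param n_samples Number of cohort samples.
#' @param n_pon Number of PoN samples.
#' @param depth Mean per-site depth.
#' @param n_sites Number of panel background/artifact sites.
#' @param vaf_grid True-variant VAFs carried by every sample.
#' @param artifact_fraction,background_range,artifact_range Error-model
#'   parameters (see [sim_site_error_model()]).
#' @param truth_site_error Per-allele background error rate at the loci
#'   carrying true variants (default: the background floor). True CH
#'   variants are modeled at clean consensus positions — alleles whose
#'   substitution error is at the floor of the background range — because
#'   only such loci are compatible with cohort-recurrence filtering: an
#'   allele with mid-range background error is called in many samples and
#'   is, by the pipeline's own definition, indistinguishable from a
#'   recurrent artifact.
#' @param callers A [caller_emulation()].
#' @param seed Master seed; all per-stage seeds derive from it.
#' @return A list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_samples = 40L, n_pon = 27L, depth = 20000,
                              n_sites = 2000L,
                              vaf_grid = c(0.002, 0.005, 0.01, 0.05, 0.2),
                              artifact_fraction = 0.02,
                              background_range = c(1e-5, 2e-4),
                              artifact_range = c(2e-4, 5e-2),
                              truth_site_error = background_range[1],
                              callers = caller_emulation(),
                              seed = 1L) {
  structure(
    list(
      n_samples = as.integer(n_samples), n_pon = as.integer(n_pon),
      depth = depth, n_sites = as.integer(n_sites), vaf_grid = vaf_grid,
      artifact_fraction = artifact_fraction,
      background_range = background_range, artifact_range = artifact_range,
      truth_site_error = truth_site_error,
      callers = callers, seed = as.integer(seed)
    ),
    class = "sim_cohort_config"
  )
}

#' Simulate a full synthetic cohort
#'
#' Builds the site error model (background plus artifact-prone sites, plus
#' one dedicated truth site per sample and grid VAF), simulates the PoN
#' count table and every sample's multi-caller call sets, and assembles the
#' cohort-wide truth set and a synthetic annotation table. Fully
#' deterministic under a fixed seed.
#'
#' @param config A [sim_cohort_config()].
#' @return A list with `model`, `pon_counts`, `calls`, `metrics`, `truth`,
#'   `annotations`, and `config`.
#' @export
simulate_cohort <- function(config = sim_cohort_config()) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 3L + config$n_samples)

  n_truth_sites <- config$n_samples * length(config$vaf_grid)
  model_all <- sim_site_error_model(
    n_sites = config$n_sites + n_truth_sites,
    background_range = config$background_range,
    artifact_fraction = config$artifact_fraction,
    artifact_range = config$artifact_range,
    seed = seeds[1L]
  )
  # dedicated truth sites: clean consensus loci, never artifact-prone
  set.seed(seeds[2L])
  truth_idx <- sample.int(nrow(model_all), n_truth_sites)
  model_all$error_rate[truth_idx] <- config$truth_site_error
  model_all$artifact_prone[truth_idx] <- FALSE

  truth_assign <- tibble(
    site = truth_idx,
    sample_id = rep(sprintf("S%02d", seq_len(config$n_samples)),
      each = length(config$vaf_grid)
    ),
    vaf = rep(config$vaf_grid, times = config$n_samples)
  )

  pon_counts <- simulate_pon(model_all, config$n_pon, config$depth, seed = seeds[3L])

  samples <- vector("list", config$n_samples)
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  for (i in seq_along(sample_ids)) {
    ta <- truth_assign[truth_assign$sample_id == sample_ids[i], , drop = FALSE]
    tv <- tibble(
      chrom = model_all$chrom[ta$site], pos = model_all$pos[ta$site],
      ref = model_all$ref[ta$site], alt = model_all$alt[ta$site],
      vaf = ta$vaf
    )
    samples[[i]] <- simulate_sample(
      model_all, tv, config$depth, config$callers,
      seed = seeds[3L + i], sample_id = sample_ids[i]
    )
  }

  truth <- bind_rows(lapply(samples, `[[`, "truth"))
  # simulated true variants are known CH drivers: the cohort's knowledge
  # base lists them as previously reported, as real driver mutations are
  kb <- knowledge_base(
    prior_ch_variants = distinct(
      truth[, c("chrom", "pos", "ref", "alt")]
    )
  )
  annotations <- model_all %>%
    mutate(
      consequence = ifelse(seq_len(n()) %in% truth_idx, "missense", "other"),
      protein_pos = (pos %/% 10L) %% 500L + 1L,
      gnomad_af = NA_real_
    ) %>%
    select(chrom, pos, ref, alt, gene, consequence, protein_pos, gnomad_af)

  list(
    model = model_all,
    pon_counts = pon_counts,
    calls = bind_rows(lapply(samples, `[[`, "calls")),
    metrics = bind_rows(lapply(samples, `[[`, "metrics")),
    truth = truth,
    annotations = annotations,
    kb = kb,
    config = config
  )
}

#' Simulate a tumor:normal dilution series
#'
#' Dilutes a set of source (tumor) variant VAFs at the given
#' tumor-to-normal ratios — the expected VAF at ratio `r` is
#' `source_vaf / (1 + r)` — and draws the observed read support per diluted
#' variant at the target depth. Each ratio yields one synthetic sample
#' carrying every diluted variant.
#'
#' @param source_vafs Source (undiluted) VAFs of the truth variants.
#' @param ratios Dilution ratios (`r` in 1:`r`); 0 means undiluted.
#' @param depth Mean per-site depth.
#' @param model Optional site error model supplying the variant keys; by
#'   default dedicated keys are generated.
#' @param seed Integer seed.
#' @return A tibble with one row per (ratio, source variant): keys,
#'   `sample_id`, `ratio`, `expected_vaf`, observed `sample_alt`,
#'   `sample_depth`, and `source = "dilution"`.
#' @export
simulate_dilution_series <- function(source_vafs,
                                     ratios = c(10, 100, 1000, 5000),
                                     depth = 20000, model = NULL, seed = 1L) {
  set.seed(seed)
  k <- length(source_vafs)
  if (is.null(model)) {
    keys <- tibble(
      chrom = "chr1", pos = 1000000L + seq_len(k) * 10L,
      ref = "A", alt = "G"
    )
  } else {
    stopifnot(nrow(model) >= k)
    keys <- model[seq_len(k), c("chrom", "pos", "ref", "alt")]
  }
  out <- lapply(seq_along(ratios), function(j) {
    r <- ratios[j]
    ev <- source_vafs / (1 + r)
    dp <- rpois(k, depth)
    alt <- rbinom(k, dp, ev)
    tibble(
      sample_id = sprintf("DIL_1_%d", r),
      chrom = keys$chrom, pos = keys$pos, ref = keys$ref, alt = keys$alt,
      ratio = r, source_vaf = source_vafs, expected_vaf = ev,
      sample_alt = alt, sample_depth = dp, source = "dilution"
    )
  })
  bind_rows(out)
}
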