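#' Run the post-calling pipeline in memory
#'
#' Executes the full post-calling stack on already-loaded tables:
#' consensus merge, PoN hard and Fisher filters, the false-positive filter
#' suite, annotation join, driver-rule classification, germline and review
#' heuristics, and the final three-way triage. This is the computational
#' core behind [run_pipeline()].
#'
#' @param calls Cohort call table (rows from [read_caller_vcf()] or the
#'   simulator, all samples and callers bound together).
#' @param pon_counts Long PoN count table, or `NULL`.
#' @param annotations Optional per-variant annotation table (keys plus
#'   [annotation_evidence()] columns).
#' @param metrics Optional read-metrics table.
#' @param kb A [knowledge_base()]; defaults to an empty one.
#' @param thresholds An [fp_thresholds()].
#' @param pon_cfg A [pon_config()].
#' @param germline_threshold Population-frequency threshold for the
#'   possible-germline flag.
#' @return A list with `merged`, `filters` (verdicts + overall), `drivers`,
#'   `triage`.
#' @export
ch_pipeline <- function(calls, pon_counts = NULL, annotations = NULL,
                        metrics = NULL, kb = knowledge_base(),
                        thresholds = fp_thresholds(),
                        pon_cfg = pon_config(),
                        germline_threshold = 0.005) {
  merged <- merge_calls(calls)
  if (!nrow(merged)) {
    return(list(
      merged = merged,
      filters = list(verdicts = tibble(), overall = tibble()),
      drivers = tibble(), triage = tibble()
    ))
  }
  filters <- apply_all_filters(
    merged,
    pon_counts = pon_counts, metrics = metrics,
    prior_ch = kb$prior_ch_variants,
    thresholds = thresholds, pon_cfg = pon_cfg
  )

  ev <- select(merged, sample_id, chrom, pos, ref, alt)
  if (!is.null(annotations) && nrow(annotations)) {
    ev <- left_join(ev, annotations, by = c("chrom", "pos", "ref", "alt"))
  }
  if (!"gene" %in% names(ev)) ev$gene <- NA_character_
  if (!"consequence" %in% names(ev)) ev$consequence <- "other"
  ev$consequence[is.na(ev$consequence)] <- "other"
  drivers <- classify_driver(ev, kb)

  germ <- tibble(
    sample_id = merged$sample_id,
    variant_id = variant_id(merged$chrom, merged$pos, merged$ref, merged$alt),
    germline = germline_flag(
      if ("gnomad_af" %in% names(ev)) ev$gnomad_af else NA_real_,
      germline_threshold
    )
  )
  review <- review_flags(merged, kb)
  triage <- triage_variants(filters$overall, germ, review)

  list(merged = merged, filters = filters, drivers = drivers, triage = triage)
}

#' Pipeline run configuration
#'
#' Collects every input path and tunable of a file-based pipeline run.
#'
#' @param vcfs Data frame describing caller VCF inputs: columns `path`,
#'   `caller_id`, and optionally `sample_id`.
#' @param pon_path Path to the PoN counts TSV, or `NULL` with
#'   `no_pon = TRUE`.
#' @param annotation_path,metrics_path Optional TSV paths.
#' @param kb A [knowledge_base()].
#' @param panel_bed,panel_bp Panel definition: a BED file or a direct
#'   base-pair count (`panel_bp` overrides).
#' @param thresholds An [fp_thresholds()].
#' @param alpha,sidedness PoN Fisher settings (see [pon_config()]).
#' @param germline_threshold Possible-germline gnomAD AF threshold.
#' @param out_prefix Output path prefix.
#' @param no_pon Allow running without a PoN table (PoN filters report
#'   "not evaluable").
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcfs, pon_path = NULL, annotation_path = NULL,
                       metrics_path = NULL, kb = knowledge_base(),
                       panel_bed = NULL, panel_bp = 23650,
                       thresholds = fp_thresholds(), alpha = 0.05,
                       sidedness = "greater", germline_threshold = 0.005,
                       out_prefix = "chvarfilt", no_pon = FALSE) {
  if (!is.null(panel_bed)) panel_bp <- panel_bp_from_bed(panel_bed)
  structure(
    list(
      vcfs = as_tibble(vcfs), pon_path = pon_path,
      annotation_path = annotation_path, metrics_path = metrics_path,
      kb = kb, panel_bp = panel_bp, thresholds = thresholds,
      alpha = alpha, sidedness = sidedness,
      germline_threshold = germline_threshold,
      out_prefix = out_prefix, no_pon = no_pon
    ),
    class = "run_config"
  )
}

#' Run the pipeline end to end from files
#'
#' Reads the per-caller VCFs and auxiliary tables named in the
#' configuration, executes [ch_pipeline()], and writes the three-way output
#' contract — `<prefix>.pass.tsv`, `<prefix>.review.tsv`,
#' `<prefix>.fail.tsv` — alongside the per-filter report, driver calls, and
#' a machine-readable JSON run manifest (configuration, package version,
#' input digests). Reruns with identical inputs and configuration are
#' byte-identical. Empty inputs produce empty outputs.
#'
#' @param config A [run_config()].
#' @return The [ch_pipeline()] result, invisibly, with an added `outputs`
#'   element naming the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$pon_path) && !config$no_pon) {
    stop("no PoN table configured; set no_pon = TRUE to run without one")
  }
  calls <- bind_rows(lapply(seq_len(nrow(config$vcfs)), function(i) {
    read_caller_vcf(
      config$vcfs$path[i], config$vcfs$caller_id[i],
      sample_id = if ("sample_id" %in% names(config$vcfs)) {
        config$vcfs$sample_id[i]
      } else {
        NULL
      }
    )
  }))
  pon <- if (!is.null(config$pon_path)) read_pipeline_tsv(config$pon_path) else NULL
  ann <- if (!is.null(config$annotation_path)) {
    read_pipeline_tsv(config$annotation_path)
  } else {
    NULL
  }
  metrics <- if (!is.null(config$metrics_path)) {
    read_pipeline_tsv(config$metrics_path)
  } else {
    NULL
  }

  res <- ch_pipeline(
    calls, pon, ann, metrics,
    kb = config$kb, thresholds = config$thresholds,
    pon_cfg = pon_config(
      alpha = config$alpha, panel_bp = config$panel_bp,
      sidedness = config$sidedness
    ),
    germline_threshold = config$germline_threshold
  )

  prefix <- config$out_prefix
  out_tbl <- if (nrow(res$merged)) {
    left_join(res$merged, res$triage, by = c("sample_id", "variant_id"))
  } else {
    res$merged
  }
  outputs <- list()
  for (b in c("PASS", "REVIEW", "FAIL")) {
    p <- sprintf("%s.%s.tsv", prefix, tolower(b))
    sel <- if ("bucket" %in% names(out_tbl)) {
      out_tbl[out_tbl$bucket %in% b, , drop = FALSE]
    } else {
      out_tbl
    }
    write_pipeline_tsv(sel, p)
    outputs[[tolower(b)]] <- p
  }
  outputs$filter_report <- write_pipeline_tsv(
    res$filters$verdicts, sprintf("%s.filter_report.tsv", prefix)
  )
  outputs$drivers <- write_pipeline_tsv(
    res$drivers, sprintf("%s.drivers.tsv", prefix)
  )
  manifest <- list(
    package = "chvarfilt",
    version = as.character(utils::packageVersion("chvarfilt")),
    panel_bp = config$panel_bp,
    alpha = config$alpha,
    sidedness = config$sidedness,
    thresholds = unclass(config$thresholds),
    inputs = list(
      vcfs = config$vcfs$path,
      pon = config$pon_path,
      annotations = config$annotation_path,
      metrics = config$metrics_path
    ),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(
      config$vcfs$path, config$pon_path, config$annotation_path,
      config$metrics_path
    ))))
  )
  outputs$manifest <- sprintf("%s.manifest.json", prefix)
  jsonlite::write_json(manifest, outputs$manifest,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  res$outputs <- outputs
  invisible(res)
}

#' Validate pipeline input files
#'
#' Schema checks on the input bundle: VCF readability, PoN count sanity
#' (`0 <= alt_count <= depth`), annotation consequence labels (unknown
#' labels are a warning — they will be coerced to `"other"`), and PoN/VCF
#' key joinability. Returns a report rather than stopping; rows are
#' `level = "error"` or `"warning"`.
#'
#' @param config A [run_config()].
#' @return Tibble with columns `level`, `input`, `message`; zero rows when
#'   everything is well-formed.
#' @export
validate_inputs <- function(config) {
  report <- list()
  note <- function(level, input, msg) {
    report[[length(report) + 1L]] <<- tibble(
      level = level, input = input, message = msg
    )
  }
  for (i in seq_len(nrow(config$vcfs))) {
    p <- config$vcfs$path[i]
    if (!file.exists(p)) {
      note("error", p, "VCF file does not exist")
      next
    }
    ok <- tryCatch(
      {
        suppressWarnings(VariantAnnotation::scanVcfHeader(p))
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) note("error", p, "not a readable VCF")
  }
  if (!is.null(config$pon_path)) {
    if (!file.exists(config$pon_path)) {
      note("error", config$pon_path, "PoN table does not exist")
    } else {
      pon <- read_pipeline_tsv(config$pon_path)
      miss <- setdiff(
        c("chrom", "pos", "ref", "alt", "pon_sample_id", "alt_count", "depth"),
        names(pon)
      )
      if (length(miss)) {
        note("error", config$pon_path, paste(
          "missing column(s):", paste(miss, collapse = ", ")
        ))
      } else {
        bad <- which(pon$alt_count > pon$depth | pon$alt_count < 0)
        if (length(bad)) {
          note("error", config$pon_path, sprintf(
            "row %d: alt_count outside [0, depth]", bad[1L]
          ))
        }
      }
    }
  }
  if (!is.null(config$annotation_path) && file.exists(config$annotation_path)) {
    ann <- read_pipeline_tsv(config$annotation_path)
    if ("consequence" %in% names(ann)) {
      unknown <- setdiff(unique(ann$consequence), annotation_consequences())
      unknown <- unknown[!is.na(unknown)]
      if (length(unknown)) {
        note("warning", config$annotation_path, paste(
          "unknown consequence label(s) treated as 'other':",
          paste(unknown, collapse = ", ")
        ))
      }
    }
  }
  if (length(report)) bind_rows(report) else {
    tibble(level = character(), input = character(), message = character())
  }
}
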