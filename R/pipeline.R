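#' Pipeline configuration
#'
#' Collects inputs, thresholds and flags for [run_pipeline()]. Inputs may
#' be file paths (`isoform_tsv`, `enhancer_tsv`), in-memory objects
#' (`dataset` from [simulate_apa_dataset()], or an isoform tibble plus an
#' enhancer tibble), or a simulation configuration (`simulate`), in which
#' case the dataset is generated as the first stage and its planted truth
#' is carried through for auditing.
#'
#' @param isoform_tsv,enhancer_tsv Input TSV paths (see
#'   [read_isoform_table()], [read_enhancer_map()]).
#' @param dataset An `apa_sim` object or a long isoform tibble.
#' @param enhancers Tibble `gene_id`, `enhancer` (overrides
#'   `enhancer_tsv`; for simulated data defaults to the planted flags).
#' @param simulate A [sim_config()] (or plain list of its arguments).
#' @param thresholds From [apa_thresholds()].
#' @param min_tpm,min_tpm_level Multi-UTR expression filter (see
#'   [filter_multi_utr()]).
#' @param pseudocount Pseudocount for expression fold changes.
#' @param pooled_pau Use pooled-count PAU (see [compute_pau()]).
#' @param continuity_correction Yates correction in the chi-square tests.
#' @param pau_scale Scale of `pau` columns in TSV input.
#' @param n_strata,strata_upper,n_repeats Stratified resampling settings.
#' @param seed Master seed for every random stage.
#' @param out_dir Output directory for stage TSVs, the manifest and the
#'   log; `NULL` skips writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(isoform_tsv = NULL, enhancer_tsv = NULL,
                            dataset = NULL, enhancers = NULL,
                            simulate = NULL,
                            thresholds = apa_thresholds(),
                            min_tpm = 3,
                            min_tpm_level = c("gene", "isoform"),
                            pseudocount = 0.01,
                            pooled_pau = FALSE,
                            continuity_correction = FALSE,
                            pau_scale = c("fraction", "percent"),
                            n_strata = 13, strata_upper = 1.0,
                            n_repeats = 3, seed = 1L,
                            out_dir = NULL) {
  min_tpm_level <- match.arg(min_tpm_level)
  pau_scale <- match.arg(pau_scale)
  check_number(min_tpm, "min_tpm", lower = 0)
  check_number(pseudocount, "pseudocount", lower = 0)
  check_number(n_strata, "n_strata", 1, Inf, integer = TRUE)
  check_number(strata_upper, "strata_upper")
  check_number(n_repeats, "n_repeats", 1, Inf, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (is.null(isoform_tsv) && is.null(dataset) && is.null(simulate)) {
    abort("one of `isoform_tsv`, `dataset` or `simulate` must be given.",
          class = "apaflow_config_error")
  }
  structure(list(
    isoform_tsv = isoform_tsv, enhancer_tsv = enhancer_tsv,
    dataset = dataset, enhancers = enhancers, simulate = simulate,
    thresholds = thresholds, min_tpm = min_tpm,
    min_tpm_level = min_tpm_level, pseudocount = pseudocount,
    pooled_pau = pooled_pau,
    continuity_correction = continuity_correction,
    pau_scale = pau_scale, n_strata = n_strata,
    strata_upper = strata_upper, n_repeats = n_repeats,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

stage_log <- function(log_lines, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  inform(line)
  c(log_lines, line)
}

#' Run the end-to-end isoform usage / enhancer enrichment pipeline
#'
#' Executes, in order: input loading (or simulation), the multi-UTR
#' expression filter, size-factor normalization, PAU/dPAU computation, the
#' gene-level NB test, the beta-binomial usage test, the four-way
#' classification, per-category enhancer enrichment, and the stratified
#' expression-matched resampling control. When `out_dir` is set, each
#' stage writes its TSV, plus a JSON run manifest (package version, seed,
#' thresholds, flags) and a plain-text log; the run is a deterministic
#' function of the manifest, so [replay_manifest()] reproduces it
#' byte-identically. For simulated input a truth-vs-call confusion matrix
#' is included.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `apa_run`: `size_factors`, `multi_utr_genes`,
#'   `pau`, `de_gene`, `usage`, `su_fc`, `categories`, `enrichment`,
#'   `stratified`, `manifest`, `log`, and for simulated runs `truth` and
#'   `confusion`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config
  logs <- character()
  truth <- NULL

  if (!is.null(cfg$simulate)) {
    simcfg <- if (inherits(cfg$simulate, "sim_config")) cfg$simulate else
      do.call(sim_config, cfg$simulate)
    sim <- simulate_apa_dataset(simcfg)
    iso <- sim$counts; truth <- sim$truth
    logs <- stage_log(logs, "simulate", "%d genes x %d samples (seed %d)",
                      nrow(truth), length(unique(iso$sample)), simcfg$seed)
  } else if (!is.null(cfg$dataset)) {
    iso <- if (inherits(cfg$dataset, "apa_sim")) {
      truth <- cfg$dataset$truth
      cfg$dataset$counts
    } else {
      cfg$dataset
    }
    iso <- validate_isoform_table(iso)
    logs <- stage_log(logs, "load", "%d isoform rows in memory", nrow(iso))
  } else {
    iso <- read_isoform_table(cfg$isoform_tsv, pau_scale = cfg$pau_scale)
    logs <- stage_log(logs, "load", "%d isoform rows from %s",
                      nrow(iso), cfg$isoform_tsv)
  }

  enh <- if (!is.null(cfg$enhancers)) {
    tibble::as_tibble(cfg$enhancers)
  } else if (!is.null(cfg$enhancer_tsv)) {
    read_enhancer_map(cfg$enhancer_tsv)
  } else if (!is.null(truth) && "enhancer" %in% names(truth)) {
    truth[, c("gene_id", "enhancer")]
  } else {
    abort("no enhancer map available (stage: enhancers).",
          class = "apaflow_config_error")
  }

  # gene-level counts and normalization; counts and TPM are each
  # normalized by median-of-ratios factors computed on their own scale
  # (TPM is depth-normalized already, so count factors would misstate its
  # compositional bias)
  gene_sum <- dplyr::summarise(
    dplyr::group_by(iso, .data$gene_id, .data$sample, .data$condition),
    count = sum(.data$count), tpm = sum(.data$tpm), .groups = "drop")
  gene_counts <- gene_sum[, c("gene_id", "sample", "condition", "count")]
  sf <- compute_size_factors(gene_counts)
  sf_tpm <- compute_size_factors(long_to_matrix(gene_sum, "tpm"))
  logs <- stage_log(logs, "normalize",
                    "count factors in [%.3f, %.3f], tpm factors in [%.3f, %.3f]",
                    min(sf$size_factor), max(sf$size_factor),
                    min(sf_tpm$size_factor), max(sf_tpm$size_factor))
  iso <- rescale_tpm(iso, sf_tpm)

  multi <- filter_multi_utr(iso, min_tpm = cfg$min_tpm,
                            level = cfg$min_tpm_level)
  n_multi_all <- dplyr::n_distinct(
    iso$gene_id[iso$isoform_class %in% c("SU", "LU")])
  logs <- stage_log(logs, "filter", "%d of %d multi-UTR genes pass >= %g TPM",
                    nrow(multi), n_multi_all, cfg$min_tpm)
  iso_multi <- dplyr::semi_join(iso, multi, by = "gene_id")

  pau <- compute_pau(iso_multi, basis = "tpm_norm", pooled = cfg$pooled_pau)
  logs <- stage_log(logs, "pau", "%d genes, %d degenerate",
                    nrow(pau), sum(pau$degenerate))

  de <- nb_gene_test(gene_counts, size_factors = sf)
  logs <- stage_log(logs, "de_gene", "%d genes tested, %d flagged",
                    nrow(de), sum(de$flag != "ok"))

  usage <- usage_test(iso_multi)
  logs <- stage_log(logs, "usage", "%d genes tested, %d without coverage",
                    nrow(usage), sum(usage$flag != "ok"))

  sufc <- su_expression_fc(iso_multi, pseudocount = cfg$pseudocount)
  cats <- classify_genes(de, usage, pau, sufc, gene_ids = multi,
                         thresholds = cfg$thresholds)
  tally <- table(cats$category)
  logs <- stage_log(logs, "classify", "%s",
                    paste(names(tally), as.integer(tally),
                          sep = "=", collapse = " "))

  enrich <- enrichment_by_category(cats, enh,
                                   correct = cfg$continuity_correction)
  logs <- stage_log(logs, "enrich", "%d categories vs reference",
                    nrow(enrich) - 1L)

  strat <- tryCatch(
    stratified_enrichment(
      cats, enh, de[, c("gene_id", "log2fc")],
      n_strata = cfg$n_strata, upper = cfg$strata_upper,
      n_repeats = cfg$n_repeats,
      seed = floor(derive_seed(cfg$seed, 271828))),
    apaflow_input_error = function(e) {
      inform(paste("stratified resampling skipped:", conditionMessage(e)))
      NULL
    })
  if (!is.null(strat)) {
    logs <- stage_log(logs, "stratified",
                      "%d repeats, %d matched genes per group",
                      nrow(strat), strat$n_matched[1])
  }

  confusion <- NULL
  if (!is.null(truth)) {
    joined <- dplyr::inner_join(truth, cats[, c("gene_id", "category")],
                                by = "gene_id")
    confusion <- dplyr::count(joined, .data$planted_category,
                              .data$category, name = "n")
  }

  manifest <- list(
    package = "apaflow",
    version = as.character(packageVersion("apaflow")),
    seed = cfg$seed,
    thresholds = cfg$thresholds,
    settings = cfg[c("min_tpm", "min_tpm_level", "pseudocount",
                     "pooled_pau", "continuity_correction", "pau_scale",
                     "n_strata", "strata_upper", "n_repeats")],
    inputs = list(
      isoform_tsv = cfg$isoform_tsv, enhancer_tsv = cfg$enhancer_tsv,
      simulate = if (!is.null(cfg$simulate)) {
        unclass(if (inherits(cfg$simulate, "sim_config")) cfg$simulate
                else do.call(sim_config, cfg$simulate))
      }
    )
  )

  out <- structure(list(
    size_factors = sf, size_factors_tpm = sf_tpm, multi_utr_genes = multi, pau = pau, de_gene = de,
    usage = usage, su_fc = sufc, categories = cats, enrichment = enrich,
    stratified = strat, truth = truth, confusion = confusion,
    manifest = manifest, log = logs
  ), class = "apa_run")

  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_apa_tsv(run$size_factors, p("size_factors.tsv"))
  write_apa_tsv(run$pau, p("pau.tsv"))
  write_apa_tsv(run$de_gene, p("de_gene.tsv"))
  write_apa_tsv(run$usage, p("usage.tsv"))
  write_apa_tsv(run$categories, p("categories.tsv"))
  write_apa_tsv(run$enrichment, p("enrichment.tsv"))
  if (!is.null(run$stratified)) {
    suppressMessages(
      write_apa_tsv(run$stratified, p("stratified.tsv")))
    samples <- dplyr::bind_rows(
      setNames(run$stratified$samples, run$stratified$repeat_id),
      .id = "repeat_id")
    write_apa_tsv(samples, p("stratified_samples.tsv"))
  }
  if (!is.null(run$truth)) {
    write_apa_tsv(run$truth, p("truth.tsv"))
    write_apa_tsv(run$confusion, p("confusion.tsv"))
  }
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(run$log, p("run.log"))
  invisible(run)
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with the configuration recorded in a run
#' manifest; given the same package version the stage tables are
#' reproduced byte-identically.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir Output directory for the replayed run (`NULL` = do not
#'   write).
#' @return The replayed `apa_run`.
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  sim <- if (!is.null(man$inputs$simulate)) {
    do.call(sim_config, man$inputs$simulate)
  }
  cfg <- pipeline_config(
    isoform_tsv = man$inputs$isoform_tsv,
    enhancer_tsv = man$inputs$enhancer_tsv,
    simulate = sim,
    thresholds = do.call(apa_thresholds, man$thresholds),
    min_tpm = man$settings$min_tpm,
    min_tpm_level = man$settings$min_tpm_level,
    pseudocount = man$settings$pseudocount,
    pooled_pau = man$settings$pooled_pau,
    continuity_correction = man$settings$continuity_correction,
    pau_scale = man$settings$pau_scale,
    n_strata = man$settings$n_strata,
    strata_upper = man$settings$strata_upper,
    n_repeats = man$settings$n_repeats,
    seed = man$seed,
    out_dir = out_dir
  )
  run_pipeline(cfg)
}

#' @export
print.apa_run <- function(x, ...) {
  cat("apaflow pipeline run\n")
  cat(" ", length(unique(x$de_gene$gene_id)), "genes;",
      nrow(x$multi_utr_genes), "filtered multi-UTR genes\n")
  tally <- table(x$categories$category)
  cat("  categories:",
      paste(names(tally), as.integer(tally), sep = "=", collapse = " "),
      "\n")
  if (!is.null(x$stratified)) {
    cat(sprintf(
      "  stratified resampling: %d repeats, enhancer fraction %.3f vs %.3f\n",
      nrow(x$stratified), mean(x$stratified$frac_group),
      mean(x$stratified$frac_reference)))
  }
  invisible(x)
}
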