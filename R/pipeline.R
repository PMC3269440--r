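#' Default pipeline configuration
#'
#' A small but complete configuration mirroring the full analysis shape:
#' simulate a nested experiment with duplicate clinical samples and both
#' calibrator types, detection-filter and quantile-normalise, decompose the
#' control-replicate variance by processing level, batch-correct, decompose
#' again, evaluate calibrators, test GC-vulnerability, and run the
#' differential-expression stage before and after correction.
#'
#' @param seed integer seed for the whole run.
#' @return Nested configuration list, suitable for [run_pipeline()] or for
#'   writing as YAML.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      n_probes = 300,
      nesting = c(experiment = 3, run = 2, chip = 2, array = 4),
      level_sd = c(experiment = 0.30, run = 0.15, chip = 0.10),
      residual_sd = 0.20,
      duplicate_plan = 4,
      gc_multiplier = 2,
      expression_coupling = 0.5),
    preprocess = list(filter = TRUE, conf_threshold = 0.95,
                      max_fail_fraction = 0.20, normalize = TRUE),
    variance = list(random_levels = c("experiment", "run"),
                    subset_role = "generic_control", method = "reml"),
    correct = list(method = "combat", batch_levels = c("experiment", "run"),
                   covariates = "group"),
    calibrators = list(batch_level = "run",
                       magnitude_bins = c(0, 0.5, 1, 1.5)),
    probeprops = list(level = "run", gc_cut = 0.55),
    diffexp = list(design = "two_group", fc_min = 1.5, p_max = 0.01))
}

pipeline_schema <- function() {
  list(
    seed = NULL,
    simulate = c("n_probes", "nesting", "level_sd", "residual_sd",
                 "duplicate_plan", "gc_multiplier", "expression_coupling"),
    preprocess = c("filter", "conf_threshold", "max_fail_fraction",
                   "normalize"),
    variance = c("random_levels", "subset_role", "method"),
    correct = c("method", "batch_levels", "covariates"),
    calibrators = c("batch_level", "magnitude_bins"),
    probeprops = c("level", "gc_cut"),
    diffexp = c("design", "fc_min", "p_max"))
}

validate_pipeline_config <- function(config) {
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (section in names(config)) {
    allowed <- schema[[section]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[section]]), allowed)
    if (length(bad))
      stop("unknown configuration key(s) in '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$seed))
    stop("configuration must set a seed", call. = FALSE)
  invisible(config)
}

#' Read or write a pipeline configuration as YAML
#'
#' Named numeric settings (`nesting`, `level_sd`) are stored as YAML maps.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the validated configuration list;
#'   `write_pipeline_config` invisibly returns `path`.
#' @export
read_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  for (nm in c("nesting", "level_sd"))
    if (!is.null(config$simulate[[nm]]))
      config$simulate[[nm]] <- unlist(config$simulate[[nm]])
  validate_pipeline_config(config)
}

#' @param config a configuration list.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  for (nm in c("nesting", "level_sd"))
    if (!is.null(config$simulate[[nm]]))
      config$simulate[[nm]] <- as.list(config$simulate[[nm]])
  yaml::write_yaml(config, path)
  invisible(path)
}

## Derive a bounded per-stage seed from the global one so each stage is
## individually reproducible.
stage_seed <- function(seed, offset)
  (as.integer(seed %% 1000000L)) * 1000L + offset

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, preprocess, decompose, correct, re-decompose,
#' calibrator evaluation, probe-property analysis and differential
#' expression as a deterministic, seeded run. All artifacts are written to
#' `out_dir` as TSV/FASTA plus a machine-readable JSON report; every stage
#' logs its parameters and the MD5 digests of its outputs to `run.log`.
#' Any stage failure aborts with the stage name.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir output directory, created if needed.
#' @param seed optional override of `config$seed`.
#' @return Invisibly, the report list (also written to `report.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("batchscope_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  artifacts <- character(0)
  stage <- function(name, code) {
    say("[stage %s] start", name)
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  report <- list(config = config)

  ## simulate
  sim <- stage("simulate", {
    sc <- config$simulate
    spec <- design_spec(
      n_probes = sc$n_probes, nesting = sc$nesting, level_sd = sc$level_sd,
      residual_sd = sc$residual_sd, duplicate_plan = sc$duplicate_plan,
      gc_model = list(cutoff = 0.55, multiplier = sc$gc_multiplier,
                      levels = NULL),
      expression_coupling = sc$expression_coupling,
      seed = stage_seed(config$seed, 1L))
    out <- simulate_experiment(spec)
    write_expression(out$expression, file.path(out_dir, "expression.tsv"),
                     file.path(out_dir, "detection.tsv"))
    write_sample_sheet(out$samples, file.path(out_dir, "samples.tsv"))
    write_probe_sheet(out$probes, file.path(out_dir, "probes.tsv"))
    write_probe_fasta(out$probes, file.path(out_dir, "probes.fasta"))
    artifacts <<- c(artifacts, file.path(out_dir, c(
      "expression.tsv", "detection.tsv", "samples.tsv", "probes.tsv",
      "probes.fasta")))
    out
  })

  ## preprocess
  pp <- config$preprocess
  m <- sim$expression
  removed <- character(0)
  m <- stage("preprocess", {
    if (isTRUE(pp$filter)) {
      fl <- detection_filter(m, pp$conf_threshold, pp$max_fail_fraction)
      removed <- fl$removed
      m <- fl$expression
    }
    if (isTRUE(pp$normalize)) m <- quantile_normalize(m)
    m
  })
  report$preprocess <- list(n_probes_removed = length(removed),
                            n_probes_retained = nrow(m$values))

  ## variance decomposition pre-correction
  vc <- config$variance
  mspec <- nested_model_spec(vc$random_levels)
  ctrl_ids <- sim$samples$sample_id[sim$samples$role == vc$subset_role]
  dec_pre <- stage("decompose", decompose_variance(
    m, sim$samples, mspec, method = vc$method, subset_samples = ctrl_ids))
  utils::write.table(dec_pre$per_probe,
                     file.path(out_dir, "variance_pre.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, file.path(out_dir, "variance_pre.tsv"))

  ## batch correction
  cc <- config$correct
  corrected <- stage("correct", {
    if (identical(cc$method, "combat"))
      combat_correct(m, sim$samples, cc$batch_levels,
                     covariates = cc$covariates)
    else {
      mm <- m
      for (lv in cc$batch_levels)
        mm <- mean_center(mm, sim$samples, lv)
      mm
    }
  })
  write_expression(corrected, file.path(out_dir, "corrected.tsv"))
  artifacts <- c(artifacts, file.path(out_dir, "corrected.tsv"))

  dec_post <- stage("redecompose", decompose_variance(
    corrected, sim$samples, mspec, method = vc$method,
    subset_samples = ctrl_ids))
  report$variance <- list(pre = dec_pre$summary, post = dec_post$summary)

  ## calibrator evaluation (on uncorrected, normalised data)
  cal <- config$calibrators
  cal_res <- stage("calibrate-eval", {
    shifts <- batch_shifts(m, sim$samples, cal$batch_level)
    ft <- fidelity_table(shifts, cal$magnitude_bins)
    utils::write.table(ft, file.path(out_dir, "fidelity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, file.path(out_dir, "fidelity.tsv"))
    overall <- ft[ft$threshold == 0, , drop = FALSE]
    cmp <- NULL
    if (nrow(overall)) {
      wide <- merge(
        overall[overall$kind == "pooled_control",
                c("pair_id", "r_pct")],
        overall[overall$kind == "generic_control",
                c("pair_id", "r_pct")],
        by = "pair_id", suffixes = c("_pooled", "_generic"))
      if (nrow(wide) >= 2L)
        cmp <- compare_calibrators(wide$r_pct_pooled, wide$r_pct_generic)
    }
    list(table = ft, comparison = cmp, shifts = shifts)
  })
  report$calibrators <- cal_res$comparison

  ## probe properties
  ppr <- config$probeprops
  probeprops_res <- stage("probe-props", {
    sd_vec <- dec_pre$per_probe[[ppr$level]]
    gc <- sim$probes$gc_fraction[match(dec_pre$per_probe$probe_id,
                                       sim$probes$probe_id)]
    enr <- gc_sd_enrichment(sd_vec, gc, gc_cut = ppr$gc_cut)
    pos <- position_sd_association(
      sd_vec, sim$probes[match(dec_pre$per_probe$probe_id,
                               sim$probes$probe_id), ],
      seed = stage_seed(config$seed, 6L))
    list(enrichment = list(statistic = enr$statistic, p = enr$p,
                           reliable = enr$reliable),
         position = pos)
  })
  report$probeprops <- probeprops_res

  ## differential expression pre/post correction
  de_cfg <- config$diffexp
  de_res <- stage("de", {
    pre <- de_test(m, sim$samples, design = de_cfg$design,
                   fc_min = de_cfg$fc_min, p_max = de_cfg$p_max)
    post <- de_test(corrected, sim$samples, design = de_cfg$design,
                    fc_min = de_cfg$fc_min, p_max = de_cfg$p_max)
    conc <- list_concordance(list(pre = significant_probes(pre),
                                  post = significant_probes(post)))
    list(n_pre = sum(pre$significant), n_post = sum(post$significant),
         n_common = conc$n_common)
  })
  report$diffexp <- de_res

  for (a in artifacts)
    say("artifact %s md5=%s", basename(a), unname(tools::md5sum(a)))
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  say("[done] report written to %s", report_path)
  writeLines(log_lines, log_path)
  invisible(report)
}
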