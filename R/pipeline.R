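# End-to-end orchestration: simulate -> fit -> infer -> compare -> report,
# every stage a pure function of (its input files, config), each artifact a
# small diffable CSV.

PIPELINE_FILES <- c(
  design      = "design.csv",
  choices     = "choices.csv",
  truth       = "ground_truth.csv",
  delta_fits  = "delta_fits.csv",
  inferences  = "inferences.csv",
  model_fits  = "model_fits.csv",
  aic_summary = "aic_summary.csv",
  comparisons = "comparisons.csv",
  prevalence  = "strategy_prevalence.csv",
  recovery    = "recovery.csv"
)

#' Build a validated pipeline run configuration
#'
#' @param seed Master seed; expanded into per-stage, per-participant
#'   substreams.
#' @param mixture Cohort mixture (see [default_mixture()]).
#' @param design_config Unambiguous-condition frequency table (see
#'   [default_design_config()]).
#' @param grid_points Grid resolution per parameter axis.
#' @param thresholds Strategy-classification thresholds.
#' @param method Endowment-inversion method, `"exact_inverse"` or
#'   `"uncorrected"`.
#' @param outdir Output directory for artifacts.
#' @return A list of class `hetg_config`.
#' @export
run_config <- function(seed = 1L, mixture = default_mixture(),
                       design_config = default_design_config(),
                       grid_points = 101L,
                       thresholds = default_thresholds(),
                       method = c("exact_inverse", "uncorrected"),
                       outdir = "hetg-run") {
  method <- match.arg(method)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_usage("`seed` must be a single integer")
  }
  if (grid_points < 2L) stop_usage("`grid_points` must be >= 2")
  stopifnot(all(c("strategy", "count", "delta_min", "delta_max", "noise_sd")
                %in% names(mixture)))
  assert_unit_interval(mixture$delta_min, "delta_min")
  assert_unit_interval(mixture$delta_max, "delta_max")
  if (any(mixture$delta_min > mixture$delta_max)) {
    stop_usage("`delta_min` must not exceed `delta_max`")
  }
  structure(
    list(seed = as.integer(seed), mixture = mixture,
         design_config = design_config, grid_points = as.integer(grid_points),
         thresholds = thresholds, method = method, outdir = outdir),
    class = "hetg_config"
  )
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognized fields mirror the [run_config()] arguments; `mixture` is an
#' array of objects and `design_config.unambiguous` an array of
#' (endowment, investment, count) objects. Missing fields take the
#' defaults.
#'
#' @param path JSON file path.
#' @return A `hetg_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  args <- list()
  for (f in c("seed", "grid_points", "method", "outdir")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$mixture)) args$mixture <- as.data.frame(raw$mixture)
  if (!is.null(raw$design_config)) {
    args$design_config <- list(unambiguous = as.data.frame(raw$design_config$unambiguous))
  }
  if (!is.null(raw$thresholds)) args$thresholds <- as.list(raw$thresholds)
  do.call(run_config, args)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, PIPELINE_FILES[[name]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Validate a choice table (file or data.frame)
#'
#' Checks the schema (required columns), value ranges
#' (`0 <= returned <= pot`, reciprocity consistent with returned/pot) and
#' per-participant condition counts (40 unambiguous + 80 ambiguous rows
#' expected; deviations raise a warning, not an error). Malformed rows abort
#' with their row numbers listed.
#'
#' @param x CSV path or data.frame.
#' @return The validated data.frame, invisibly.
#' @export
validate_choices <- function(x) {
  ch <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  required <- c("participant_id", "trial_index", "condition", "investment",
                "pot", "returned", "reciprocity")
  missing <- setdiff(required, names(ch))
  if (length(missing)) {
    stop_usage("choice table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  bad_range <- which(is.na(ch$returned) | ch$returned < -1e-9 |
                       ch$returned > ch$pot + 1e-9)
  bad_cond <- which(!ch$condition %in% c("unambiguous", "ambiguous"))
  bad_recip <- which(abs(ch$reciprocity - ch$returned / ch$pot) > 1e-6)
  bad <- sort(unique(c(bad_range, bad_cond, bad_recip)))
  if (length(bad)) {
    stop_usage("invalid choice rows (row numbers): %s",
               paste(utils::head(bad, 20L), collapse = ", "))
  }
  counts <- table(ch$participant_id, ch$condition)
  if (!all(c("ambiguous", "unambiguous") %in% colnames(counts)) ||
      any(counts[, "unambiguous"] != 40L) || any(counts[, "ambiguous"] != 80L)) {
    warning("condition counts differ from the canonical 40 unambiguous + 80 ambiguous rows per participant",
            call. = FALSE)
  }
  invisible(ch)
}

#' Run the full analysis pipeline
#'
#' Stages: design generation, cohort simulation, fairness-norm fitting,
#' endowment inference, ARS + archetype model fitting, AIC scoring and
#' paired comparison, strategy classification and reporting. Every stage
#' writes its CSV artifact into `config$outdir`; a `manifest.json` records
#' the stage order and file list. The artifact set is a deterministic
#' function of the configuration.
#'
#' @param config A `hetg_config` from [run_config()].
#' @param overwrite Overwrite an existing completed run in `outdir`.
#' @param resume Reuse artifacts already present in `outdir` instead of
#'   recomputing them.
#' @return Invisibly, a list with the in-memory stage results, the
#'   `hetg_report`, and the artifact paths.
#' @export
run_pipeline <- function(config, overwrite = FALSE, resume = FALSE) {
  stopifnot(inherits(config, "hetg_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$outdir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite && !resume) {
    stop_usage("output directory '%s' already holds a run; use overwrite = TRUE or resume = TRUE",
               config$outdir)
  }
  have <- function(name) resume && file.exists(file.path(config$outdir, PIPELINE_FILES[[name]]))
  load_csv <- function(name) read.csv(file.path(config$outdir, PIPELINE_FILES[[name]]),
                                      stringsAsFactors = FALSE)

  design <- if (have("design")) load_csv("design") else {
    d <- generate_session(config$design_config, config$seed)
    write_stage_csv(d, config$outdir, "design")
    d
  }
  if (have("choices") && have("truth")) {
    choices <- load_csv("choices")
    truth <- load_csv("truth")
  } else {
    sim <- simulate_cohort(config$mixture, design, seed = config$seed + 1L)
    choices <- sim$choices
    truth <- sim$truth
    write_stage_csv(choices, config$outdir, "choices")
    write_stage_csv(truth, config$outdir, "truth")
  }
  validate_choices(choices)
  delta_fits <- if (have("delta_fits")) load_csv("delta_fits") else {
    f <- fit_delta_cohort(choices, design, grid_points = config$grid_points)
    write_stage_csv(f, config$outdir, "delta_fits")
    f
  }
  inferences <- if (have("inferences")) load_csv("inferences") else {
    inf <- infer_endowments(choices, design, delta_fits, method = config$method)
    write_stage_csv(inf, config$outdir, "inferences")
    inf
  }
  model_fits <- if (have("model_fits")) load_csv("model_fits") else {
    mf <- fit_ars_cohort(inferences, design, grid_points = config$grid_points)
    write_stage_csv(mf, config$outdir, "model_fits")
    mf
  }
  scores <- score_models(model_fits)
  report <- cohort_report(scores, truth = truth, delta_fits = delta_fits,
                          choices = choices, design = design,
                          inferences = inferences,
                          thresholds = config$thresholds)
  write_stage_csv(report$aic_summary, config$outdir, "aic_summary")
  if (!is.null(report$comparisons)) {
    write_stage_csv(report$comparisons, config$outdir, "comparisons")
  }
  if (!is.null(report$prevalence)) {
    write_stage_csv(report$prevalence, config$outdir, "prevalence")
  }
  if (!is.null(report$recovery)) {
    write_stage_csv(report$recovery, config$outdir, "recovery")
  }
  write_report_md(report, file.path(config$outdir, "report.md"))
  jsonlite::write_json(
    list(package = "hetg",
         version = as.character(utils::packageVersion("hetg")),
         seed = config$seed, method = config$method,
         grid_points = config$grid_points,
         stages = c("design", "simulate", "fit-delta", "infer-endowment",
                    "fit-ars", "compare", "report"),
         files = unname(PIPELINE_FILES)),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(seed = config$seed, grid_points = config$grid_points,
         method = config$method, thresholds = config$thresholds,
         mixture = config$mixture,
         design_config = config$design_config),
    file.path(config$outdir, "config.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(list(design = design, choices = choices, truth = truth,
                 delta_fits = delta_fits, inferences = inferences,
                 scores = scores, report = report,
                 outdir = config$outdir))
}

# Plain-markdown rendering of a cohort report.
write_report_md <- function(report, path) {
  fmt_table <- function(df) {
    df <- as.data.frame(lapply(df, function(col) {
      if (is.numeric(col)) signif(col, 6L) else col
    }))
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    rows <- apply(df, 1L, paste, collapse = " | ")
    c(header, sep, rows, "")
  }
  lines <- c("# Hidden-endowment Trust Game cohort report", "",
             "One-tailed, uncorrected paired t-tests are used deliberately:",
             "a single best-fitting archetype model is expected, so the ARS",
             "model is effectively tested against that one competitor.", "",
             "## Mean AIC by model", "", fmt_table(report$aic_summary))
  if (!is.null(report$comparisons)) {
    lines <- c(lines, "## ARS vs single-strategy models", "",
               fmt_table(report$comparisons))
  }
  if (!is.null(report$prevalence)) {
    lines <- c(lines, "## Strategy prevalence", "", fmt_table(report$prevalence))
  }
  if (!is.null(report$recovery)) {
    lines <- c(lines, "## Recovery vs ground truth", "", fmt_table(report$recovery))
  }
  if (!is.null(report$condition_means)) {
    lines <- c(lines, "## Mean reciprocity by bestowed-trust condition", "",
               fmt_table(report$condition_means))
  }
  if (!is.null(report$variance_explained)) {
    lines <- c(lines, "## Pooled variance explained by the reciprocity model (%)",
               "", fmt_table(report$variance_explained))
  }
  if (length(report$excluded_from_summary)) {
    lines <- c(lines, paste0("Excluded from the AIC summary (perfect fit ",
                             "under some model): ",
                             paste(report$excluded_from_summary, collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}
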