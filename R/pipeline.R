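# End-to-end orchestration: simulate or load a cohort, compute structure
# metrics, preprocess gaze, fit the mixed models, and write every table,
# report, figure and a run manifest.

stage_log <- function(logfile, stage, msg) {
  line <- sprintf("[%s] %s %s", stage, format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: vocabulary structure, semantic networks,
#' gaze preprocessing and filtering, predictor coding and model fitting;
#' writes all intermediate tables, the exclusion ledger, the timecourse
#' table, model reports, figures and a run manifest into `outdir`.  With
#' `simulate = TRUE` (default) the cohort is drawn from `config`;
#' otherwise `inputs` must name the delimited-text input files.
#'
#' @param config An [sim_config()]; also carries the seed.
#' @param outdir Output directory, created if needed.
#' @param simulate Draw a synthetic cohort (default) instead of reading
#'   input files.
#' @param inputs When `simulate = FALSE`, a named list with paths
#'   `checklist`, `vocab_reports`, `norms`, `gaze_samples`,
#'   `trial_metadata`.
#' @param window Analysis window in ms (half-open).
#' @param bin_ms Timecourse bin width.
#' @param min_rating Comprehension filter threshold.
#' @param min_onscreen Track-loss filter threshold.
#' @param smoothing Additive smoothing constant of the log-gaze ratio.
#' @param p_method P-value method, see [fit_condition_model()].
#' @param figures Also render figures (PDF).
#' @return Invisibly, a list with all in-memory results (`cohort` or input
#'   tables, `accuracy`, `filtered`, `models`, `timecourse`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         simulate = TRUE, inputs = NULL,
                         window = c(300, 2000), bin_ms = 50,
                         min_rating = 2, min_onscreen = 0.2,
                         smoothing = 0.5,
                         p_method = c("z", "satterthwaite"),
                         figures = TRUE) {
  p_method <- match.arg(p_method)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lexigaze")),
    seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    config = unclass(config),
    parameters = list(window = window, bin_ms = bin_ms,
                      min_rating = min_rating, min_onscreen = min_onscreen,
                      smoothing = smoothing, p_method = p_method),
    stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  write_manifest()

  if (simulate) {
    stage_log(logfile, "simulate", "drawing synthetic cohort")
    cohort <- simulate_cohort(config)
    checklist <- cohort$checklist
    children <- cohort$children
    norms <- cohort$norms
    density <- cohort$density
    groups <- cohort$groups
    metrics <- cohort$metrics
    trials <- cohort$gaze
    write_sim_truth(cohort$truth, file.path(outdir, "sim_truth.json"))
  } else {
    stopifnot(!is.null(inputs))
    stage_log(logfile, "load", "reading input files")
    checklist <- read_checklist(inputs$checklist)
    children <- read_vocab_reports(inputs$vocab_reports, checklist)
    norms <- read_feature_norms(inputs$norms)
    manifest$input_digests <- as.list(tools::md5sum(unlist(inputs)))
    stage_log(logfile, "vocab", "density and group assignments")
    density <- density_assignments(children, checklist)
    groups <- split_vocab_groups(children)
    stage_log(logfile, "graph", "structure metrics")
    metrics <- structure_metrics(children, norms,
                                 targets = experimental_items()$item)
    trials <- read_gaze_trials(inputs$gaze_samples, inputs$trial_metadata)
    cohort <- NULL
  }
  write_assignments(density, groups, outdir)
  write_structure_metrics(metrics, outdir)

  stage_log(logfile, "gaze", sprintf("%d trials: accuracy and filters",
                                     length(trials)))
  acc <- trial_accuracy_table(trials, window = window, smoothing = smoothing)
  filtered <- filter_trials(acc, min_rating = min_rating,
                            min_onscreen = min_onscreen)
  write_tsv(acc, file.path(outdir, "trial_accuracy.tsv"))
  write_tsv(filtered$exclusions, file.path(outdir, "exclusions.tsv"))
  write_tsv(filtered$ledger, file.path(outdir, "exclusion_ledger.tsv"))
  manifest$stages$gaze <- list(
    trials_in = nrow(acc),
    excluded = sum(filtered$ledger$n_excluded),
    retained = nrow(filtered$retained),
    ledger = filtered$ledger)
  write_manifest()

  stage_log(logfile, "timecourse", "per-condition binned timecourses")
  kept <- trials[vapply(trials, `[[`, character(1), "trial_id") %in%
                   filtered$retained$trial_id]
  tc <- timecourse_by_metric(kept, metrics, density, groups,
                             bin_ms = bin_ms)
  write_tsv(tc, file.path(outdir, "timecourse.tsv"))

  stage_log(logfile, "inference", "mixed-effects models")
  models <- list()
  for (cond in c("unrelated", "related")) {
    des <- code_predictors(filtered$retained, metrics, density, groups,
                           condition = cond)
    models[[paste0(cond, "_all")]] <- fit_condition_model(des, p_method)
    for (grp in c("High", "Low")) {
      dg <- code_predictors(filtered$retained, metrics, density, groups,
                            condition = cond, vocab_group = grp)
      models[[paste0(cond, "_", tolower(grp))]] <-
        fit_group_model(dg, p_method)
    }
  }
  rep_out <- model_report(models, file.path(outdir, "model_report.txt"))
  write_tsv(rep_out$table, file.path(outdir, "model_terms.tsv"))
  write_model_results(models, file.path(outdir, "models.json"))
  manifest$stages$inference <- list(
    models = names(models),
    converged = vapply(models, `[[`, logical(1), "converged"))

  if (figures) {
    stage_log(logfile, "figures", "rendering")
    make_figures(tc, filtered$retained, metrics, density, groups, outdir)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  write_manifest()
  stage_log(logfile, "done", sprintf("%d trials retained, %d models",
                                     nrow(filtered$retained),
                                     length(models)))
  invisible(list(cohort = cohort, checklist = checklist,
                 metrics = metrics, density = density, groups = groups,
                 accuracy = acc, filtered = filtered, models = models,
                 timecourse = tc, manifest = manifest, outdir = outdir))
}

# condition x metric-split grand timecourses in one long table
timecourse_by_metric <- function(trials, metrics, density, groups,
                                 bin_ms = 50) {
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  child <- vapply(trials, `[[`, character(1), "child_id")
  target <- vapply(trials, `[[`, character(1), "target")
  cond <- vapply(trials, `[[`, character(1), "condition")
  item_cat <- setNames(experimental_items()$category,
                       experimental_items()$item)
  dens <- setNames(density$condition,
                   paste(density$child_id, density$category))
  gcc <- setNames(metrics$metrics$gcc, metrics$metrics$child_id)
  dkey <- paste(metrics$degrees$child_id, metrics$degrees$item)
  degree <- setNames(metrics$degrees$degree, dkey)
  splits <- list(
    density = unname(dens[paste(child, item_cat[target])]),
    degree = unname(median_split(as.numeric(degree[paste(child, target)]))),
    gcc = unname(median_split(as.numeric(gcc[child]))))
  out <- list()
  for (metric in names(splits)) {
    sp <- data.frame(trial_id = ids,
                     group = paste(cond, metric, splits[[metric]],
                                   sep = "."),
                     stringsAsFactors = FALSE)
    tc <- grand_timecourse(trials, sp, bin_ms = bin_ms)
    tc$metric <- metric
    parts <- strsplit(tc$group, ".", fixed = TRUE)
    tc$condition <- vapply(parts, `[[`, character(1), 1L)
    tc$level <- vapply(parts, `[[`, character(1), 3L)
    out[[metric]] <- tc[, c("condition", "metric", "level", "bin_start",
                            "state", "proportion", "n_trials")]
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Render timecourse and accuracy figures
#'
#' Timecourse panels show mean target (solid) and distractor (dashed)
#' fixation proportions per 50 ms bin, one row per condition and one
#' column per structure metric, split into high/low metric levels.
#' Accuracy panels show the distribution of trial log-gaze ratios per
#' metric level.
#'
#' @param timecourse Long table from the pipeline's timecourse stage.
#' @param accuracy Retained trial accuracy table.
#' @param metrics,density,groups Cohort structure tables.
#' @param outdir Directory for the PDF files.
#' @return Invisibly, the written paths; with empty inputs a warning is
#'   emitted and nothing is written.
#' @export
make_figures <- function(timecourse, accuracy, metrics, density, groups,
                         outdir) {
  if (nrow(timecourse) == 0L || nrow(accuracy) == 0L) {
    warning("empty tables; no figures rendered", call. = FALSE)
    return(invisible(character(0)))
  }
  p1 <- ggplot2::ggplot(timecourse,
                        ggplot2::aes(x = .data$bin_start,
                                     y = .data$proportion,
                                     colour = .data$level,
                                     linetype = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(condition ~ metric) +
    ggplot2::labs(x = "time from label onset (ms)",
                  y = "fixation proportion",
                  colour = "metric level", linetype = NULL) +
    ggplot2::theme_minimal()
  f1 <- file.path(outdir, "timecourse.pdf")
  ggplot2::ggsave(f1, p1, width = 9, height = 5)

  item_cat <- setNames(experimental_items()$category,
                       experimental_items()$item)
  dens <- setNames(density$condition,
                   paste(density$child_id, density$category))
  gcc <- setNames(metrics$metrics$gcc, metrics$metrics$child_id)
  dkey <- paste(metrics$degrees$child_id, metrics$degrees$item)
  degree <- setNames(metrics$degrees$degree, dkey)
  acc <- accuracy
  acc$density <- unname(dens[paste(acc$child_id, item_cat[acc$item])])
  acc$degree <- unname(median_split(
    as.numeric(degree[paste(acc$child_id, acc$item)])))
  acc$gcc <- unname(median_split(as.numeric(gcc[acc$child_id])))
  long <- do.call(rbind, lapply(c("density", "degree", "gcc"), function(m) {
    data.frame(condition = acc$condition, metric = m, level = acc[[m]],
               log_gaze = acc$log_gaze, stringsAsFactors = FALSE)
  }))
  p2 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$level,
                                           y = .data$log_gaze)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_grid(condition ~ metric) +
    ggplot2::labs(x = NULL, y = "log-gaze proportion ratio") +
    ggplot2::theme_minimal()
  f2 <- file.path(outdir, "accuracy.pdf")
  ggplot2::ggsave(f2, p2, width = 9, height = 5)
  invisible(c(f1, f2))
}

#' Command-line entry point
#'
#' A thin argument parser over [run_pipeline()], used by the
#' `inst/cli/lexigaze` script.  Supported flags: `--seed`, `--config`
#' (YAML, see [read_sim_config()]), `--outdir`, `--no-figures`,
#' `--n-children`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
lexigaze_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  val <- function(flag, default) {
    i <- which(argv == flag)
    if (length(i) == 1L && i < length(argv)) argv[i + 1L] else default
  }
  status <- tryCatch({
    cfg <- if (!is.null(v <- val("--config", NULL))) read_sim_config(v)
           else sim_config()
    if (!is.null(s <- val("--seed", NULL))) cfg$seed <- as.integer(s)
    if (!is.null(n <- val("--n-children", NULL)))
      cfg$n_children <- as.integer(n)
    outdir <- val("--outdir", "lexigaze_run")
    run_pipeline(cfg, outdir, figures = !("--no-figures" %in% argv))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
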