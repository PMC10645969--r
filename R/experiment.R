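#' The study's standard task presets
#'
#' The ten binary contrasts evaluated by the pipeline: each of the eight
#' organ-specific cancer groups against the symptomatic controls (ovarian
#' restricted to female NCS patients, prostate to male), plus the pooled
#' contrasts cancer vs all non-cancer (C vs NC) and cancer vs asymptomatic
#' non-cancer (C vs NCA). Organ-specific contrasts default to a 0.90 CV
#' tuning minimum and the pooled contrasts to 0.98.
#'
#' @param target_metric `"sensitivity"` or `"specificity"` for all tasks.
#' @param organ_minimum,pooled_minimum CV tuning minima.
#' @return Named list of [task_definition()] objects.
#' @export
standard_tasks <- function(target_metric = c("sensitivity", "specificity"),
                           organ_minimum = 0.90, pooled_minimum = 0.98) {
  target_metric <- match.arg(target_metric)
  tasks <- list()
  for (g in CANCER_GROUPS) {
    sexf <- switch(g, ovarian = "F", prostate = "M", "none")
    tasks[[g]] <- task_definition(
      g, "NCS", sex_filter = sexf, target_metric = target_metric,
      target_minimum = organ_minimum,
      name = paste0(g, "_vs_NCS", switch(g, ovarian = "-F", prostate = "-M", "")))
  }
  tasks[["C_vs_NC"]] <- task_definition(
    CANCER_GROUPS, c("NCS", "NCA"), target_metric = target_metric,
    target_minimum = pooled_minimum, name = "C_vs_NC")
  tasks[["C_vs_NCA"]] <- task_definition(
    CANCER_GROUPS, "NCA", target_metric = target_metric,
    target_minimum = pooled_minimum, name = "C_vs_NCA")
  tasks
}

parse_task <- function(t) {
  task_definition(
    case_groups = unlist(t$case_groups),
    control_groups = unlist(t$control_groups),
    sex_filter = t$sex_filter %||% "none",
    target_metric = t$target_metric %||% "sensitivity",
    target_minimum = t$target_minimum %||% 0.90,
    name = t$name)
}

parse_grid <- function(g, family) {
  if (is.null(g)) return(default_tuning_grid(family))
  do.call(expand.grid, lapply(g, unlist))
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML (or JSON) experiment configuration describing the cohort
#' (either simulation settings or paths to CSV files from
#' [write_cohort()]), the preprocessing recipe, the classifier family and
#' tuning grid, the resampling settings, and the task list. All tasks are
#' validated against the cohort's group labels before any computation.
#'
#' @param path Path to the configuration file.
#' @return List of class `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg, dir = dirname(path))
}

validate_experiment_config <- function(cfg, dir = ".") {
  seed <- as.integer(cfg$seed %||% 1L)
  co <- cfg$cohort
  if (is.null(co)) stop("config must contain a `cohort` section")
  if (!is.null(co$spectra_file)) {
    cohort_source <- list(
      type = "files",
      spectra = file.path(dir, co$spectra_file),
      metadata = file.path(dir, co$metadata_file %||%
                             stop("metadata_file required with spectra_file")))
    groups_present <- NULL  # validated after reading
  } else {
    if (is.null(co$group_sizes)) stop("cohort needs group_sizes or spectra_file")
    sizes <- unlist(co$group_sizes)
    effects <- if (isTRUE(co$null_effects)) NULL else {
      default_class_effects(co$effect_amplitude %||%
                              (5 * (co$noise_sd %||% 0.01)))
    }
    cc <- cohort_config(
      group_sizes = sizes,
      noise_sd = co$noise_sd %||% 0.01,
      drift_amplitude = co$drift_amplitude %||% 0.005,
      scatter_sd = co$scatter_sd %||% 0.01,
      spectra_per_patient = co$spectra_per_patient %||% 9,
      effects = effects,
      seed = child_seed(seed, 777))
    cohort_source <- list(type = "simulate", config = cc)
    groups_present <- names(sizes)[sizes > 0]
  }
  pp <- cfg$preprocess %||% list()
  params <- preprocess_params(
    windows = if (is.null(pp$windows)) list(c(2700, 3700), c(1000, 1800))
              else lapply(pp$windows, unlist),
    baseline = pp$baseline %||% "rubberband",
    poly_order = pp$poly_order %||% 2,
    normalization = pp$normalization %||% "vector",
    derivative = pp$derivative %||% 0,
    sg_window = pp$sg_window %||% 9,
    sg_order = pp$sg_order %||% 3)
  cl <- cfg$classifier %||% list()
  family <- cl$family %||% "rf"
  grid <- parse_grid(cl$grid, family)
  rs <- cfg$resampling %||% list()
  if (is.null(cfg$tasks) || !length(cfg$tasks)) stop("config lists no tasks")
  tasks <- lapply(cfg$tasks, parse_task)
  names(tasks) <- vapply(tasks, `[[`, "", "name")
  if (!is.null(groups_present)) {
    for (t in tasks) {
      used <- c(t$case_groups, t$control_groups)
      bad <- setdiff(used, groups_present)
      if (length(bad)) {
        stop("task '", t$name, "' references group(s) absent from the cohort: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  structure(list(
    seed = seed, cohort_source = cohort_source, params = params,
    family = family, grid = grid,
    n_resamples = rs$n_resamples %||% 51,
    train_frac = rs$train_frac %||% 0.70,
    k_inner = rs$k_inner %||% 5,
    tasks = tasks,
    output_dir = cfg$output_dir %||% "specbiopsy_results"
  ), class = "experiment_config")
}

#' Run a configured experiment end to end
#'
#' Simulates (or reads) the cohort, runs every configured task through
#' [run_task()], and writes a report bundle under the output directory:
#' per task a metrics JSON, the mean ROC curve, per-patient predictions,
#' detection-rate tables by stage/group/sex, the aggregated importance
#' profile with its top regions, plus a run manifest. Rerunning the same
#' configuration and seed reproduces the metrics byte for byte.
#'
#' @param config Path to a YAML config, or an `experiment_config`.
#' @param output_dir Optional override of the configured output directory.
#' @param verbose Print per-task progress.
#' @return Invisibly, a named list of `experiment_result` objects.
#' @export
run_experiment <- function(config, output_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- load_experiment_config(config)
  if (!inherits(config, "experiment_config")) {
    stop("config must be a path or an experiment_config")
  }
  out <- output_dir %||% config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  cohort <- if (config$cohort_source$type == "simulate") {
    generate_cohort(config$cohort_source$config)
  } else {
    read_cohort(config$cohort_source$spectra, config$cohort_source$metadata)
  }
  results <- list()
  for (t in config$tasks) {
    if (verbose) message("running task: ", t$name)
    res <- run_task(cohort, t, params = config$params, grid = config$grid,
                    family = config$family, n_resamples = config$n_resamples,
                    train_frac = config$train_frac, k_inner = config$k_inner,
                    seed = child_seed(config$seed, 7000 + length(results)))
    write_task_report(res, file.path(out, t$name))
    results[[t$name]] <- res
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("specbiopsy")),
    seed = config$seed, n_resamples = config$n_resamples,
    family = config$family, tasks = names(results),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Write the report bundle for one task
#'
#' @param result An `experiment_result`.
#' @param dir Output directory for this task (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_task_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- result$summary
  metrics <- list(
    task = result$task$name,
    target_metric = result$task$target_metric,
    target_minimum = result$task$target_minimum,
    n_resamples = s$n_resamples,
    sensitivity = list(mean = s$sensitivity_mean, sd = s$sensitivity_sd,
                       ci95 = s$sensitivity_ci95),
    specificity = list(mean = s$specificity_mean, sd = s$specificity_sd,
                       ci95 = s$specificity_ci95),
    auc = list(mean = s$auc_mean, sd = s$auc_sd,
               mean_roc_auc = s$mean_roc_auc),
    cv = list(sensitivity_mean = s$cv_sensitivity_mean,
              specificity_mean = s$cv_specificity_mean),
    ppv_analytic = lapply(c(0.02, 0.07), function(prev) {
      list(prevalence = prev,
           ppv = ppv_at_prevalence(s$sensitivity_mean, s$specificity_mean, prev))
    }))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(
    data.frame(fpr = result$mean_roc$fpr, tpr = result$mean_roc$tpr),
    file.path(dir, "mean_roc.csv"), row.names = FALSE)
  preds <- do.call(rbind, lapply(result$resamples, function(r) {
    cbind(resample = r$index, r$predictions)
  }))
  utils::write.csv(preds, file.path(dir, "predictions.csv"), row.names = FALSE)
  det <- do.call(rbind, lapply(c("stage", "group", "sex"), function(f) {
    d <- detection_rates(result, f)
    cbind(field = f, d$table)
  }))
  utils::write.csv(det, file.path(dir, "detection_rates.csv"),
                   row.names = FALSE)
  prof <- aggregate_importance(result)
  utils::write.csv(
    data.frame(wavenumber = prof$wavenumber, mean = prof$mean, sd = prof$sd),
    file.path(dir, "importance.csv"), row.names = FALSE)
  utils::write.csv(top_regions(prof, k = 5),
                   file.path(dir, "top_regions.csv"), row.names = FALSE)
  ppv <- do.call(rbind, lapply(seq(0.01, 0.20, by = 0.01), function(p) {
    data.frame(prevalence = p,
               ppv = ppv_at_prevalence(s$sensitivity_mean,
                                       s$specificity_mean, p))
  }))
  utils::write.csv(ppv, file.path(dir, "ppv_vs_prevalence.csv"),
                   row.names = FALSE)
  invisible(dir)
}
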