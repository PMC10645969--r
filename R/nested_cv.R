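#' Define a binary classification task
#'
#' A case/control contrast over cohort groups, with an optional sex
#' restriction (used for the ovarian vs female-control and prostate vs
#' male-control contrasts) and a threshold tuning target: the probability
#' threshold is chosen so the cross-validated value of `target_metric`
#' reaches at least `target_minimum`, while maximizing the complementary
#' metric. Conventional minima are 0.90 and 0.45 for organ-specific
#' contrasts and 0.98 for pooled-cancer contrasts.
#'
#' @param case_groups,control_groups Disjoint sets of group labels.
#' @param sex_filter `"none"`, `"F"` or `"M"` - restrict eligible patients.
#' @param target_metric `"sensitivity"` or `"specificity"`.
#' @param target_minimum Required CV minimum for the target metric, in (0,1).
#' @param name Optional task name used in reports.
#' @return List of class `task_definition`.
#' @export
task_definition <- function(case_groups, control_groups,
                            sex_filter = c("none", "F", "M"),
                            target_metric = c("sensitivity", "specificity"),
                            target_minimum = 0.90, name = NULL) {
  sex_filter <- match.arg(sex_filter)
  target_metric <- match.arg(target_metric)
  if (length(intersect(case_groups, control_groups))) {
    stop("case and control groups must be disjoint")
  }
  bad <- setdiff(c(case_groups, control_groups), ALL_GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!is.finite(target_minimum) || target_minimum <= 0 || target_minimum >= 1) {
    stop("target_minimum must lie in (0, 1)")
  }
  name <- name %||% paste0(paste(case_groups, collapse = "+"), "_vs_",
                           paste(control_groups, collapse = "+"),
                           "_", substr(target_metric, 1, 4), target_minimum * 100)
  structure(list(case_groups = case_groups, control_groups = control_groups,
                 sex_filter = sex_filter, target_metric = target_metric,
                 target_minimum = target_minimum, name = name),
            class = "task_definition")
}

# Eligible patients for a task: metadata subset plus logical case label.
eligible_patients <- function(metadata, task) {
  keep <- metadata$group %in% c(task$case_groups, task$control_groups)
  if (task$sex_filter != "none") keep <- keep & metadata$sex == task$sex_filter
  m <- metadata[keep, , drop = FALSE]
  m$is_case <- m$group %in% task$case_groups
  if (sum(m$is_case) < 2 || sum(!m$is_case) < 2) {
    stop("task infeasible: fewer than 2 patients in a class after filtering")
  }
  m
}

#' Outer resampling splits
#'
#' Patient-level 70:30 train/test splits repeated `n_resamples` times,
#' stratified by class so every test set contains both classes. The train
#' count per class is `round(train_frac * n)`, clamped so both sets keep at
#' least one patient per class. No patient appears in both sets of the same
#' resample. Per-resample seeds derive from the master seed and the
#' resample index.
#'
#' @param cohort A `cohort` (or its [cohort_metadata()] data frame).
#' @param task A [task_definition()].
#' @param n_resamples Number of outer resamples (default 51).
#' @param train_frac Training fraction (default 0.70).
#' @param seed Master seed.
#' @return List of splits, each `list(index, train_ids, test_ids)`.
#' @export
make_splits <- function(cohort, task, n_resamples = 51, train_frac = 0.70,
                        seed = 1L) {
  meta <- if (inherits(cohort, "cohort")) cohort_metadata(cohort) else cohort
  elig <- eligible_patients(meta, task)
  lapply(seq_len(n_resamples), function(r) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(child_seed(seed, r))
    train <- character(0)
    for (cls in c(TRUE, FALSE)) {
      ids <- elig$patient_id[elig$is_case == cls]
      n_tr <- min(max(round(train_frac * length(ids)), 1), length(ids) - 1)
      train <- c(train, sample(ids, n_tr))
    }
    list(index = r, train_ids = train,
         test_ids = setdiff(elig$patient_id, train))
  })
}

#' Select a probability threshold for a target metric
#'
#' Candidate thresholds are the midpoints between adjacent distinct sorted
#' scores plus `-Inf`/`+Inf` sentinels (a patient is called a case when its
#' score strictly exceeds the threshold). Among candidates whose
#' `target` metric is at least `minimum`, the one maximizing the
#' complementary metric is returned, ties broken toward the higher
#' threshold. If no candidate attains the minimum, the threshold maximizing
#' the target metric is returned instead (documented fallback; with the
#' infinite sentinels a sensitivity or specificity minimum below 1 is
#' always attainable).
#'
#' @param scores Finite numeric scores.
#' @param labels Logical case indicator (or `"case"`/`"control"`).
#' @param target `"sensitivity"` or `"specificity"`.
#' @param minimum Required minimum for the target metric.
#' @return List: `threshold`, achieved `sensitivity` and `specificity`.
#' @export
select_threshold <- function(scores, labels,
                             target = c("sensitivity", "specificity"),
                             minimum = 0.90) {
  target <- match.arg(target)
  is_case <- labels_as_case(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  sens <- vapply(cand, function(t) sum(scores > t & is_case) / n_case, 0)
  spec <- vapply(cand, function(t) sum(scores <= t & !is_case) / n_ctrl, 0)
  tgt <- if (target == "sensitivity") sens else spec
  oth <- if (target == "sensitivity") spec else sens
  ok <- tgt >= minimum
  pick <- if (any(ok)) {
    idx <- which(ok)
    best <- idx[oth[idx] == max(oth[idx])]
    max(best)  # ties toward the higher threshold (candidates are sorted)
  } else {
    max(which(tgt == max(tgt)))
  }
  list(threshold = cand[pick], sensitivity = sens[pick],
       specificity = spec[pick])
}

#' Consensus (maximum-vote) patient prediction
#'
#' Each replicate spectrum votes case when its score exceeds the threshold;
#' the patient is called a case when case votes are in the majority. Vote
#' ties - only possible for even replicate counts - are resolved toward
#' case, consistent with the intended rule-out triage use. The patient
#' score is the median replicate score; for odd replicate counts the
#' consensus label is provably identical to thresholding the median.
#'
#' @param scores Replicate spectrum scores for one patient (length >= 1).
#' @param threshold Probability threshold.
#' @return List: `patient_score` (median score), `label` (logical case).
#' @export
consensus_predict <- function(scores, threshold) {
  if (length(scores) < 1) stop("at least one spectrum score is required")
  votes <- sum(scores > threshold)
  n <- length(scores)
  label <- if (2 * votes == n) TRUE else 2 * votes > n
  list(patient_score = stats::median(scores), label = label)
}

# Stratified patient-level folds: within each class, patients are shuffled
# and dealt to folds 1..k in turn, so every fold contains both classes
# whenever k <= min class size.
make_folds <- function(ids, is_case, k, seed) {
  if (k > min(sum(is_case), sum(!is_case))) {
    stop("k exceeds the smaller class size; reduce k_inner")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(ids))
  for (cls in c(TRUE, FALSE)) {
    i <- which(is_case == cls)
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
  }
  fold
}

#' Inner fivefold tuning of hyperparameters and threshold
#'
#' Patient-level k-fold CV on the training patients (all replicate spectra
#' of a patient share its fold). Each hyperparameter setting is scored by
#' the mean out-of-fold patient-level AUC (patient score = median replicate
#' score); the winning setting's pooled out-of-fold patient scores are then
#' passed to [select_threshold()] with the task's tuning target.
#'
#' @param features Spectrum-level feature matrix for the training patients.
#' @param patient_ids Patient id per feature row.
#' @param is_case Logical case label per feature row.
#' @param task A [task_definition()] (supplies the tuning target).
#' @param grid Hyperparameter grid (data frame, one row per setting).
#' @param family Estimator family for [fit_classifier()].
#' @param k Number of inner folds (default 5).
#' @param seed Integer seed.
#' @return List: `hp`, `threshold`, `cv_auc`, `cv_sensitivity`,
#'   `cv_specificity` (CV metrics at the selected threshold).
#' @export
inner_tune <- function(features, patient_ids, is_case, task,
                       grid = default_tuning_grid(family), family = "rf",
                       k = 5, seed = 1L) {
  pid <- unique(patient_ids)
  p_case <- is_case[match(pid, patient_ids)]
  fold <- make_folds(pid, p_case, k, seed)
  fold_rows <- lapply(seq_len(k), function(f) {
    which(patient_ids %in% pid[fold == f])
  })
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    hp <- as.list(grid[gi, , drop = FALSE])
    aucs <- numeric(k)
    oof_scores <- setNames(numeric(length(pid)), pid)
    for (f in seq_len(k)) {
      te <- fold_rows[[f]]; tr <- setdiff(seq_len(nrow(features)), te)
      model <- fit_classifier(features[tr, , drop = FALSE], is_case[tr],
                              hp = hp, family = family,
                              seed = child_seed(seed, 100 * gi + f))
      sc <- predict_scores(model, features[te, , drop = FALSE])
      psc <- tapply(sc, patient_ids[te], stats::median)
      oof_scores[names(psc)] <- psc
      aucs[f] <- auc(roc_curve(as.numeric(psc),
                               p_case[match(names(psc), pid)]))
    }
    cand <- list(hp = hp, mean_auc = mean(aucs), oof = oof_scores)
    if (is.null(best) || cand$mean_auc > best$mean_auc) best <- cand
  }
  sel <- select_threshold(as.numeric(best$oof), p_case,
                          target = task$target_metric,
                          minimum = task$target_minimum)
  list(hp = best$hp, threshold = sel$threshold, cv_auc = best$mean_auc,
       cv_sensitivity = sel$sensitivity, cv_specificity = sel$specificity)
}

#' Vertically averaged ROC curve
#'
#' Interpolates each resample's patient-level ROC onto a fixed
#' false-positive-rate grid (0, 0.01, ..., 1 by default), averages the
#' true-positive rates pointwise, and reports the trapezoid area of the
#' averaged curve.
#'
#' @param rocs List of `roc_curve` objects.
#' @param fpr_grid Common FPR grid for vertical averaging.
#' @return List of class `mean_roc`: `fpr`, `tpr`, `auc`, `n_curves`.
#' @export
mean_roc <- function(rocs, fpr_grid = seq(0, 1, by = 0.01)) {
  if (!length(rocs)) stop("at least one ROC curve is required")
  tprs <- vapply(rocs, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = fpr_grid, ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  tpr <- rowMeans(tprs)
  tpr <- cummax(tpr)  # guard monotonicity against interpolation jitter
  structure(list(fpr = fpr_grid, tpr = tpr,
                 auc = sum(diff(fpr_grid) * (tpr[-1] + tpr[-length(tpr)]) / 2),
                 n_curves = length(rocs)),
            class = "mean_roc")
}

#' Run a full nested cross-validation experiment for one task
#'
#' The core procedure: the cohort is featurized once (all preprocessing is
#' per-spectrum), then for each of `n_resamples` outer 70:30 patient-level
#' splits the inner k-fold CV tunes hyperparameters (by mean out-of-fold
#' patient AUC) and the probability threshold (to the task's
#' sensitivity/specificity target), a final model is fit on the full
#' training set, test spectra are scored, and each test patient receives a
#' consensus (maximum-vote) prediction over its replicate spectra.
#' Per-resample test sensitivity/specificity, patient-level ROC, and
#' feature importances are aggregated into means, standard deviations,
#' percentile 95% confidence intervals, a vertically averaged ROC, and a
#' per-patient prediction history for detection-rate analysis.
#'
#' @param cohort A `cohort`.
#' @param task A [task_definition()].
#' @param params A [preprocess_params()].
#' @param grid Hyperparameter grid (data frame); a single row skips
#'   hyperparameter search and tunes only the threshold.
#' @param family Estimator family (`"rf"` or `"logistic"`).
#' @param n_resamples Outer resamples (default 51).
#' @param train_frac Outer training fraction (default 0.70).
#' @param k_inner Inner folds (default 5).
#' @param seed Master seed; all randomness derives from it.
#' @param verbose Print per-resample progress.
#' @return List of class `experiment_result`; see Details in the package
#'   vignette. Key elements: `resamples` (per-split results), `summary`
#'   (aggregated metrics), `mean_roc`, `history` (per-patient appearance
#'   and correct-call counts), `importance` (resample x feature matrix),
#'   `feature_grid`, `metadata`.
#' @export
run_task <- function(cohort, task, params = preprocess_params(),
                     grid = default_tuning_grid(family), family = "rf",
                     n_resamples = 51, train_frac = 0.70, k_inner = 5,
                     seed = 1L, verbose = FALSE) {
  feats <- featurize(cohort, params)
  meta <- cohort_metadata(cohort)
  elig <- eligible_patients(meta, task)
  splits <- make_splits(meta, task, n_resamples, train_frac, seed)
  row_pid <- feats$index$patient_id
  row_case <- elig$is_case[match(row_pid, elig$patient_id)]

  history <- data.frame(patient_id = elig$patient_id,
                        appearances = 0L, correct = 0L,
                        stringsAsFactors = FALSE)
  resamples <- vector("list", n_resamples)
  importance <- matrix(NA_real_, nrow = n_resamples, ncol = ncol(feats$features))

  for (r in seq_len(n_resamples)) {
    sp <- splits[[r]]
    tr_rows <- which(row_pid %in% sp$train_ids)
    te_rows <- which(row_pid %in% sp$test_ids)
    tune <- tryCatch(
      inner_tune(feats$features[tr_rows, , drop = FALSE], row_pid[tr_rows],
                 row_case[tr_rows], task, grid = grid, family = family,
                 k = k_inner, seed = child_seed(seed, 10000 + r)),
      error = function(e) stop("resample ", r, ": ", conditionMessage(e)))
    model <- fit_classifier(feats$features[tr_rows, , drop = FALSE],
                            row_case[tr_rows], hp = tune$hp, family = family,
                            seed = child_seed(seed, 20000 + r))
    sc <- predict_scores(model, feats$features[te_rows, , drop = FALSE])
    te_pid <- row_pid[te_rows]
    preds <- lapply(split(sc, te_pid), consensus_predict,
                    threshold = tune$threshold)
    pids <- names(preds)
    p_score <- vapply(preds, `[[`, 0, "patient_score")
    p_label <- vapply(preds, `[[`, TRUE, "label")
    p_true <- elig$is_case[match(pids, elig$patient_id)]
    cm <- confusion_at(p_label, p_true)
    rc <- roc_curve(p_score, p_true)
    hi <- match(pids, history$patient_id)
    history$appearances[hi] <- history$appearances[hi] + 1L
    history$correct[hi] <- history$correct[hi] + as.integer(p_label == p_true)
    importance[r, ] <- feature_importance(model)
    resamples[[r]] <- list(
      index = r, hp = tune$hp, threshold = tune$threshold,
      cv_auc = tune$cv_auc, cv_sensitivity = tune$cv_sensitivity,
      cv_specificity = tune$cv_specificity,
      test_sensitivity = cm$sensitivity, test_specificity = cm$specificity,
      test_auc = auc(rc), roc = rc,
      predictions = data.frame(patient_id = pids, patient_score = p_score,
                               predicted_case = p_label, true_case = p_true,
                               stringsAsFactors = FALSE, row.names = NULL))
    if (verbose) {
      message(sprintf("resample %d/%d: AUC %.3f sens %.2f spec %.2f",
                      r, n_resamples, auc(rc), cm$sensitivity, cm$specificity))
    }
  }

  sens <- vapply(resamples, `[[`, 0, "test_sensitivity")
  spec <- vapply(resamples, `[[`, 0, "test_specificity")
  aucs <- vapply(resamples, `[[`, 0, "test_auc")
  mroc <- mean_roc(lapply(resamples, `[[`, "roc"))
  ci <- function(x) unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  summary <- list(
    n_resamples = n_resamples,
    sensitivity_mean = mean(sens), sensitivity_sd = stats::sd(sens),
    sensitivity_ci95 = ci(sens),
    specificity_mean = mean(spec), specificity_sd = stats::sd(spec),
    specificity_ci95 = ci(spec),
    auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
    mean_roc_auc = mroc$auc,
    cv_sensitivity_mean = mean(vapply(resamples, `[[`, 0, "cv_sensitivity")),
    cv_specificity_mean = mean(vapply(resamples, `[[`, 0, "cv_specificity")))
  structure(list(task = task, resamples = resamples, summary = summary,
                 mean_roc = mroc, history = history,
                 importance = importance,
                 feature_grid = feats$grid,
                 metadata = meta, params = params, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  s <- x$summary
  cat("Task:", x$task$name, "\n")
  cat(sprintf("  %d resamples | mean AUC %.3f (per-resample) / %.3f (mean ROC)\n",
              s$n_resamples, s$auc_mean, s$mean_roc_auc))
  cat(sprintf("  sensitivity %.1f%% +/- %.1f | specificity %.1f%% +/- %.1f\n",
              100 * s$sensitivity_mean, 100 * s$sensitivity_sd,
              100 * s$specificity_mean, 100 * s$specificity_sd))
  cat(sprintf("  tuning: %s >= %.0f%% (CV achieved sens %.1f%%, spec %.1f%%)\n",
              x$task$target_metric, 100 * x$task$target_minimum,
              100 * s$cv_sensitivity_mean, 100 * s$cv_specificity_mean))
  invisible(x)
}
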