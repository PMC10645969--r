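#' Receiver operating characteristic curve
#'
#' Computes the ROC curve over all distinct score thresholds, grouping tied
#' scores, with the endpoints (0,0) and (1,1) always included. The
#' prediction convention matches the rest of the package: a spectrum or
#' patient is called a case when its score exceeds the threshold.
#'
#' @param scores Finite numeric scores (higher = more case-like).
#' @param labels Logical case indicator (or `"case"`/`"control"`).
#' @return List of class `roc_curve` with `fpr`, `tpr`, `thresholds`
#'   (same length; `thresholds[1]` is `Inf` for the (0,0) point).
#' @export
roc_curve <- function(scores, labels) {
  is_case <- labels_as_case(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  if (n_case == 0 || n_ctrl == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- is_case[ord]
  last_of_group <- c(diff(s) != 0, TRUE)  # group tied scores
  cum_tp <- cumsum(y)[last_of_group]
  cum_fp <- cumsum(!y)[last_of_group]
  structure(list(
    fpr = c(0, cum_fp / n_ctrl),
    tpr = c(0, cum_tp / n_case),
    thresholds = c(Inf, s[last_of_group])
  ), class = "roc_curve")
}

#' Area under a ROC curve
#'
#' Trapezoid-rule area. For a curve built by [roc_curve()] this equals the
#' Mann-Whitney U statistic divided by (n_case * n_control), with ties
#' counted one half.
#'
#' @param curve A `roc_curve`.
#' @return AUC in \code{[0, 1]}.
#' @export
auc <- function(curve) {
  if (!inherits(curve, "roc_curve")) stop("curve must be a roc_curve")
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Confusion metrics for a set of binary predictions
#'
#' @param predicted Logical predicted-case indicator.
#' @param truth Logical true-case indicator, same length.
#' @return List with `sensitivity` (TP/(TP+FN)), `specificity`
#'   (TN/(TN+FP)), `ppv`, `npv` (empirical, on these predictions; `NaN`
#'   when the corresponding call count is zero).
#' @export
confusion_at <- function(predicted, truth) {
  predicted <- labels_as_case(predicted)
  truth <- labels_as_case(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!any(truth) || all(truth)) {
    stop("both cases and controls are required for confusion metrics")
  }
  tp <- sum(predicted & truth);  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth); fp <- sum(predicted & !truth)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
       npv = if (tn + fn > 0) tn / (tn + fn) else NaN)
}

#' Positive predictive value at an assumed prevalence
#'
#' Bayes' rule: `PPV = prev * sens / (prev * sens + (1 - prev) * (1 - spec))`.
#' Distinct from the empirical PPV of [confusion_at()], which reflects the
#' case/control mix of the evaluation cohort rather than a deployment
#' population.
#'
#' @param sensitivity,specificity,prevalence Values in \code{[0, 1]}.
#' @return PPV in \code{[0, 1]}; `NA` when the denominator is zero.
#' @export
ppv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity, specificity, prevalence)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("sensitivity, specificity and prevalence must lie in [0, 1]")
    }
  }
  num <- prevalence * sensitivity
  den <- num + (1 - prevalence) * (1 - specificity)
  if (den == 0) return(NA_real_)
  num / den
}

#' Round half-up to integer percentages
#'
#' @param x Numeric vector (percent scale).
#' @return `floor(x + 0.5)`, matching conventional half-up presentation of
#'   percentages (unlike R's banker's rounding).
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Per-patient detection rates stratified by metadata
#'
#' For each patient, collects its consensus predictions over every outer
#' test set containing it and computes a detection rate: correct calls /
#' total appearances (a cancer patient is correct when called a case, a
#' control when called a control). Rates are then averaged (unweighted)
#' over the patients in each category of the chosen metadata field.
#' Patients with zero test-set appearances are excluded from the averages
#' and counted in `n_excluded`.
#'
#' @param result An `experiment_result` from [run_task()].
#' @param field Metadata field: one of `"group"`, `"stage"`, `"sex"`, or
#'   `"age"` (binned by decade).
#' @return List of class `detection_rate_table`: `field`, `table` (data
#'   frame `category`, `n`, `rate`, `rate_pct`), `overall`, `n_excluded`.
#' @export
detection_rates <- function(result, field) {
  if (!inherits(result, "experiment_result")) {
    stop("result must be an experiment_result")
  }
  h <- result$history
  meta <- result$metadata
  if (!field %in% c("group", "stage", "sex", "age")) {
    stop("unknown metadata field: ", field)
  }
  rate <- ifelse(h$appearances > 0, h$correct / h$appearances, NA_real_)
  m <- meta[match(h$patient_id, meta$patient_id), ]
  category <- if (field == "age") {
    paste0(floor(m$age / 10) * 10, "-", floor(m$age / 10) * 10 + 9)
  } else {
    as.character(m[[field]])
  }
  category[is.na(category)] <- "none"
  seen <- !is.na(rate)
  tab <- stats::aggregate(rate[seen], by = list(category = category[seen]),
                          FUN = mean)
  names(tab)[2] <- "rate"
  tab$n <- as.integer(table(category[seen])[tab$category])
  tab$rate_pct <- round_half_up(100 * tab$rate)
  tab <- tab[, c("category", "n", "rate", "rate_pct")]
  structure(list(field = field, table = tab,
                 overall = mean(rate[seen]),
                 n_excluded = sum(!seen)),
            class = "detection_rate_table")
}

#' @export
print.detection_rate_table <- function(x, ...) {
  cat("Detection rates by", x$field, "\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("overall %.1f%%; %d patient(s) never appeared in a test set\n",
              100 * x$overall, x$n_excluded))
  invisible(x)
}

#' Pool category detection rates
#'
#' Size-weighted mean of per-category percentage rates, reported as a
#' percentage rounded half-up to the nearest integer - e.g. pooling Stage I
#' and II rates of 64% and 51% over 231 and 516 patients gives 55%.
#'
#' @param rates Percentage rates (0-100), one per category.
#' @param sizes Positive patient counts, same length.
#' @return Pooled integer percentage.
#' @export
pooled_rate <- function(rates, sizes) {
  if (length(rates) != length(sizes)) stop("rates and sizes length mismatch")
  if (any(sizes <= 0)) stop("sizes must be positive")
  round_half_up(sum(rates * sizes) / sum(sizes))
}
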