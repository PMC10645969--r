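#' Aggregate per-resample feature importances
#'
#' Pointwise mean and standard deviation of the per-resample importance
#' vectors over the post-preprocessing wavenumber grid, with the mean
#' renormalized to sum to 1. For derivative-transformed features the
#' importance is attributed to the wavenumber of the feature column.
#'
#' @param result An `experiment_result` from [run_task()], or a numeric
#'   matrix (resamples x features) together with `grid`.
#' @param grid Wavenumber grid matching the columns (only needed when
#'   `result` is a bare matrix).
#' @return List of class `importance_profile`: `wavenumber`, `mean`, `sd`.
#' @export
aggregate_importance <- function(result, grid = NULL) {
  if (inherits(result, "experiment_result")) {
    imp <- result$importance
    grid <- result$feature_grid
  } else {
    imp <- result
    if (is.null(grid)) stop("grid is required when passing a bare matrix")
  }
  if (ncol(imp) != length(grid)) {
    stop("importance columns and wavenumber grid differ in length")
  }
  if (any(!is.finite(imp)) || any(imp < 0)) {
    stop("importance values must be finite and non-negative")
  }
  m <- colMeans(imp)
  if (sum(m) > 0) m <- m / sum(m)
  s <- apply(imp, 2, stats::sd)
  if (nrow(imp) == 1) s <- rep(0, ncol(imp))
  structure(list(wavenumber = as.numeric(grid), mean = unname(m),
                 sd = unname(s), n_resamples = nrow(imp)),
            class = "importance_profile")
}

#' Top discriminatory wavenumber regions
#'
#' Greedy peak-picking on the mean importance profile: the global maximum
#' is taken, all points within `min_separation` cm^-1 of it are suppressed,
#' and the process repeats up to `k` times. Exact ties are broken toward
#' the higher wavenumber. Each peak is labelled with the tentative
#' biomolecular assignment of the enclosing region from
#' [band_assignments()], or `"unassigned"`.
#'
#' @param profile An `importance_profile`.
#' @param k Number of regions to report.
#' @param min_separation Suppression half-width around each picked peak
#'   (cm^-1, default 30 - a typical band width).
#' @param assignments Assignment lookup table (see [band_assignments()]).
#' @return Data frame `wavenumber`, `importance`, `label`, ranked by
#'   importance. Fewer than `k` rows (with attribute `truncated = TRUE`)
#'   when the profile runs out of separable peaks.
#' @export
top_regions <- function(profile, k = 5, min_separation = 30,
                        assignments = band_assignments()) {
  if (!inherits(profile, "importance_profile")) {
    stop("profile must be an importance_profile")
  }
  if (k < 1) stop("k must be >= 1")
  wn <- profile$wavenumber
  imp <- profile$mean
  avail <- rep(TRUE, length(wn))
  rows <- list()
  while (length(rows) < k && any(avail)) {
    mx <- max(imp[avail])
    at <- which(avail & imp == mx)
    pick <- at[which.max(wn[at])]  # ties -> highest wavenumber
    lab <- "unassigned"
    hit <- which(assignments$low <= wn[pick] & wn[pick] <= assignments$high)
    if (length(hit)) lab <- assignments$label[hit[1]]
    rows[[length(rows) + 1]] <- data.frame(
      wavenumber = wn[pick], importance = imp[pick], label = lab,
      stringsAsFactors = FALSE)
    avail <- avail & abs(wn - wn[pick]) > min_separation
  }
  out <- do.call(rbind, rows)
  if (nrow(out) < k) {
    warning("only ", nrow(out), " separable peaks available (requested ", k, ")")
    attr(out, "truncated") <- TRUE
  }
  out
}
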