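#' Preprocessing parameters
#'
#' Defines the fixed-order preprocessing recipe applied to every spectrum:
#' truncate to wavenumber window(s), baseline-correct, (optionally)
#' differentiate with a Savitzky-Golay filter, then normalize. The default
#' recipe - windows 3700-2700 and 1800-1000 cm^-1, rubberband baseline,
#' vector normalization, no derivative - is a conventional serum-FTIR
#' choice. All steps are per-spectrum, so no statistic crosses the
#' train/test boundary by construction.
#'
#' @param windows List of `c(low, high)` wavenumber windows (cm^-1); bounds
#'   in either order. `NULL` keeps the full grid.
#' @param baseline `"none"`, `"rubberband"` or `"polynomial"`.
#' @param poly_order Polynomial order for `baseline = "polynomial"`.
#' @param normalization `"none"`, `"vector"` (unit Euclidean norm) or
#'   `"minmax"` (rescale to \code{[0, 1]}).
#' @param derivative 0 (none), 1 or 2; Savitzky-Golay derivative order.
#' @param sg_window Odd Savitzky-Golay window length (points).
#' @param sg_order Savitzky-Golay polynomial order, < `sg_window`.
#' @return List of class `preprocess_params`.
#' @export
preprocess_params <- function(windows = list(c(2700, 3700), c(1000, 1800)),
                              baseline = c("rubberband", "none", "polynomial"),
                              poly_order = 2,
                              normalization = c("vector", "none", "minmax"),
                              derivative = 0, sg_window = 9, sg_order = 3) {
  baseline <- match.arg(baseline)
  normalization <- match.arg(normalization)
  if (!derivative %in% 0:2) stop("derivative must be 0, 1 or 2")
  if (derivative > 0) {
    if (sg_window %% 2 != 1 || sg_window <= sg_order) {
      stop("sg_window must be odd and greater than sg_order")
    }
    if (sg_order <= derivative) stop("sg_order must exceed the derivative order")
  }
  if (!is.null(windows)) {
    windows <- lapply(windows, function(w) {
      w <- sort(as.numeric(w))
      if (length(w) != 2 || w[1] >= w[2]) stop("each window must be c(low, high) with low < high")
      w
    })
  }
  structure(list(windows = windows, baseline = baseline,
                 poly_order = poly_order, normalization = normalization,
                 derivative = as.integer(derivative),
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order)),
            class = "preprocess_params")
}

#' Restrict a spectrum to wavenumber windows
#'
#' @param values Absorbance vector.
#' @param grid Matching `wavenumber_grid`.
#' @param windows List of `c(low, high)` windows; bounds in either order.
#' @return List with `values` and `grid` restricted to the union of the
#'   windows, original (descending) order preserved.
#' @export
truncate_spectrum <- function(values, grid, windows) {
  grid <- validate_grid(grid)
  if (length(values) != length(grid)) stop("values/grid length mismatch")
  keep <- window_mask(grid, windows)
  if (!any(keep)) stop("windows do not intersect the wavenumber grid")
  list(values = values[keep], grid = validate_grid(grid[keep]))
}

window_mask <- function(grid, windows) {
  if (is.null(windows)) return(rep(TRUE, length(grid)))
  keep <- rep(FALSE, length(grid))
  for (w in windows) {
    w <- sort(as.numeric(w))
    keep <- keep | (grid >= w[1] & grid <= w[2])
  }
  keep
}

# Indices of contiguous runs of TRUE in a keep-mask, as a list of integer
# vectors relative to the kept grid. Baseline and derivative steps operate
# per contiguous segment so disjoint windows are never bridged.
contiguous_segments <- function(grid_full, keep) {
  idx <- which(keep)
  if (!length(idx)) return(list())
  breaks <- c(0, which(diff(idx) > 1), length(idx))
  lapply(seq_len(length(breaks) - 1), function(i) {
    seq(breaks[i] + 1, breaks[i + 1])
  })
}

# Lower convex hull baseline (the "rubberband"): the unique convex minorant
# through the spectrum's endpoints. Computed by Andrew's monotone chain on
# points sorted by ascending wavenumber, then linearly interpolated.
rubberband_baseline <- function(values, grid) {
  n <- length(values)
  ord <- order(grid)  # ascending x
  x <- as.numeric(grid)[ord]
  y <- values[ord]
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      o <- hull[length(hull) - 1]; a <- hull[length(hull)]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  base_asc <- stats::approx(x[hull], y[hull], xout = x, rule = 2)$y
  base <- numeric(n)
  base[ord] <- base_asc
  base
}

#' Baseline-correct a spectrum
#'
#' `"rubberband"` subtracts the lower convex hull through the spectrum's
#' endpoints, guaranteeing a non-negative corrected spectrum (to numerical
#' tolerance); `"polynomial"` subtracts an ordinary least-squares polynomial
#' fit of the stated order; `"none"` is the identity.
#'
#' @inheritParams truncate_spectrum
#' @param method `"none"`, `"rubberband"` or `"polynomial"`.
#' @param poly_order Order of the polynomial fit.
#' @return Corrected absorbance vector.
#' @export
baseline_correct <- function(values, grid,
                             method = c("rubberband", "none", "polynomial"),
                             poly_order = 2) {
  method <- match.arg(method)
  if (length(values) != length(grid)) stop("values/grid length mismatch")
  if (method == "none") return(values)
  if (length(values) < 3) stop("baseline correction needs at least 3 points")
  if (method == "rubberband") {
    return(values - rubberband_baseline(values, grid))
  }
  if (poly_order >= length(values)) {
    stop("polynomial order must be smaller than the number of points")
  }
  x <- as.numeric(grid)
  fit <- stats::lm(values ~ stats::poly(x, poly_order))
  values - unname(stats::fitted(fit))
}

#' Normalize a spectrum
#'
#' @inheritParams truncate_spectrum
#' @param mode `"none"`, `"vector"` (divide by the Euclidean norm) or
#'   `"minmax"` (affine rescale to \code{[0, 1]}).
#' @return Normalized vector. Vector normalization is idempotent.
#' @export
normalize_spectrum <- function(values, mode = c("vector", "none", "minmax")) {
  mode <- match.arg(mode)
  if (mode == "none") return(values)
  if (mode == "vector") {
    nrm <- sqrt(sum(values^2))
    if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum")
    return(values / nrm)
  }
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot minmax-normalize a constant spectrum")
  (values - rng[1]) / diff(rng)
}

# Savitzky-Golay derivative w.r.t. wavenumber on a uniform grid segment.
sg_derivative <- function(values, grid, m, window, order) {
  step <- diff(as.numeric(grid))
  if (max(abs(step - step[1])) > 1e-6 * abs(step[1])) {
    stop("Savitzky-Golay derivative requires a uniform wavenumber grid")
  }
  if (length(values) < window) stop("segment shorter than the SG window")
  signal::sgolayfilt(values, p = order, n = window, m = m) / step[1]^m
}

# Apply the full recipe to one spectrum already truncated to `grid`, with
# `segments` the contiguous runs of the kept grid.
apply_recipe <- function(values, grid, segments, params) {
  for (seg in segments) {
    values[seg] <- baseline_correct(values[seg], grid[seg],
                                    params$baseline, params$poly_order)
    if (params$derivative > 0) {
      values[seg] <- sg_derivative(values[seg], grid[seg], params$derivative,
                                   params$sg_window, params$sg_order)
    }
  }
  normalize_spectrum(values, params$normalization)
}

#' Build the feature matrix for a cohort
#'
#' Applies the preprocessing recipe (truncate, then per contiguous window
#' segment baseline and derivative, then normalization) to every replicate
#' spectrum. Row order is stable: patients in cohort order, replicates
#' ascending. The transform uses no class labels and no cross-spectrum
#' statistics, so train/test subsets of the rows are preprocessed
#' identically and independently.
#'
#' @param cohort A `cohort`.
#' @param params A [preprocess_params()].
#' @return List with `features` (matrix, one row per spectrum, columns named
#'   by wavenumber), `grid` (the post-truncation `wavenumber_grid`), and
#'   `index` (data frame `patient_id`, `replicate`).
#' @export
featurize <- function(cohort, params = preprocess_params()) {
  if (!inherits(cohort, "cohort")) stop("`cohort` must be a cohort object")
  if (!inherits(params, "preprocess_params")) {
    stop("`params` must be preprocess_params")
  }
  keep <- window_mask(cohort$grid, params$windows)
  if (!any(keep)) stop("windows do not intersect the cohort grid")
  grid <- validate_grid(as.numeric(cohort$grid)[keep])
  segments <- contiguous_segments(cohort$grid, keep)
  n_spec <- sum(vapply(cohort$patients, function(p) nrow(p$spectra), 0L))
  features <- matrix(NA_real_, nrow = n_spec, ncol = length(grid))
  pid <- character(n_spec); rep_idx <- integer(n_spec)
  r <- 0L
  for (p in cohort$patients) {
    for (j in seq_len(nrow(p$spectra))) {
      r <- r + 1L
      features[r, ] <- apply_recipe(p$spectra[j, keep], grid, segments, params)
      pid[r] <- p$patient_id
      rep_idx[r] <- j
    }
  }
  colnames(features) <- format(as.numeric(grid), trim = TRUE)
  list(features = features, grid = grid,
       index = data.frame(patient_id = pid, replicate = rep_idx,
                          stringsAsFactors = FALSE))
}
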