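#' Construct a wavenumber grid
#'
#' FTIR spectra are indexed by wavenumber (cm^-1) on a strictly descending
#' axis, conventionally plotted from high to low wavenumber. The default grid
#' spans 4000-452 cm^-1 at 4 cm^-1 spacing, a typical mid-infrared benchtop
#' resolution covering both the high-wavenumber (lipid/amide A) region and
#' the biological fingerprint region (~1800-900 cm^-1).
#'
#' @param from,to Grid endpoints in cm^-1 (`from` > `to`).
#' @param by Positive step size in cm^-1.
#' @return Numeric vector of class `wavenumber_grid`, strictly decreasing.
#' @examples
#' g <- wavenumber_grid()
#' length(g)
#' @export
wavenumber_grid <- function(from = 4000, to = 452, by = 4) {
  if (from <= to) stop("grid must run from high to low wavenumber")
  if (by <= 0) stop("grid step must be positive")
  validate_grid(seq(from, to, by = -by))
}

#' @rdname wavenumber_grid
#' @param values Numeric vector of wavenumbers to validate as a grid.
#' @export
validate_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("wavenumber grid needs at least 2 points")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("wavenumbers must be finite and positive")
  }
  if (any(diff(values) >= 0)) stop("wavenumber grid must be strictly descending")
  structure(values, class = "wavenumber_grid")
}

#' Define an absorption band
#'
#' A single vibrational band parameterized by its center, full width at half
#' maximum (FWHM), peak amplitude, and line shape. Gaussian and Lorentzian
#' profiles are supported; serum bands are rendered Gaussian by default.
#'
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param amplitude Peak absorbance at the band center, >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param label Optional tentative biomolecular assignment.
#' @return A list of class `band`.
#' @export
band <- function(center, fwhm, amplitude, shape = c("gaussian", "lorentzian"),
                 label = "") {
  shape <- match.arg(shape)
  if (!is.finite(fwhm) || fwhm <= 0) stop("band fwhm must be positive")
  if (!is.finite(amplitude) || amplitude < 0) stop("band amplitude must be >= 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape, label = label),
            class = "band")
}

# Evaluate a single band on a grid. Gaussian: a*exp(-4 ln2 (x-c)^2 / w^2);
# Lorentzian: a * (w/2)^2 / ((x-c)^2 + (w/2)^2). Both peak at `a` at x = c.
eval_band <- function(b, grid) {
  x <- as.numeric(grid)
  d <- x - b$center
  if (b$shape == "gaussian") {
    b$amplitude * exp(-4 * log(2) * d^2 / b$fwhm^2)
  } else {
    hw2 <- (b$fwhm / 2)^2
    b$amplitude * hw2 / (d^2 + hw2)
  }
}

#' Render a list of bands on a wavenumber grid
#'
#' Sums the band profiles pointwise over the grid. The result is linear in
#' band amplitudes and non-negative whenever all amplitudes are.
#'
#' @param bands List of [band()] objects (possibly empty).
#' @param grid A `wavenumber_grid`.
#' @return Numeric absorbance vector, `length(grid)`.
#' @examples
#' g <- wavenumber_grid(1800, 1000, 4)
#' amide2 <- band(1530, 50, 0.5, label = "Amide II")
#' prof <- render_band_profile(list(amide2), g)
#' prof[which.min(abs(g - 1530))]  # 0.5 at the band center
#' @export
render_band_profile <- function(bands, grid) {
  grid <- validate_grid(grid)
  out <- numeric(length(grid))
  for (b in bands) {
    if (!inherits(b, "band")) stop("all elements of `bands` must be band objects")
    out <- out + eval_band(b, grid)
  }
  out
}

#' Default serum band library
#'
#' A qualitative stand-in for a pooled human serum absorbance spectrum:
#' the dominant protein amide bands (Amide A ~3290, Amide I ~1655, Amide II
#' ~1530, Amide III ~1260 cm^-1), CH stretching bands near 2960/2872 cm^-1,
#' phosphate (PO2-) stretches near 1240/1080 cm^-1, and a carbohydrate band
#' near 1025 cm^-1. Amplitudes are chosen so relative peak heights resemble
#' a vector-normalized serum spectrum; they are not quantitative.
#'
#' @return List of [band()] objects.
#' @export
serum_band_library <- function() {
  list(
    band(3290, 260, 0.45, label = "Amide A (N-H/O-H stretch)"),
    band(2960, 45, 0.12, label = "CH3 asymmetric stretch"),
    band(2872, 45, 0.08, label = "CH3 symmetric stretch / C-OH"),
    band(1655, 55, 1.00, label = "Amide I (C=O stretch)"),
    band(1530, 50, 0.70, label = "Amide II (N-H bend, C-N stretch)"),
    band(1400, 60, 0.20, label = "COO- symmetric stretch"),
    band(1260, 60, 0.18, label = "Amide III / asym PO2- stretch"),
    band(1080, 55, 0.16, label = "sym PO2- stretch, C-O stretch"),
    band(1025, 45, 0.12, label = "C-O, C-C stretch (carbohydrate)")
  )
}

#' Tentative biomolecular band assignments
#'
#' Lookup table mapping wavenumber regions to tentative biological
#' assignments and vibrational modes, used to label discriminatory regions
#' found by feature-importance analysis. Regions are non-overlapping.
#'
#' An editable copy of the default table ships with the package as
#' `extdata/band_assignments.yaml`; pass its (modified) path to override
#' the built-in defaults.
#'
#' @param path Optional path to a YAML assignment table with fields
#'   `low`, `high`, `label`, `modes` per entry.
#' @return Data frame with columns `low`, `high`, `label`, `modes` (cm^-1).
#' @export
band_assignments <- function(path = NULL) {
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    return(data.frame(
      low = vapply(y, function(e) as.numeric(e$low), 0),
      high = vapply(y, function(e) as.numeric(e$high), 0),
      label = vapply(y, function(e) as.character(e$label), ""),
      modes = vapply(y, function(e) as.character(e$modes), ""),
      stringsAsFactors = FALSE))
  }
  tab <- rbind(
    c(3250, 3450, "Amide A / OH", "O-H, C-H, N-H stretching"),
    c(2920, 2980, "lipid CH3/CH2", "C-H stretching (lipid, protein)"),
    c(2850, 2895, "carbohydrate C-OH", "C-OH deformation, C-O/C-C stretch"),
    c(2720, 2790, "lipid CH", "C-H, CH2 stretching"),
    c(1600, 1700, "Amide I", "C=O stretch, C-N stretch, N-H bend"),
    c(1500, 1565, "Amide II", "N-H bending, C-N stretching"),
    c(1330, 1380, "protein/lipid CH", "CH2/CH3 deformation"),
    c(1220, 1290, "Amide III / asym PO2-", "N-H bend, C-N stretch, asym PO2- stretch"),
    c(1140, 1180, "asym PO2-", "asymmetric PO2- stretching"),
    c(1050, 1095, "sym PO2-", "symmetric PO2- stretching, C-O stretch"),
    c(1000, 1045, "carbohydrate", "C-O and C-C stretching, C-OH deformation")
  )
  data.frame(low = as.numeric(tab[, 1]), high = as.numeric(tab[, 2]),
             label = tab[, 3], modes = tab[, 4], stringsAsFactors = FALSE)
}
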