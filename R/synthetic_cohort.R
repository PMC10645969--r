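#' @keywords internal
"_PACKAGE"

#' Group labels used throughout the package
#'
#' Eight solid-tumour groups plus two control groups: symptomatic non-cancer
#' (NCS; patients referred with generic symptoms or benign disease) and
#' asymptomatic non-cancer (NCA).
#' @export
CANCER_GROUPS <- c("brain", "breast", "colorectal", "kidney", "lung",
                   "ovarian", "pancreatic", "prostate")

#' @rdname CANCER_GROUPS
#' @export
CONTROL_GROUPS <- c("NCS", "NCA")

#' @rdname CANCER_GROUPS
#' @export
ALL_GROUPS <- c(CANCER_GROUPS, CONTROL_GROUPS)

STAGES <- c("I", "II", "III", "IV")

#' Class-dependent spectral effect
#'
#' The mechanism by which disease signal is injected into simulated spectra:
#' an additive Gaussian perturbation at a discriminatory wavenumber, scaled
#' per tumour stage. `delta_amplitude` may be negative (band depletion).
#' Stage scaling defaults to (0.5, 0.75, 1, 1.25) for Stages I-IV, so that
#' early-stage disease carries a weaker spectral signature, mirroring the
#' lower abundance of tumour-derived material in early disease.
#'
#' @param band_center Wavenumber of the affected region (cm^-1).
#' @param delta_amplitude Signed absorbance change applied to the case class.
#' @param fwhm Width of the perturbation (cm^-1).
#' @param stage_scaling Positive multiplier per stage I-IV.
#' @return List of class `class_effect`.
#' @export
class_effect <- function(band_center, delta_amplitude, fwhm = 30,
                         stage_scaling = c(I = 0.5, II = 0.75, III = 1, IV = 1.25)) {
  stage_scaling <- as.numeric(stage_scaling)
  if (length(stage_scaling) != 4L || any(stage_scaling <= 0)) {
    stop("stage_scaling must be 4 positive multipliers (Stages I-IV)")
  }
  names(stage_scaling) <- STAGES
  structure(list(band_center = band_center, delta_amplitude = delta_amplitude,
                 fwhm = fwhm, stage_scaling = stage_scaling),
            class = "class_effect")
}

# Signed effect profile on a grid, scaled for a given stage (NA stage for
# controls contributes nothing; effects only apply to case patients anyway).
eval_effect <- function(eff, grid, stage) {
  s <- if (is.na(stage)) 1 else eff$stage_scaling[[stage]]
  shape <- eval_band(band(eff$band_center, eff$fwhm, 1), grid)
  eff$delta_amplitude * s * shape
}

#' Default per-cancer spectral effects
#'
#' Each cancer type perturbs the regions reported as most discriminatory for
#' its organ-specific classifier: e.g. Amide II (~1530 cm^-1) and lipid CH
#' (~2861 cm^-1) for brain, carbohydrate C-OH (~2872 cm^-1) for breast,
#' Amide III (~1258 cm^-1) for kidney, phosphate stretches (1074/1167 cm^-1)
#' and lipid CH (~2750 cm^-1) for lung, and protein/lipid bands for the
#' remaining groups. Effect amplitude defaults to five times the replicate
#' noise standard deviation.
#'
#' @param amplitude Absorbance change at the band center for a Stage III
#'   patient (stage scaling 1).
#' @return Named list: cancer group -> list of [class_effect()].
#' @export
default_class_effects <- function(amplitude = 0.05) {
  a <- amplitude
  list(
    brain      = list(class_effect(1530,  a), class_effect(2861,  0.6 * a)),
    breast     = list(class_effect(2872,  a)),
    colorectal = list(class_effect(1530,  a), class_effect(1240,  0.6 * a)),
    kidney     = list(class_effect(1258,  a), class_effect(2920,  0.5 * a)),
    lung       = list(class_effect(1074,  a), class_effect(1167,  0.7 * a),
                      class_effect(2750,  0.5 * a)),
    ovarian    = list(class_effect(1655,  a), class_effect(1530,  0.7 * a)),
    pancreatic = list(class_effect(1655,  a), class_effect(1260,  0.7 * a)),
    prostate   = list(class_effect(1530,  a), class_effect(1357,  0.6 * a),
                      class_effect(2947,  0.5 * a))
  )
}

#' Cohort simulation configuration
#'
#' Defines the composition and noise model of a simulated cohort. Defaults
#' mirror the study design this package models: nine replicate spectra per
#' patient, eight cancer groups plus NCS/NCA controls, and cancer stage
#' proportions 231:516:410:377 (Stages I:II:III:IV).
#'
#' The replicate noise model is additive i.i.d. Gaussian noise per point,
#' one smooth second-order polynomial baseline per spectrum, and one global
#' multiplicative scatter factor per spectrum - the standard benchtop FTIR
#' artefact set.
#'
#' @param group_sizes Named integer vector of patients per group (subset of
#'   [ALL_GROUPS]); unnamed groups default to 0.
#' @param stage_proportions Length-4 positive vector, normalized internally.
#' @param bands Base band library, list of [band()] objects.
#' @param effects Named list of per-group effect lists, or `NULL` for a
#'   null (no-signal) cohort.
#' @param noise_sd Additive replicate noise standard deviation (absorbance).
#' @param drift_amplitude Scale of the per-spectrum polynomial baseline.
#' @param scatter_sd Standard deviation of the multiplicative scatter factor.
#' @param spectra_per_patient Replicate spectra per patient (default 9).
#' @param age_mean,age_sd Cohort age distribution (years).
#' @param grid Wavenumber grid for all spectra.
#' @param seed Master RNG seed; per-patient child seeds are derived from it
#'   so cohorts are extensible without reshuffling existing patients.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes,
                          stage_proportions = c(231, 516, 410, 377),
                          bands = serum_band_library(),
                          effects = default_class_effects(5 * noise_sd),
                          noise_sd = 0.01,
                          drift_amplitude = 0.005,
                          scatter_sd = 0.01,
                          spectra_per_patient = 9,
                          age_mean = 60, age_sd = 12,
                          grid = wavenumber_grid(),
                          seed = 1L) {
  sizes <- setNames(integer(length(ALL_GROUPS)), ALL_GROUPS)
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% ALL_GROUPS)) {
    stop("group_sizes must be named with labels among: ",
         paste(ALL_GROUPS, collapse = ", "))
  }
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  sizes[names(group_sizes)] <- as.integer(group_sizes)
  if (length(stage_proportions) != 4L || any(stage_proportions < 0) ||
      sum(stage_proportions) <= 0) {
    stop("stage_proportions must be 4 non-negative values with positive sum")
  }
  if (spectra_per_patient < 1) stop("spectra_per_patient must be >= 1")
  if (noise_sd < 0 || drift_amplitude < 0 || scatter_sd < 0) {
    stop("noise parameters must be >= 0")
  }
  structure(list(
    group_sizes = sizes,
    stage_proportions = stage_proportions / sum(stage_proportions),
    bands = bands, effects = effects,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    scatter_sd = scatter_sd,
    spectra_per_patient = as.integer(spectra_per_patient),
    age_mean = age_mean, age_sd = age_sd,
    grid = validate_grid(grid), seed = as.integer(seed)
  ), class = "cohort_config")
}

# Deterministic child seed per patient index: a multiplicative-congruential
# mix of (master seed, index), kept within the 32-bit integer range.
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 1299721 + 17) %%
               2147483647)
}

#' Deterministic stage allocation by largest remainder
#'
#' Allocates `n` cancer patients to Stages I-IV in the exact configured
#' proportions: floor of each expected count, with leftover patients given
#' to the stages with the largest fractional remainders (ties broken toward
#' earlier stage). With n = 1534 and proportions 231:516:410:377 this yields
#' exactly 231 Stage I, 516 Stage II, 410 Stage III and 377 Stage IV.
#'
#' @param n Number of cancer patients.
#' @param proportions Length-4 non-negative weights.
#' @return Integer vector of per-stage counts, names `I`..`IV`.
#' @export
allocate_stages <- function(n, proportions = c(231, 516, 410, 377)) {
  p <- proportions / sum(proportions)
  expect <- n * p
  counts <- floor(expect)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(expect - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  setNames(as.integer(counts), STAGES)
}

# Deterministic metadata table for a config: patient ids, group, stage, sex,
# age. Stages are dealt across cancer groups in an interleaved order so each
# group receives an approximately proportional stage mix; sex alternates F/M
# within mixed-sex groups; ages are evenly spaced quantiles of the cohort age
# distribution. Metadata is thus identical across master seeds - only the
# spectra change with the seed.
cohort_metadata_layout <- function(config) {
  rows <- list()
  for (g in ALL_GROUPS) {
    ng <- config$group_sizes[[g]]
    if (ng == 0) next
    sex <- if (g == "ovarian") rep("F", ng)
           else if (g == "prostate") rep("M", ng)
           else rep(c("F", "M"), length.out = ng)
    age <- round(stats::qnorm((seq_len(ng) - 0.5) / ng,
                              config$age_mean, config$age_sd), 1)
    age <- pmin(pmax(age, 18), 95)
    rows[[g]] <- data.frame(
      patient_id = sprintf("%s_%04d", g, seq_len(ng)),
      group = g, stage = NA_character_, sex = sex, age = age,
      within = seq_len(ng), stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  if (is.null(meta)) stop("config has no patients")
  rownames(meta) <- NULL
  is_cancer <- meta$group %in% CANCER_GROUPS
  n_cancer <- sum(is_cancer)
  if (n_cancer > 0) {
    counts <- allocate_stages(n_cancer, config$stage_proportions)
    stage_seq <- rep(STAGES, counts)
    deal <- order(meta$within[is_cancer], match(meta$group[is_cancer], ALL_GROUPS))
    meta$stage[is_cancer][deal] <- stage_seq
  }
  meta$within <- NULL
  meta
}

#' Simulate one patient with replicate spectra
#'
#' Each replicate spectrum is `scatter * (base profile + stage-scaled class
#' effects) + polynomial baseline drift + additive noise`, with all random
#' draws taken from `seed`. The same `(config, seed)` pair reproduces the
#' patient bit-for-bit.
#'
#' @param config A [cohort_config()].
#' @param patient_id Unique identifier.
#' @param group One of [ALL_GROUPS].
#' @param stage `"I"`-`"IV"` for cancer patients, `NA` for controls.
#' @param sex `"F"` or `"M"`; ovarian implies F and prostate implies M.
#' @param age Age in years.
#' @param seed Integer seed for this patient's spectra.
#' @return List of class `patient_record` with a `spectra` matrix
#'   (`spectra_per_patient` rows, one column per grid point).
#' @export
generate_patient <- function(config, patient_id, group, stage, sex, age, seed) {
  if (!group %in% ALL_GROUPS) stop("unknown group: ", group)
  if (group %in% CONTROL_GROUPS) {
    if (!is.na(stage)) stop("non-cancer patients must have stage NA")
  } else if (is.na(stage) || !stage %in% STAGES) {
    stop("cancer patients must have a stage I-IV")
  }
  if (group == "ovarian" && sex != "F") stop("ovarian cancer requires sex F")
  if (group == "prostate" && sex != "M") stop("prostate cancer requires sex M")

  grid <- config$grid
  n <- length(grid)
  signal <- render_band_profile(config$bands, grid)
  if (!is.null(config$effects) && group %in% names(config$effects)) {
    for (eff in config$effects[[group]]) {
      signal <- signal + eval_effect(eff, grid, stage)
    }
  }
  t <- seq(-1, 1, length.out = n)  # normalized axis for the drift polynomial
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- config$spectra_per_patient
  spectra <- matrix(0, nrow = k, ncol = n)
  for (j in seq_len(k)) {
    scatter <- 1 + stats::rnorm(1, 0, config$scatter_sd)
    coef <- stats::rnorm(3)
    drift <- config$drift_amplitude * (coef[1] + coef[2] * t + coef[3] * t^2)
    noise <- stats::rnorm(n, 0, config$noise_sd)
    spectra[j, ] <- scatter * signal + drift + noise
  }
  structure(list(patient_id = patient_id, group = group, stage = stage,
                 sex = sex, age = age, spectra = spectra),
            class = "patient_record")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a full cohort
#'
#' Builds the deterministic metadata layout (group sizes, largest-remainder
#' stage allocation, alternating sex, quantile-spaced ages) and then draws
#' each patient's replicate spectra from a child seed derived from the
#' master seed and the patient's position. Cohorts with the same config and
#' seed are bit-identical; cohorts differing only in seed share the same
#' metadata layout.
#'
#' @param config A [cohort_config()].
#' @return List of class `cohort` with elements `grid`, `patients`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  meta <- cohort_metadata_layout(config)
  patients <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    patients[[i]] <- generate_patient(
      config, meta$patient_id[i], meta$group[i], meta$stage[i],
      meta$sex[i], meta$age[i], seed = child_seed(config$seed, i))
  }
  names(patients) <- meta$patient_id
  new_cohort(config$grid, patients)
}

new_cohort <- function(grid, patients) {
  ids <- vapply(patients, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  n <- length(grid)
  for (p in patients) {
    if (ncol(p$spectra) != n) stop("all spectra must share the cohort grid")
  }
  structure(list(grid = validate_grid(grid), patients = patients),
            class = "cohort")
}

#' Cohort metadata as a data frame
#'
#' @param cohort A `cohort`.
#' @return Data frame with one row per patient: `patient_id`, `group`,
#'   `stage`, `sex`, `age`, `n_spectra`.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id, group = p$group,
               stage = if (is.na(p$stage)) NA_character_ else p$stage,
               sex = p$sex, age = p$age, n_spectra = nrow(p$spectra),
               stringsAsFactors = FALSE)
  })) -> meta
  rownames(meta) <- NULL
  meta
}

#' @export
print.cohort <- function(x, ...) {
  meta <- cohort_metadata(x)
  cat("FTIR cohort:", nrow(meta), "patients,",
      sum(meta$n_spectra), "spectra,",
      length(x$grid), "wavenumbers (",
      round(max(x$grid)), "-", round(min(x$grid)), "cm-1 )\n")
  print(table(meta$group)[table(meta$group) > 0])
  invisible(x)
}
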