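test_that("generate_patient is deterministic and respects the noise model", {
  cfg0 <- small_config(noise_sd = 0, drift_amplitude = 0, scatter_sd = 0,
                       effects = default_class_effects(0.05))
  p <- generate_patient(cfg0, "x1", "lung", "III", "M", 60, seed = 11)
  expect_equal(nrow(p$spectra), 9L)
  # with all noise terms off, every replicate equals profile + effects
  expect_true(all(apply(p$spectra, 2, function(col) diff(range(col)) == 0)))
  base <- render_band_profile(cfg0$bands, cfg0$grid)
  eff <- p$spectra[1, ] - base
  # lung effects live at 1074/1167/2750; elsewhere the spectrum is the base
  far <- abs(as.numeric(cfg0$grid) - 1074) > 200 &
         abs(as.numeric(cfg0$grid) - 1167) > 200 &
         abs(as.numeric(cfg0$grid) - 2750) > 200
  expect_lt(max(abs(eff[far])), 1e-6)
  expect_gt(max(eff[!far]), 0.01)

  cfg <- small_config()
  a <- generate_patient(cfg, "x1", "lung", "II", "F", 55, seed = 7)
  b <- generate_patient(cfg, "x1", "lung", "II", "F", 55, seed = 7)
  expect_identical(a, b)
  c <- generate_patient(cfg, "x1", "lung", "II", "F", 55, seed = 8)
  expect_false(identical(a$spectra, c$spectra))
})

test_that("stage scaling multiplies the injected effect", {
  cfg <- cohort_config(c(brain = 1, NCS = 1), noise_sd = 0,
                       drift_amplitude = 0, scatter_sd = 0,
                       effects = default_class_effects(0.05))
  base <- render_band_profile(cfg$bands, cfg$grid)
  eff_at <- function(stage) {
    p <- generate_patient(cfg, "p", "brain", stage, "F", 60, seed = 1)
    max(p$spectra[1, ] - base)
  }
  e1 <- eff_at("I"); e3 <- eff_at("III"); e4 <- eff_at("IV")
  expect_equal(e1 / e3, 0.5, tolerance = 1e-9)
  expect_equal(e4 / e3, 1.25, tolerance = 1e-9)
})

test_that("patient invariants are enforced", {
  cfg <- small_config()
  expect_error(generate_patient(cfg, "p", "prostate", "II", "F", 60, 1),
               "prostate")
  expect_error(generate_patient(cfg, "p", "ovarian", "II", "M", 60, 1),
               "ovarian")
  expect_error(generate_patient(cfg, "p", "NCS", "II", "M", 60, 1),
               "stage NA")
  expect_error(generate_patient(cfg, "p", "lung", NA, "M", 60, 1),
               "stage I-IV")
  expect_error(generate_patient(cfg, "p", "thyroid", "I", "M", 60, 1),
               "unknown group")
})

test_that("cohort counts, ids and replicate totals are exact", {
  cfg <- cohort_config(c(lung = 10, NCS = 10), seed = 2)
  co <- generate_cohort(cfg)
  meta <- cohort_metadata(co)
  expect_equal(nrow(meta), 20)
  expect_equal(sum(meta$n_spectra), 180)
  expect_setequal(unique(meta$group), c("lung", "NCS"))
  expect_false(anyDuplicated(meta$patient_id) > 0)
  expect_true(all(is.na(meta$stage[meta$group == "NCS"])))
  expect_true(all(meta$stage[meta$group == "lung"] %in% c("I", "II", "III", "IV")))
  expect_error(cohort_config(c(lung = -1)), ">= 0")
})

test_that("largest-remainder stage allocation reproduces the cohort's printed stage counts", {
  counts <- allocate_stages(1534, c(231, 516, 410, 377))
  expect_identical(counts, c(I = 231L, II = 516L, III = 410L, IV = 377L))
  # exactness generalizes: totals always match and deviate < 1 per stage
  for (n in c(7, 100, 747)) {
    cn <- allocate_stages(n, c(231, 516, 410, 377))
    expect_equal(sum(cn), n)
    expect_true(all(abs(cn - n * c(231, 516, 410, 377) / 1534) < 1))
  }
})

test_that("seeds change spectra but not the metadata layout", {
  cfg_a <- cohort_config(c(brain = 5, breast = 5, NCS = 6), seed = 10)
  cfg_b <- cohort_config(c(brain = 5, breast = 5, NCS = 6), seed = 11)
  a <- generate_cohort(cfg_a); b <- generate_cohort(cfg_b)
  ma <- cohort_metadata(a); mb <- cohort_metadata(b)
  expect_identical(ma, mb)
  expect_false(identical(a$patients[[1]]$spectra, b$patients[[1]]$spectra))
  # same seed: bit-identical cohorts
  expect_identical(a, generate_cohort(cfg_a))
})

test_that("a null cohort carries no class signal (two-sample check)", {
  # with all effects removed, case and control intensities at 1530 cm^-1
  # are drawn from the same distribution
  cfg <- null_config(c(lung = 100, NCS = 100), seed = 42)
  co <- generate_cohort(cfg)
  wn_i <- which(as.numeric(co$grid) == 1528)
  vals <- vapply(co$patients, function(p) mean(p$spectra[, wn_i]), 0)
  grp <- cohort_metadata(co)$group
  pv <- stats::wilcox.test(vals[grp == "lung"], vals[grp == "NCS"])$p.value
  expect_gt(pv, 0.01)
})
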