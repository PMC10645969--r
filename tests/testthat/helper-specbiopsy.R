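# Shared fixtures: small cohorts and independent oracles used across tests.

# A short fingerprint-region grid keeps unit tests fast; the 2 cm^-1 step
# puts the canonical band centers (1530, 1400, 1080 cm^-1) on the grid.
small_grid <- function() wavenumber_grid(1800, 1000, 2)

# Minimal two-group cohort config on the full default grid.
small_config <- function(sizes = c(lung = 6, NCS = 6), seed = 1L, ...) {
  cohort_config(sizes, seed = seed, ...)
}

# Null cohort: no class effects anywhere.
null_config <- function(sizes, seed = 1L, ...) {
  cohort_config(sizes, effects = NULL, seed = seed, ...)
}

# Signal cohort: one cancer group with effects at 1530 and 1080 cm^-1,
# amplitude a fixed multiple of the replicate noise sd, no stage scaling.
signal_config <- function(sizes = c(lung = 40, NCS = 40), noise_sd = 0.01,
                          snr = 5, seed = 1L, ...) {
  flat <- c(1, 1, 1, 1)
  cohort_config(
    sizes, noise_sd = noise_sd, seed = seed,
    effects = list(lung = list(
      class_effect(1530, snr * noise_sd, stage_scaling = flat),
      class_effect(1080, snr * noise_sd, stage_scaling = flat))),
    ...)
}

# Single-row hyperparameter grid: no hyperparameter search, threshold only.
one_hp <- function() data.frame(num_trees = 200, max_depth = 8, min_node = 5)

# O(n^2) pairwise Mann-Whitney AUC oracle (ties count one half).
pairwise_auc <- function(scores, is_case) {
  cs <- scores[is_case]; ct <- scores[!is_case]
  wins <- 0
  for (a in cs) for (b in ct) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(cs) * length(ct))
}

# Exhaustive threshold-scan oracle, written independently of
# select_threshold: evaluates every midpoint and the infinite sentinels by
# direct counting and applies the selection rule literally.
scan_threshold <- function(scores, is_case, target, minimum) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[is_case] > t)
    spec <- mean(scores[!is_case] <= t)
    tgt <- if (target == "sensitivity") sens else spec
    oth <- if (target == "sensitivity") spec else sens
    if (tgt >= minimum) {
      if (is.null(best) || oth > best$oth ||
          (oth == best$oth && t > best$t)) {
        best <- list(t = t, sens = sens, spec = spec, oth = oth)
      }
    }
  }
  if (is.null(best)) {  # fallback: maximize the target metric
    for (t in cand) {
      sens <- mean(scores[is_case] > t)
      spec <- mean(scores[!is_case] <= t)
      tgt <- if (target == "sensitivity") sens else spec
      if (is.null(best) || tgt > best$tgt ||
          (tgt == best$tgt && t > best$t)) {
        best <- list(t = t, sens = sens, spec = spec, tgt = tgt)
      }
    }
  }
  best
}

# Experiment-result skeleton with a prescribed per-patient history: within
# each stage, a fraction of patients is always correct and the rest never.
history_fixture <- function(stage_counts, correct_frac, appearances = 15) {
  n <- sum(stage_counts)
  meta <- data.frame(
    patient_id = sprintf("p%04d", seq_len(n)),
    group = "lung",
    stage = rep(names(stage_counts), stage_counts),
    sex = "M", age = 60, n_spectra = 9, stringsAsFactors = FALSE)
  correct <- unlist(mapply(function(k, f) {
    n_ok <- round(f * k)
    rep(c(appearances, 0), c(n_ok, k - n_ok))
  }, stage_counts, correct_frac, SIMPLIFY = FALSE))
  structure(list(
    history = data.frame(patient_id = meta$patient_id,
                         appearances = appearances, correct = correct,
                         stringsAsFactors = FALSE),
    metadata = meta), class = "experiment_result")
}

# Linearly separable two-cloud feature fixture.
separable_features <- function(n_per_class = 20, p = 5, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(features = x,
       is_case = rep(c(FALSE, TRUE), each = n_per_class))
}
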