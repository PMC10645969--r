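meta_fixture <- function(n_case = 50, n_ctrl = 50) {
  data.frame(
    patient_id = c(sprintf("ca%03d", seq_len(n_case)),
                   sprintf("co%03d", seq_len(n_ctrl))),
    group = c(rep("lung", n_case), rep("NCS", n_ctrl)),
    stage = c(rep("II", n_case), rep(NA, n_ctrl)),
    sex = "M", age = 60, n_spectra = 9, stringsAsFactors = FALSE)
}

test_that("70:30 splits are disjoint, exhaustive and class-stratified", {
  meta <- meta_fixture()
  task <- task_definition("lung", "NCS")
  splits <- make_splits(meta, task, n_resamples = 20, seed = 3)
  expect_length(splits, 20)
  for (sp in splits) {
    expect_length(sp$train_ids, 70)
    expect_length(sp$test_ids, 30)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), meta$patient_id)
    # stratification: 35 cases in train
    expect_equal(sum(grepl("^ca", sp$train_ids)), 35)
  }
  # reproducible under seed, different across seeds
  expect_identical(splits, make_splits(meta, task, n_resamples = 20, seed = 3))
  expect_false(identical(splits, make_splits(meta, task, n_resamples = 20, seed = 4)))
})

test_that("sex filters restrict eligibility and can make a task infeasible", {
  meta <- meta_fixture(10, 10)
  meta$sex[meta$group == "NCS"] <- rep(c("F", "M"), 5)
  task_f <- task_definition("lung", "NCS", sex_filter = "F")
  expect_error(make_splits(meta, task_f, seed = 1), "fewer than 2")
  meta$sex[meta$group == "lung"] <- "F"
  splits <- make_splits(meta, task_f, n_resamples = 2, seed = 1)
  expect_length(c(splits[[1]]$train_ids, splits[[1]]$test_ids), 15)
})

test_that("threshold selection matches an exhaustive scan on random score sets", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    is_case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_case) || all(is_case)) next
    scores <- round(runif(n), sample(1:3, 1))  # ties likely
    target <- sample(c("sensitivity", "specificity"), 1)
    minimum <- sample(c(0.45, 0.7, 0.9, 0.98), 1)
    got <- select_threshold(scores, is_case, target, minimum)
    want <- scan_threshold(scores, is_case, target, minimum)
    expect_equal(got$threshold, want$t)
    expect_equal(got$sensitivity, want$sens)
    expect_equal(got$specificity, want$spec)
  }
})

test_that("threshold selection handles the worked corner cases", {
  # separable: sens target met with sens = spec = 1
  sel <- select_threshold(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE),
                          "sensitivity", 0.9)
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
  expect_true(sel$threshold > 0.2 && sel$threshold < 0.8)
  # a low-sensitivity target keeps the high-specificity qualifier
  sel2 <- select_threshold(c(0.9, 0.1, 0.05, 0.2), c(TRUE, TRUE, FALSE, FALSE),
                           "sensitivity", 0.45)
  expect_gte(sel2$sensitivity, 0.45)
  expect_equal(sel2$specificity, 1)
  # minimum 1 with overlap forces the -Inf sentinel
  sel3 <- select_threshold(c(0.4, 0.6), c(TRUE, FALSE), "sensitivity",
                           minimum = 0.999)
  expect_equal(sel3$threshold, -Inf)  # only the sentinel reaches sens 1
  expect_equal(sel3$sensitivity, 1)
  expect_equal(sel3$specificity, 0)
  # inverted separation: only the +Inf sentinel reaches the spec minimum
  sel4 <- select_threshold(c(0.4, 0.6), c(TRUE, FALSE), "specificity",
                           minimum = 0.999)
  expect_equal(sel4$threshold, Inf)
  expect_equal(sel4$sensitivity, 0)
  expect_equal(sel4$specificity, 1)
  expect_error(select_threshold(c(0.2, 0.4), c(TRUE, TRUE), "sensitivity", 0.9),
               "both classes")
})

test_that("raising a sensitivity minimum never raises achieved specificity", {
  set.seed(5)
  for (i in 1:20) {
    scores <- runif(30)
    is_case <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(is_case) || all(is_case)) next
    specs <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), function(mn) {
      select_threshold(scores, is_case, "sensitivity", mn)$specificity
    }, 0)
    expect_true(all(diff(specs) <= 1e-12))
  }
})

test_that("consensus voting follows majority with ties toward case", {
  thr <- 0.5
  expect_true(consensus_predict(c(rep(0.9, 5), rep(0.1, 4)), thr)$label)
  expect_false(consensus_predict(rep(0.1, 9), thr)$label)
  # 4 of 8 above: tie broken toward case
  expect_true(consensus_predict(c(rep(0.9, 4), rep(0.1, 4)), thr)$label)
  expect_false(consensus_predict(c(rep(0.9, 3), rep(0.1, 5)), thr)$label)
  p <- consensus_predict(c(0.2, 0.9, 0.4), thr)
  expect_equal(p$patient_score, 0.4)
  expect_error(consensus_predict(numeric(0), thr), "at least one")
})

test_that("vertical ROC averaging reproduces closed-form mixtures", {
  perfect <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  diagonal <- roc_curve(rep(0.5, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(mean_roc(list(perfect))$auc, 1, tolerance = 1e-9)
  avg <- mean_roc(list(perfect, diagonal))
  expect_equal(avg$auc, 0.75, tolerance = 0.01)
  expect_true(all(diff(avg$tpr) >= 0))
  expect_equal(avg$tpr[length(avg$tpr)], 1)
  # averaging identical curves is the identity on the FPR grid
  same <- mean_roc(list(perfect, perfect, perfect))
  expect_equal(same$tpr, mean_roc(list(perfect))$tpr)
})

test_that("inner tuning meets its target on separable patient scores", {
  set.seed(2)
  n_pat <- 20
  pid <- rep(sprintf("p%02d", 1:n_pat), each = 3)
  is_case <- rep(c(TRUE, FALSE), each = n_pat / 2 * 3)
  x <- matrix(rnorm(length(pid) * 6), ncol = 6)
  colnames(x) <- paste0("f", 1:6)
  x[is_case, 1] <- x[is_case, 1] + 6
  task <- task_definition("lung", "NCS", target_metric = "sensitivity",
                          target_minimum = 0.9)
  tune <- inner_tune(x, pid, is_case, task, grid = one_hp(), k = 3, seed = 5)
  # separable scores: the target is met with perfect specificity (the
  # tie-break toward higher thresholds may leave sensitivity at the target)
  expect_gte(tune$cv_sensitivity, 0.9)
  expect_equal(tune$cv_specificity, 1)
  expect_equal(tune$cv_auc, 1)
  expect_identical(tune$hp$max_depth, one_hp()$max_depth)
})

test_that("run_task aggregates resamples consistently", {
  co <- generate_cohort(signal_config(c(lung = 16, NCS = 16), seed = 8))
  task <- task_definition("lung", "NCS", target_metric = "sensitivity",
                          target_minimum = 0.9)
  res <- run_task(co, task, grid = one_hp(), n_resamples = 2, k_inner = 3,
                  seed = 4)
  expect_s3_class(res, "experiment_result")
  expect_length(res$resamples, 2)
  sens <- vapply(res$resamples, `[[`, 0, "test_sensitivity")
  expect_gte(res$summary$sensitivity_mean, min(sens))
  expect_lte(res$summary$sensitivity_mean, max(sens))
  # leakage audit: no patient in both sides of any resample
  splits <- make_splits(cohort_metadata(co), task, n_resamples = 2, seed = 4)
  for (sp in splits) {
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  }
  # per-patient history totals match the number of test predictions
  expect_equal(sum(res$history$appearances),
               sum(vapply(res$resamples, function(r) nrow(r$predictions), 0)))
  # determinism of the whole experiment
  res2 <- run_task(co, task, grid = one_hp(), n_resamples = 2, k_inner = 3,
                   seed = 4)
  expect_equal(res$summary, res2$summary)
})
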