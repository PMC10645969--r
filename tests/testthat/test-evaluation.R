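test_that("ROC curves hit the canonical fixed points", {
  # separable scores pass through (0, 1)
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(auc(rc), 1)
  # all-tied scores collapse to the chance diagonal
  rc2 <- roc_curve(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(rc2$fpr, c(0, 1))
  expect_equal(rc2$tpr, c(0, 1))
  expect_equal(auc(rc2), 0.5)
  # 4-patient worked case: 3 of 4 case-control pairs won
  rc3 <- roc_curve(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc(rc3), 0.75)
  # antisymmetry under label swap
  rc4 <- roc_curve(c(0.8, 0.4, 0.6, 0.2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(auc(rc4), 0.25)
  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
  expect_error(roc_curve(c(NA, 0.2), c(TRUE, FALSE)), "finite")
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    is_case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_case) || all(is_case)) next
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # with and without ties
    expect_equal(auc(roc_curve(scores, is_case)),
                 pairwise_auc(scores, is_case), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(23)
  scores <- runif(80)
  is_case <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  expect_equal(auc(roc_curve(scores, is_case)),
               as.numeric(pROC::auc(pROC::roc(is_case, scores,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("confusion metrics reproduce the canonical worked pairing", {
  # 57 of 100 cases and 99 of 100 controls called correctly
  truth <- rep(c(TRUE, FALSE), each = 100)
  pred <- c(rep(TRUE, 57), rep(FALSE, 43), rep(TRUE, 1), rep(FALSE, 99))
  cm <- confusion_at(pred, truth)
  expect_equal(cm$sensitivity, 0.57)
  expect_equal(cm$specificity, 0.99)
  all_right <- confusion_at(truth, truth)
  expect_equal(unlist(all_right), c(sensitivity = 1, specificity = 1,
                                    ppv = 1, npv = 1))
  # inverted predictions flip the error structure (direct hand count)
  inv <- confusion_at(!pred, truth)
  expect_equal(inv$sensitivity, 0.43)
  expect_equal(inv$specificity, 0.01)
  expect_error(confusion_at(pred, rep(TRUE, 200)), "both cases")
})

test_that("Bayes PPV obeys its boundary and worked values", {
  expect_equal(ppv_at_prevalence(0.5, 1, 0.1), 1)
  expect_equal(ppv_at_prevalence(0.9, 0.6, 0), 0)
  # direct arithmetic: 0.02*0.9 / (0.02*0.9 + 0.98*0.4)
  expect_equal(ppv_at_prevalence(0.90, 0.60, 0.02), 0.018 / (0.018 + 0.392))
  expect_equal(round(ppv_at_prevalence(0.90, 0.60, 0.02), 4), 0.0439)
  expect_true(is.na(ppv_at_prevalence(0, 1, 0)))
  expect_error(ppv_at_prevalence(1.2, 0.5, 0.5), "0, 1")
})

test_that("PPV is monotone in prevalence and specificity", {
  prevs <- seq(0, 1, by = 0.05)
  ppv_prev <- vapply(prevs, function(p) ppv_at_prevalence(0.8, 0.9, p), 0)
  expect_true(all(diff(ppv_prev) >= -1e-12))
  specs <- seq(0, 0.999, by = 0.05)
  ppv_spec <- vapply(specs, function(s) ppv_at_prevalence(0.8, s, 0.05), 0)
  expect_true(all(diff(ppv_spec) >= -1e-12))
})

test_that("detection rates average per-patient histories by category", {
  res <- history_fixture(c(I = 10, II = 10), c(1, 0.5))
  d <- detection_rates(res, "stage")
  tab <- d$table
  expect_equal(tab$rate[tab$category == "I"], 1)
  expect_equal(tab$rate[tab$category == "II"], 0.5)
  expect_equal(tab$n, c(10, 10))
  expect_equal(d$n_excluded, 0)
  # a patient correct in 12 of 15 appearances has rate 0.8
  res$history$correct[1] <- 12
  d2 <- detection_rates(res, "stage")
  expect_equal(d2$table$rate[d2$table$category == "I"],
               mean(c(0.8, rep(1, 9))))
  # zero-appearance patients are excluded and counted
  res$history$appearances[2] <- 0
  d3 <- detection_rates(res, "stage")
  expect_equal(d3$n_excluded, 1)
  expect_equal(d3$table$n[d3$table$category == "I"], 9)
  expect_error(detection_rates(res, "hospital"), "unknown")
})

test_that("category rates are invariant to patient order", {
  res <- history_fixture(c(I = 6, III = 4), c(0.5, 1))
  perm <- sample(nrow(res$history))
  res2 <- res
  res2$history <- res2$history[perm, ]
  res2$metadata <- res2$metadata[perm, ]
  expect_equal(detection_rates(res, "stage")$table,
               detection_rates(res2, "stage")$table)
})

test_that("pooled rates are size-weighted with half-up integer rounding", {
  expect_equal(pooled_rate(c(64, 51), c(231, 516)), 55)
  expect_equal(pooled_rate(c(99, 96, 99, 99), c(231, 516, 410, 377)), 98)
  expect_equal(pooled_rate(73, 123), 73)
  expect_error(pooled_rate(c(50, 60), 100), "mismatch")
  expect_error(pooled_rate(c(50, 60), c(10, 0)), "positive")
  expect_equal(round_half_up(c(92.5, 91.46, 84.88)), c(93, 91, 85))
})
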