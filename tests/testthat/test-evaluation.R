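test_that("confusion counts follow the RIF-positive convention", {
  truth <- c(rep("RIF", 6), rep("control", 4))
  cc <- confusion_counts(truth, truth)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 6, fp = 0, fn = 0, tn = 4))
  cc2 <- confusion_counts(rep("control", 5),
                          c("RIF", "RIF", "RIF", "control", "control"))
  expect_equal(unlist(cc2[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 3, tn = 2))
  # order invariance
  set.seed(2)
  calls <- sample(c("RIF", "control"), 30, replace = TRUE)
  tr <- sample(c("RIF", "control"), 30, replace = TRUE)
  p <- sample(30)
  expect_equal(confusion_counts(calls, tr), confusion_counts(calls[p], tr[p]))
  expect_error(confusion_counts("maybe", "RIF"), "unknown label")
})

test_that("Wilson intervals reproduce the published diagnostic CIs", {
  expect_equal(round(100 * wilson_ci(7, 7), 1),
               c(low = 64.6, high = 100.0))
  expect_equal(round(100 * wilson_ci(7, 12), 1),
               c(low = 32.0, high = 80.7))
  ci0 <- wilson_ci(0, 5)
  expect_identical(unname(ci0["low"]), 0)
  expect_true(all(ci0 >= 0 & ci0 <= 1))
  ci_all <- wilson_ci(5, 5)
  expect_identical(unname(ci_all["high"]), 1)
  expect_error(wilson_ci(3, 0), "n must be")
  expect_error(wilson_ci(6, 5), "0..n")
})

test_that("metric tables match the published discovery and validation columns", {
  disc <- metrics_report(confusion_counts(
    c(rep("RIF", 31), rep("control", 50)),
    c(rep("RIF", 28), rep("control", 3), rep("RIF", 3), rep("control", 47))))
  get <- function(tab, m) round(unlist(
    tab[tab$metric == m, c("estimate", "ci_low", "ci_high")]), 1)
  expect_equal(unname(get(disc, "sensitivity")), c(90.3, 75.1, 96.7))
  expect_equal(unname(get(disc, "specificity")), c(94.0, 83.8, 97.9))
  expect_equal(unname(get(disc, "accuracy")), c(92.6, 84.8, 96.6))
  expect_equal(unname(get(disc, "PPV")), c(90.3, 75.1, 96.7))
  expect_equal(unname(get(disc, "NPV")), c(94.0, 83.8, 97.9))

  val <- metrics_report(structure(list(tp = 7, fp = 0, fn = 5, tn = 22),
                                  class = "confusion_counts"))
  expect_equal(unname(get(val, "PPV"))[1], 100)
  expect_equal(unname(get(val, "NPV"))[1], 81.5)
  expect_equal(unname(get(val, "accuracy"))[1], 85.3)

  # symmetric table: sens = spec, PPV = NPV
  sym <- metrics_report(structure(list(tp = 9, fp = 2, fn = 2, tn = 9),
                                  class = "confusion_counts"))
  expect_equal(sym$estimate[sym$metric == "sensitivity"],
               sym$estimate[sym$metric == "specificity"])
  expect_equal(sym$estimate[sym$metric == "PPV"],
               sym$estimate[sym$metric == "NPV"])

  # zero denominator reports NA, not 0
  none <- metrics_report(structure(list(tp = 0, fp = 0, fn = 3, tn = 2),
                                   class = "confusion_counts"))
  expect_true(is.na(none$estimate[none$metric == "PPV"]))
})

test_that("Fisher exact P matches exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2, 2)), 0.1)
  expect_warning(p <- fisher_exact_2x2(matrix(c(0, 0, 2, 3), 2, 2)),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2, 2)))
  # spot checks against the enumeration oracle (the full sweep over all
  # tables with total <= 12 runs in the acceptance suite)
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4) + 1, 2, 2)
    expect_equal(fisher_exact_2x2(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("AUC equals pairwise concordance with half credit for ties", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
                     c("RIF", "RIF", "control", "control"))
  expect_equal(perfect$auc, 1.0)
  ties <- roc_auc(rep(0.5, 6), rep(c("RIF", "control"), 3))
  expect_equal(ties$auc, 0.5)
  ex <- roc_auc(c(0.9, 0.35, 0.4, 0.3),
                c("RIF", "RIF", "control", "control"))
  expect_equal(ex$auc, 0.75)
  expect_true(ex$ci["low"] <= ex$auc && ex$auc <= ex$ci["high"])
  expect_error(roc_auc(1:3 / 4, rep("RIF", 3)), "both classes")

  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    truth <- c("RIF", "control",
               sample(c("RIF", "control"), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # coarse grid so ties occur
    expect_equal(roc_auc(scores, truth)$auc,
                 auc_concordance_oracle(scores, truth), tolerance = 1e-12)
  }
})

test_that("monotone score transforms preserve the ROC ordering", {
  set.seed(7)
  scores <- runif(30)
  truth <- sample(c("RIF", "control"), 30, replace = TRUE,
                  prob = c(0.4, 0.6))
  a1 <- roc_auc(scores, truth)$auc
  a2 <- roc_auc(plogis(5 * scores - 2), truth)$auc
  expect_equal(a1, a2)
})

test_that("classification_report assembles all pieces coherently", {
  set.seed(9)
  scored <- data.frame(
    score = c(runif(12, 0.3, 1), runif(20, 0, 0.7)),
    truth = c(rep("RIF", 12), rep("control", 20)))
  scored$call <- ifelse(scored$score >= 0.5, "RIF", "control")
  rep <- classification_report(scored)
  expect_equal(rep$counts$tp + rep$counts$fn, 12)
  expect_equal(rep$counts$tn + rep$counts$fp, 20)
  expect_true(rep$fisher_p >= 0 && rep$fisher_p <= 1)
  expect_equal(rep$roc$auc, auc_concordance_oracle(scored$score,
                                                   scored$truth))
  acc <- rep$metrics[rep$metrics$metric == "accuracy", ]
  expect_equal(acc$numerator, rep$counts$tp + rep$counts$tn)
})
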