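test_that("confusion counting follows the >= threshold convention", {
  cm <- confusion_from_scores(c(1, 0), c(0.4, 0.6), threshold = 0.5)
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 0L, fp = 1L, fn = 1L, tn = 0L))
  perfect <- confusion_from_scores(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$fp + perfect$fn, 0)
  # tie at the threshold counts as a positive call
  tie <- confusion_from_scores(c(0, 1), c(0.5, 0.5), threshold = 0.5)
  expect_equal(c(tie$tp, tie$fp), c(1L, 1L))
  expect_error(confusion_from_scores(integer(0), numeric(0)), "empty")
})

test_that("confusion counting matches a brute-force loop on random data", {
  set.seed(1)
  labels <- rbinom(1000, 1, 0.3)
  scores <- runif(1000)
  t <- 0.35
  cm <- confusion_from_scores(labels, scores, t)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:1000) {
    if (scores[i] >= t) {
      if (labels[i] == 1) tp <- tp + 1 else fp <- fp + 1
    } else {
      if (labels[i] == 1) fn <- fn + 1 else tn <- tn + 1
    }
  }
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(tp, fp, fn, tn))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 1000)
})

test_that("published benchmark rows recompute to their printed metrics", {
  # two spot rows; the full table is exercised by the comparison formatter
  m <- compute_metrics(confusion_matrix(273, 38, 183, 5121))
  expect_equal(round_half_up(m$accuracy), 0.961)
  expect_equal(round_half_up(m$sensitivity), 0.599)
  expect_equal(round_half_up(m$specificity), 0.993)
  expect_equal(round_half_up(m$precision), 0.878)
  expect_equal(round_half_up(m$npv), 0.965)
  expect_equal(round_half_up(m$f1), 0.712)
  expect_equal(round_half_up(m$prevalence), 0.081)
  m2 <- compute_metrics(confusion_matrix(147, 11, 309, 5148))
  expect_equal(round_half_up(m2$accuracy), 0.943)
  expect_equal(round_half_up(m2$precision), 0.930)
  expect_equal(round_half_up(m2$sensitivity), 0.322)
})

test_that("zero denominators flag metrics as undefined without erroring", {
  m <- compute_metrics(confusion_matrix(0, 0, 0, 10))
  expect_equal(m$accuracy, 1)
  expect_equal(m$specificity, 1)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_setequal(attr(m, "undefined"), c("sensitivity", "recall", "precision", "f1"))
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "all-zero")
  td <- tidy(m)
  expect_true(td$undefined[td$metric == "precision"])
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(2)
  for (i in 1:50) {
    cm <- confusion_matrix(sample(0:500, 1), sample(0:500, 1),
                           sample(0:500, 1), sample(1:500, 1))
    m <- compute_metrics(cm)
    expect_identical(m$sensitivity, m$recall)
    if (!is.na(m$sensitivity) && !is.na(m$specificity)) {
      expect_equal(m$accuracy,
                   m$prevalence * m$sensitivity +
                     (1 - m$prevalence) * m$specificity)
    }
    vals <- unlist(m)
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
  }
})

test_that("half-away-from-zero rounding differs from banker's rounding", {
  expect_equal(round_half_up(0.5965, 3), 0.597)
  expect_equal(round_half_up(-0.0005, 3), -0.001)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("AUC equals the worked example and the closed-form limits", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc, 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("trapezoidal AUC equals concordant-pair counting", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(20:400, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(runif(n), sample(1:3, 1))  # coarse scores force ties
    expect_equal(roc_auc(labels, scores)$auc,
                 auc_pair_counting(labels, scores))
  }
})

test_that("the comparison table reproduces every published cell", {
  ref <- published_table2()
  tab <- comparison_table(reference_confusions())
  expect_equal(tab$metric,
               c("Accuracy", "Sensitivity", "Specificity", "Prevalence",
                 "Precision", "NPV", "F1 Score", "TP", "FP", "FN", "TN"))
  for (i in seq_len(nrow(ref))) {
    col <- tab[[paste(ref$backbone[i], ref$method[i], sep = "_")]]
    expect_equal(col[1:7], as.numeric(ref[i, c("accuracy", "sensitivity",
                                               "specificity", "prevalence",
                                               "precision", "npv", "f1")]))
    expect_equal(col[8:11], as.numeric(ref[i, c("tp", "fp", "fn", "tn")]))
  }
})

test_that("comparison table writes CSV and JSON faithfully", {
  out <- withr::local_tempdir()
  runs <- reference_confusions()[1, ]
  csv <- file.path(out, "t.csv"); json <- file.path(out, "t.json")
  tab <- comparison_table(runs, csv = csv, json = json)
  expect_equal(ncol(tab), 2)  # metric column + one run
  rt <- utils::read.csv(csv)
  expect_equal(rt[[2]], tab[[2]])
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js[[2]], tab[[2]])
  expect_error(comparison_table(runs[0, ]), "at least one")
})
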