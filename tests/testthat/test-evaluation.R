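test_that("label tallies follow the reported TN convention", {
  cm <- confusion_matrix(c("0", "0", "0", "0", "1", "1", "1", "1", "1", "1"),
                         c("0", "0", "0", "1", "0", "0", "1", "1", "1", "1"))
  # counts: [[3,1],[2,4]] indexed (truth, predicted)
  expect_equal(unclass(cm), matrix(c(3L, 2L, 1L, 4L), 2,
                                   dimnames = list(truth = c("0", "1"),
                                                   predicted = c("0", "1"))))
  t0 <- tally_label(cm, "0")
  expect_equal(t0[c("TP", "FP", "FN", "TN")],
               list(TP = 3, FP = 2, FN = 1, TN = 4))
  # for two classes the two conventions coincide
  t0s <- tally_label(cm, "0", tn_convention = "standard")
  expect_equal(t0s$TN, 4)
  expect_error(tally_label(cm, "zebra"), "not present")
})

test_that("the two TN conventions differ exactly by the off-diagonal mass", {
  cm <- confusion_matrix(rep(c("a", "b", "c"), times = c(5, 5, 5)),
                         c("a","a","a","b","c", "b","b","b","a","c",
                           "c","c","c","a","a"))
  for (l in c("a", "b", "c")) {
    t_rep <- tally_label(cm, l, "tp_rest")
    t_std <- tally_label(cm, l, "standard")
    expect_equal(t_rep$TN, sum(diag(unclass(cm))) - cm[l, l])
    expect_equal(t_std$TN, sum(cm) - t_std$TP - t_std$FP - t_std$FN)
  }
})

test_that("degenerate tallies behave", {
  cm <- confusion_matrix(c("a", "b"), c("a", "b"))
  cm[] <- 0L
  t <- tally_label(cm, "a")
  expect_equal(unlist(t[c("TP", "FP", "FN", "TN")]), c(TP = 0, FP = 0,
                                                       FN = 0, TN = 0))
  expect_warning(expect_equal(f1_score(t), 0), "F1")
  id <- confusion_matrix(rep(c("a", "b"), each = 5), rep(c("a", "b"), each = 5))
  ta <- tally_label(id, "a")
  expect_equal(c(ta$FP, ta$FN), c(0, 0))
  expect_equal(f1_score(ta), 1)
})

test_that("metric closed forms give the textbook values", {
  t1 <- structure(list(TP = 2, FP = 1, FN = 1, TN = 0, label = "x"),
                  class = "label_tally")
  expect_equal(f1_score(t1), 2 / 3, tolerance = 1e-12)
  t2 <- structure(list(TP = 0, FP = 3, FN = 2, TN = 0, label = "x"),
                  class = "label_tally")
  expect_equal(f1_score(t2), 0)
  t3 <- structure(list(TP = 8, FP = 1, FN = 2, TN = 9, label = "x"),
                  class = "label_tally")
  ssa <- sensitivity_specificity_accuracy(t3)
  expect_equal(unname(ssa["sensitivity"]), 0.8)
  expect_equal(unname(ssa["specificity"]), 0.9)
  t4 <- structure(list(TP = 3, FP = 2, FN = 1, TN = 4, label = "x"),
                  class = "label_tally")
  expect_equal(unname(sensitivity_specificity_accuracy(t4)["accuracy"]), 0.7)
})

test_that("chance level is 100/n to two decimals", {
  expect_equal(chance_level(7), 14.29)
  expect_equal(chance_level(2), 50)
  expect_equal(chance_level(4), 25)
})

test_that("summed per-label TPs over total equals multi-class accuracy", {
  set.seed(11)
  truth <- sample(letters[1:4], 200, TRUE)
  pred <- ifelse(runif(200) < 0.6, truth, sample(letters[1:4], 200, TRUE))
  cm <- confusion_matrix(truth, pred)
  tps <- vapply(letters[1:4], function(l) tally_label(cm, l)$TP, numeric(1))
  expect_equal(sum(tps) / sum(cm), mean(truth == pred))
})

test_that("macro-F1 is invariant to label permutation", {
  set.seed(12)
  truth <- sample(c("x", "y", "z"), 120, TRUE)
  pred <- sample(c("x", "y", "z"), 120, TRUE)
  macro <- function(t, p) {
    cm <- confusion_matrix(t, p)
    mean(vapply(rownames(cm), function(l) {
      suppressWarnings(f1_score(tally_label(cm, l)))
    }, numeric(1)))
  }
  map <- c(x = "z", y = "x", z = "y")
  expect_equal(macro(truth, pred), macro(map[truth], map[pred]))
})

test_that("ROC handles separation, ties and the rank-statistic identity", {
  # perfect separation
  r <- roc_one_vs_rest(c(0.9, 0.8, 0.2, 0.1), c("a", "a", "b", "b"), "a")
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  expect_error(roc_one_vs_rest(c(0.4, 0.6), c("a", "a"), "a"), "positive")

  # AUC equals Mann-Whitney U / (n_pos * n_neg) on random instances with ties
  set.seed(13)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    lab <- sample(c("p", "n"), n, TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    sc <- round(runif(n), sample(1:3, 1))  # rounding creates ties
    r <- roc_one_vs_rest(sc, lab, "p")
    ranks <- rank(sc)
    n_pos <- sum(lab == "p"); n_neg <- sum(lab == "n")
    u <- sum(ranks[lab == "p"]) - n_pos * (n_pos + 1) / 2
    expect_equal(r$auc, u / (n_pos * n_neg), tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    lab <- sample(c("p", "n"), 60, TRUE)
    sc <- rnorm(60) + (lab == "p") * runif(1, 0, 2)
    ours <- roc_one_vs_rest(sc, lab, "p")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = lab, predictor = sc, levels = c("n", "p"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("scores independent of labels give chance AUC", {
  set.seed(15)
  lab <- sample(c("p", "n"), 4000, TRUE)
  sc <- rnorm(4000)
  expect_lt(abs(roc_one_vs_rest(sc, lab, "p")$auc - 0.5), 0.05)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(16)
  lab <- sample(c("p", "n"), 80, TRUE)
  sc <- rnorm(80)
  a0 <- roc_one_vs_rest(sc, lab, "p")$auc
  for (f in list(function(x) 3 * x + 2, exp, function(x) atan(x) / pi + 0.5)) {
    expect_equal(roc_one_vs_rest(f(sc), lab, "p")$auc, a0, tolerance = 1e-12)
  }
})

test_that("confusion-matrix normalization divides rows by label counts", {
  cm <- confusion_matrix(rep(c("a", "b"), times = c(6, 2)),
                         c(rep("a", 5), "b", "a", "b"))
  nm <- normalize_confusion(cm)
  expect_equal(rowSums(nm), c(a = 1, b = 1))
  expect_equal(nm["a", "a"], 5 / 6)
})

test_that("metrics_report aggregates per-label metrics and AUC", {
  set.seed(17)
  truth <- sample(c("a", "b", "c"), 90, TRUE)
  scores <- matrix(runif(90 * 3), 90, 3,
                   dimnames = list(NULL, c("p_a", "p_b", "p_c")))
  scores[cbind(seq_len(90), match(truth, c("a", "b", "c")))] <-
    scores[cbind(seq_len(90), match(truth, c("a", "b", "c")))] + 0.8
  pred <- c("a", "b", "c")[max.col(scores)]
  rep <- metrics_report(truth, pred, scores = as.data.frame(scores))
  expect_equal(rep$overall_accuracy, mean(truth == pred))
  expect_equal(nrow(rep$by_label), 3L)
  expect_true(all(rep$by_label$auc > 0.5))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_labels, 3L)
})
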