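# Confusion-matrix reductions, the binary metric suite, multiclass MCC,
# and ROC/PR curves against brute-force oracles.

# the reference test-set confusion matrix: 500 tiles/class, two lung_aca
# tiles called lung_scc and two lung_scc tiles called lung_aca
reference_cm <- function() {
  cm <- diag(500L, 5)
  dimnames(cm) <- list(truth = bilight_classes(),
                       predicted = bilight_classes())
  cm["lung_aca", "lung_aca"] <- 498L; cm["lung_aca", "lung_scc"] <- 2L
  cm["lung_scc", "lung_scc"] <- 498L; cm["lung_scc", "lung_aca"] <- 2L
  cm
}

test_that("one-vs-rest reduction conserves counts", {
  cm <- reference_cm()
  expect_equal(sum(cm), 2500)
  tallies <- lapply(1:5, function(c) one_vs_rest(cm, c))
  expect_equal(sum(vapply(tallies, `[[`, numeric(1), "FN")), 4)
  expect_equal(sum(vapply(tallies, `[[`, numeric(1), "TP")), sum(diag(cm)))
  for (t in tallies) expect_equal(t$TP + t$TN + t$FP + t$FN, 2500)
  perfect <- diag(10L, 4)
  for (c in 1:4) {
    t <- one_vs_rest(perfect, c)
    expect_equal(t$FP, 0); expect_equal(t$FN, 0)
  }
})

test_that("binary metrics match direct evaluation of their formulas", {
  m <- binary_metrics(list(TP = 498, FN = 2, FP = 2, TN = 1998))
  expect_equal(m$precision, 0.996)
  expect_equal(m$recall, 0.996)
  expect_equal(m$mcc, (498 * 1998 - 2 * 2) / sqrt(500 * 500 * 2000 * 2000))
  expect_equal(m$mcc, 0.995, tolerance = 1e-4)
  perfect <- binary_metrics(list(TP = 7, FN = 0, FP = 0, TN = 13))
  for (k in c("accuracy", "precision", "recall", "f1", "mcc"))
    expect_equal(perfect[[k]], 1)
  allwrong <- binary_metrics(list(TP = 0, FN = 5, FP = 5, TN = 0))
  expect_equal(allwrong$mcc, -1)
  expect_error(binary_metrics(list(TP = 0, FN = 0, FP = 0, TN = 0)), "empty")
})

test_that("F1 is the harmonic mean of its own precision and recall on
           random tallies", {
  set.seed(8)
  for (i in 1:200) {
    t <- as.list(stats::setNames(sample(0:50, 4, replace = TRUE),
                                 c("TP", "TN", "FP", "FN")))
    if (sum(unlist(t)) == 0) next
    m <- binary_metrics(t)
    for (k in c("accuracy", "precision", "recall", "f1"))
      expect_true(m[[k]] >= 0 && m[[k]] <= 1)
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("the reference confusion matrix reproduces the published global
           figures", {
  g <- global_metrics(reference_cm())
  expect_equal(g$accuracy, 0.9984)
  expect_equal(g$multiclass_mcc, 0.998, tolerance = 1e-3)
  expect_equal(g$macro_precision, g$macro_recall)
})

test_that("multiclass MCC reduces to the binary formula at C = 2 and
           vanishes on uniform confusion", {
  set.seed(9)
  for (i in 1:50) {
    cm <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(cm) == 0) || any(colSums(cm) == 0)) next
    bin <- binary_metrics(list(TP = cm[1, 1], FN = cm[1, 2],
                               FP = cm[2, 1], TN = cm[2, 2]))
    expect_equal(global_metrics(cm)$multiclass_mcc, bin$mcc,
                 tolerance = 1e-12)
  }
  expect_equal(global_metrics(matrix(7, 5, 5))$multiclass_mcc, 0)
  # invariance under class relabeling
  cm <- reference_cm()
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(global_metrics(cm[perm, perm])$multiclass_mcc,
               global_metrics(cm)$multiclass_mcc)
})

# brute-force AUC: fraction of correctly ordered positive-negative pairs,
# ties counting one half
pair_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

test_that("ROC AUC equals the pair-counting oracle, including ties", {
  scores <- cbind(c(0.9, 0.8, 0.4, 0.2), 1 - c(0.9, 0.8, 0.4, 0.2))
  labels <- c(1, 2, 1, 2)
  out <- roc_pr_curves(scores, labels, classes = c("pos", "neg"))
  expect_equal(out$pos$roc_auc, 0.75)
  expect_equal(out$pos$roc_auc, pair_auc(scores[, 1], labels == 1))
  # perfect separation and all-tied scores
  s2 <- cbind(c(0.9, 0.8, 0.3, 0.1), 1 - c(0.9, 0.8, 0.3, 0.1))
  expect_equal(roc_pr_curves(s2, c(1, 1, 2, 2),
                             c("pos", "neg"))$pos$roc_auc, 1)
  s3 <- cbind(rep(0.5, 6), rep(0.5, 6))
  expect_equal(roc_pr_curves(s3, rep(1:2, 3),
                             c("pos", "neg"))$pos$roc_auc, 0.5)
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    sc <- round(stats::runif(n), 2)   # rounding forces ties
    lab <- sample(1:2, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    out <- roc_pr_curves(cbind(sc, 1 - sc), lab, c("pos", "neg"))
    expect_equal(out$pos$roc_auc, pair_auc(sc, lab == 1), tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  sc <- stats::runif(60)
  lab <- sample(1:2, 60, replace = TRUE)
  ours <- roc_pr_curves(cbind(sc, 1 - sc), lab, c("pos", "neg"))$pos$roc_auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab == 1, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("degenerate classes are skipped with a flag", {
  sc <- cbind(runif(4), runif(4), runif(4))
  out <- roc_pr_curves(sc, c(1, 1, 2, 2), c("a", "b", "c"))
  expect_true(out$c$skipped)
  expect_false(out$a$skipped)
})

test_that("the report bundles per-class rows, global metrics and curves", {
  set.seed(12)
  classes <- bilight_classes()
  truth <- sample(classes, 100, replace = TRUE)
  probs <- matrix(stats::runif(500), 100)
  probs <- probs / rowSums(probs)
  pred <- classes[max.col(probs)]
  rep <- metric_report(truth, pred, scores = probs, classes = classes)
  expect_s3_class(rep, "bilight_report")
  expect_equal(nrow(rep$per_class), 5)
  expect_equal(sum(rep$confusion), 100)
  d <- tempfile(); write_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("confusion.csv",
                                             "per_class.csv", "global.json",
                                             "curves.csv")))))
})
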