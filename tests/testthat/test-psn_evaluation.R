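# direct-formula oracle kept independent of psn_metrics
oracle_metrics <- function(tp, tn, fp, fn) {
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    f1 = if (tp > 0) 2 * tp / (2 * tp + fp + fn) else 0)
}

test_that("metrics follow the printed formulas including zero division", {
  m <- psn_metrics(confusion_counts(TP = 2, TN = 2, FP = 1, FN = 1))
  expect_equal(unname(m["accuracy"]), 4 / 6)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 2 / 3)
  expect_equal(unname(m["f1"]), 2 / 3)

  perfect <- psn_metrics(confusion_counts(TP = 3, TN = 4, FP = 0, FN = 0))
  expect_equal(unname(perfect["accuracy"]), 1.0)

  zd <- psn_metrics(confusion_counts(TP = 0, TN = 1, FP = 2, FN = 0))
  expect_equal(unname(zd["precision"]), 0)
  expect_equal(unname(zd["f1"]), 0)
  expect_true("f1" %in% attr(zd, "zero_division"))
})

test_that("metrics agree with the direct-formula oracle on random counts", {
  withr::with_seed(21, {
    for (rep in 1:200) {
      cts <- stats::rpois(4, lambda = sample(c(0.5, 3, 20), 1))
      if (sum(cts) == 0) cts[1] <- 1
      m <- psn_metrics(confusion_counts(cts[1], cts[2], cts[3], cts[4]))
      o <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
      expect_equal(as.numeric(m), as.numeric(o), tolerance = 1e-12)
    }
  })
})

test_that("pairwise confusion enumerates unordered pairs correctly", {
  # perfect block structure, threshold 0.5: no errors
  M <- block_matrix(c(3, 3))
  out <- factor(rep(c("a", "b"), each = 3))
  cc <- pairwise_confusion(M, out, cutoff_rule("threshold", 0.5))
  expect_equal(cc$FP + cc$FN, 0L)
  expect_equal(cc$TP, 6L)  # 2 * choose(3,2)
  expect_equal(cc$TN, 9L)

  # all-ones matrix, classes 2+2: every pair predicted similar
  M1 <- psn_matrix(matrix(1, 4, 4), ids = paste0("P", 1:4))
  out2 <- factor(c("x", "x", "y", "y"))
  cc2 <- pairwise_confusion(M1, out2, cutoff_rule("threshold", 0.5))
  expect_equal(cc2$TP, 2L)
  expect_equal(cc2$FP, 4L)
  expect_equal(cc2$FN, 0L)
  expect_equal(cc2$TN, 0L)

  # threshold above every off-diagonal entry: all pairs negative
  cc3 <- pairwise_confusion(block_matrix(c(2, 2)), out2,
                            cutoff_rule("threshold", 0.95))
  expect_equal(cc3$TP + cc3$FP, 0L)
  expect_equal(cc3$FN + cc3$TN, 6L)
})

test_that("top-K rule symmetrizes by OR", {
  M <- psn_matrix(rbind(c(1, 0.9, 0.1),
                        c(0.9, 1, 0.5),
                        c(0.1, 0.5, 1)), ids = paste0("P", 1:3))
  out <- factor(c("a", "a", "b"))
  cc <- pairwise_confusion(M, out, cutoff_rule("topk", 1))
  # P1 lists P2; P2 lists P1; P3 lists P2 -> pairs (1,2) and (2,3) predicted
  expect_equal(cc$TP, 1L)
  expect_equal(cc$FP, 1L)
  expect_equal(cc$TN, 1L)
})

test_that("single-class outcomes trigger a warning but still count", {
  M <- block_matrix(c(2, 2))
  expect_warning(cc <- pairwise_confusion(M, rep("a", 4),
                                          cutoff_rule("threshold", 0.5)),
                 "single outcome class")
  expect_equal(cc$TP + cc$FN, 6L)
})

test_that("patient KNN prediction votes among most similar training
           patients", {
  M <- psn_matrix(rbind(c(1, 1, 0, 0),
                        c(1, 1, 0, 0),
                        c(0, 0, 1, 0.2),
                        c(0, 0, 0.2, 1)), ids = paste0("P", 1:4))
  out <- factor(c("a", "b", "b", "b"))
  # test patient 1 identical to training patient 2 -> inherits label b
  pred <- patient_knn_predict(M, out, train_idx = 2:4, test_idx = 1, K = 1)
  expect_equal(as.character(pred), "b")
  # K = |train| -> global majority
  pred_all <- patient_knn_predict(M, out, train_idx = 2:4, test_idx = 1,
                                  K = 3)
  expect_equal(as.character(pred_all), "b")
  expect_error(patient_knn_predict(M, out, integer(0), 1, K = 1), "empty")
  expect_error(patient_knn_predict(M, out, 1:2, 2:3, K = 1), "overlap")
})

test_that("planted two-cluster structure is recovered by KNN voting", {
  withr::with_seed(31, {
    M <- block_matrix(c(30, 30), within = 0.8, between = 0.3)
    noise <- matrix(stats::runif(60 * 60, 0, 0.1), 60, 60)
    noise <- (noise + t(noise)) / 2
    Mn <- psn_matrix(pmax(unclass(M) + noise - 0.05, 0),
                     ids = rownames(M))
    out <- factor(rep(c("a", "b"), each = 30))
    cv <- crossvalidate(Mn, out, eval_protocol("patient_knn", K = 5,
                                               seed = 17))
    expect_gt(cv$mean["accuracy"], 0.9)
  })
})

test_that("cross-validation is stratified, deterministic, and permutation
           invariant", {
  M <- block_matrix(c(20, 20), within = 0.9, between = 0.2)
  out <- factor(rep(c("a", "b"), each = 20))
  proto <- eval_protocol("patient_knn", K = 3, folds = 5, seed = 9)
  cv1 <- crossvalidate(M, out, proto)
  cv2 <- crossvalidate(M, out, proto)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$folds, cv2$folds)
  # each fold holds 4 from each class
  tab <- table(cv1$folds, out)
  expect_true(all(tab == 4))
  # perfectly separable: every fold perfect
  expect_equal(unname(cv1$mean["accuracy"]), 1.0)
  expect_equal(unname(cv1$sd["accuracy"]), 0.0)

  # permute patients and labels together: same mean accuracy
  perm <- withr::with_seed(3, sample(40))
  Mp <- psn_matrix(unclass(M)[perm, perm], ids = rownames(M)[perm])
  cvp <- crossvalidate(Mp, out[perm], proto)
  expect_equal(cvp$mean["accuracy"], cv1$mean["accuracy"])
})

test_that("label shuffling drives accuracy to chance", {
  M <- rand_similarity(60, seed = 41)
  withr::with_seed(42, {
    accs <- vapply(1:10, function(i) {
      out <- factor(sample(rep(c("a", "b"), each = 30)))
      cv <- crossvalidate(M, out, eval_protocol("patient_knn", K = 5,
                                                folds = 5, seed = i))
      unname(cv$mean["accuracy"])
    }, numeric(1))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("rare classes fall back to unstratified folds with a warning", {
  M <- block_matrix(c(8, 2))
  out <- factor(c(rep("a", 8), "b", "b"))
  expect_warning(crossvalidate(M, out,
                               eval_protocol("patient_knn", K = 1,
                                             folds = 5, seed = 1)),
                 "unstratified")
})

test_that("neighbor fraction sweep reports one accuracy per p", {
  M <- block_matrix(c(15, 15), within = 0.9, between = 0.1)
  out <- factor(rep(c("a", "b"), each = 15))
  sweep_tab <- neighbor_fraction_sweep(M, out, p_values = c(5, 50, 100),
                                       folds = 5, seed = 2)
  expect_equal(sweep_tab$p_percent, c(5, 50, 100))
  expect_true(all(sweep_tab$accuracy >= 0 & sweep_tab$accuracy <= 1))
  # separable cohort: small-p accuracy at least matches full-data voting
  expect_gte(sweep_tab$accuracy[1], sweep_tab$accuracy[3])
})
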