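#' Similarity cutoff rules
#'
#' Rule deciding which pairs a similarity matrix "predicts similar":
#' `threshold` (global cutoff on the score), `topk` (j is among i's K most
#' similar, symmetrized by OR), or `top_p` (top p percent of each patient's
#' neighbors).
#'
#' @param type `"threshold"`, `"topk"`, or `"top_p"`.
#' @param value cutoff value: the threshold, K, or p (percent).
#' @return Object of class `cutoff_rule`.
#' @export
cutoff_rule <- function(type = c("threshold", "topk", "top_p"), value) {
  type <- match.arg(type)
  stopifnot(is.numeric(value), length(value) == 1)
  structure(list(type = type, value = value), class = "cutoff_rule")
}

#' Pairwise confusion counts of a similarity matrix
#'
#' Over all unordered patient pairs (i < j): a pair is predicted similar iff
#' the cutoff rule fires; the truth is exact outcome-label equality. Counts:
#' TP = predicted similar, same outcome; FP = predicted similar, different
#' outcomes; FN = predicted dissimilar, same outcome; TN = predicted
#' dissimilar, different outcomes.
#'
#' @param M symmetric similarity [psn_matrix()].
#' @param outcomes per-patient class labels (2+ classes expected; a single
#'   class triggers a warning since no negative pairs exist).
#' @param rule a [cutoff_rule()].
#' @return Object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`, `n_pairs`.
#' @export
pairwise_confusion <- function(M, outcomes, rule) {
  n <- nrow(M)
  outcomes <- as.factor(outcomes)
  if (length(outcomes) != n) {
    stop("outcomes must be defined for every patient", call. = FALSE)
  }
  if (nlevels(droplevels(outcomes)) < 2) {
    warning("single outcome class: no dissimilar pairs exist", call. = FALSE)
  }
  pred <- predicted_similar(M, rule)
  ut <- upper.tri(M)
  p <- pred[ut]
  same <- outer(as.character(outcomes), as.character(outcomes), "==")[ut]
  counts <- list(TP = sum(p & same), FP = sum(p & !same),
                 FN = sum(!p & same), TN = sum(!p & !same))
  counts <- lapply(counts, as.integer)
  counts$n_pairs <- as.integer(n * (n - 1) / 2)
  structure(counts, class = "confusion_counts")
}

predicted_similar <- function(M, rule) {
  n <- nrow(M)
  raw <- unclass_psn_safe(M)
  if (rule$type == "threshold") {
    pred <- raw >= rule$value
  } else {
    K <- if (rule$type == "topk") rule$value
         else max(1, ceiling(rule$value / 100 * (n - 1)))
    K <- min(as.integer(K), n - 1)
    nb <- top_k_neighbors(raw, K)
    pred <- matrix(FALSE, n, n)
    for (i in seq_len(n)) pred[i, nb[[i]]] <- TRUE
    pred <- pred | t(pred)  # OR symmetrization
  }
  diag(pred) <- FALSE
  pred
}

#' Construct confusion counts directly
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @return `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), TN = as.integer(TN),
                 n_pairs = as.integer(TP + TN + FP + FN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion_counts: TP", x$TP, "FP", x$FP, "FN", x$FN, "TN", x$TN, "\n")
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, and F1 `2*recall*precision/(recall+precision)`. Any metric
#' whose denominator is zero is returned as 0 and named in the
#' `"zero_division"` attribute.
#'
#' @param counts a `confusion_counts` object.
#' @return named numeric vector `accuracy`, `recall`, `precision`, `f1` with
#'   a `zero_division` attribute listing flagged metrics.
#' @export
psn_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated pairs", call. = FALSE)
  flagged <- character(0)
  acc <- (tp + tn) / total
  if (tp + fn == 0) { rec <- 0; flagged <- c(flagged, "recall") }
  else rec <- tp / (tp + fn)
  if (tp + fp == 0) { prec <- 0; flagged <- c(flagged, "precision") }
  else prec <- tp / (tp + fp)
  if (rec + prec == 0) { f1 <- 0; flagged <- c(flagged, "f1") }
  else f1 <- 2 * rec * prec / (rec + prec)
  structure(c(accuracy = acc, recall = rec, precision = prec, f1 = f1),
            zero_division = flagged)
}

#' Patient-level KNN outcome prediction
#'
#' Predicts each test patient's outcome as the majority vote among its K
#' most-similar training patients. `p_percent` converts to
#' `K = ceiling(p/100 * n_train)`. Vote ties are broken toward the most
#' frequent class in the training fold, then the lower class index.
#'
#' @param M similarity [psn_matrix()] over all patients.
#' @param outcomes per-patient labels.
#' @param train_idx,test_idx disjoint integer index vectors.
#' @param K neighbor count (`K <= |train|`), or give `p_percent`.
#' @param p_percent percentage of the training fold to use as neighbors.
#' @return factor of predicted labels for `test_idx` (levels of `outcomes`).
#' @export
patient_knn_predict <- function(M, outcomes, train_idx, test_idx,
                                K = NULL, p_percent = NULL) {
  outcomes <- as.factor(outcomes)
  if (length(intersect(train_idx, test_idx))) {
    stop("train and test indices overlap", call. = FALSE)
  }
  if (length(train_idx) == 0) stop("empty training fold", call. = FALSE)
  if (is.null(K)) {
    if (is.null(p_percent)) stop("give K or p_percent", call. = FALSE)
    K <- ceiling(p_percent / 100 * length(train_idx))
  }
  K <- max(1L, min(as.integer(K), length(train_idx)))
  raw <- unclass_psn_safe(M)
  train_lab <- outcomes[train_idx]
  # tie-break fallback order: most frequent training class, then level order
  fallback <- order(-tabulate(train_lab, nlevels(outcomes)),
                    seq_len(nlevels(outcomes)))
  pred <- integer(length(test_idx))
  for (ti in seq_along(test_idx)) {
    i <- test_idx[ti]
    sims <- raw[i, train_idx]
    nb <- order(-sims, seq_along(sims))[seq_len(K)]
    votes <- tabulate(train_lab[nb], nlevels(outcomes))
    top <- which(votes == max(votes))
    if (length(top) > 1) top <- top[order(match(top, fallback))][1]
    pred[ti] <- top
  }
  factor(levels(outcomes)[pred], levels = levels(outcomes))
}

#' Evaluation protocol
#'
#' @param mode `"patient_knn"` (per-patient majority-vote prediction) or
#'   `"pairwise"` (pair-level confusion counts of test-vs-train pairs).
#' @param rule a [cutoff_rule()] (pairwise mode).
#' @param K,p_percent neighborhood size (patient_knn mode); exactly one.
#' @param folds cross-validation folds (default 5).
#' @param seed fold-assignment seed.
#' @return Object of class `eval_protocol`.
#' @export
eval_protocol <- function(mode = c("patient_knn", "pairwise"), rule = NULL,
                          K = NULL, p_percent = NULL, folds = 5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(folds >= 2)
  if (mode == "patient_knn" && is.null(K) && is.null(p_percent)) {
    stop("patient_knn mode needs K or p_percent", call. = FALSE)
  }
  if (mode == "pairwise" && is.null(rule)) {
    stop("pairwise mode needs a cutoff rule", call. = FALSE)
  }
  structure(list(mode = mode, rule = rule, K = K, p_percent = p_percent,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "eval_protocol")
}

# stratified fold assignment; falls back to unstratified when a class has
# fewer members than folds
make_folds <- function(outcomes, folds, seed) {
  outcomes <- as.factor(outcomes)
  n <- length(outcomes)
  withr::with_seed(seed, {
    if (min(table(outcomes)) < folds) {
      warning("a class has fewer members than folds; ",
              "falling back to unstratified folds", call. = FALSE)
      return(sample(rep_len(seq_len(folds), n)))
    }
    fold <- integer(n)
    for (lv in levels(outcomes)) {
      idx <- which(outcomes == lv)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

#' Cross-validated evaluation of a similarity matrix
#'
#' Splits patients into stratified folds and evaluates each fold against the
#' remaining patients, either by patient-level KNN prediction or pairwise
#' confusion counts. Deterministic under the protocol seed.
#'
#' @param M similarity [psn_matrix()].
#' @param outcomes per-patient labels.
#' @param protocol an [eval_protocol()].
#' @return list with `per_fold` (data.frame fold x metric), `mean`, `sd`
#'   (named numeric vectors over folds), and `folds` (the fold assignment).
#' @export
crossvalidate <- function(M, outcomes, protocol) {
  outcomes <- as.factor(outcomes)
  n <- nrow(M)
  if (n < protocol$folds) stop("fewer patients than folds", call. = FALSE)
  fold <- make_folds(outcomes, protocol$folds, protocol$seed)
  rows <- vector("list", protocol$folds)
  for (f in seq_len(protocol$folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (protocol$mode == "patient_knn") {
      pred <- patient_knn_predict(M, outcomes, train_idx, test_idx,
                                  K = protocol$K,
                                  p_percent = protocol$p_percent)
      truth <- outcomes[test_idx]
      m <- label_metrics(pred, truth)
    } else {
      cc <- pairwise_confusion_split(M, outcomes, train_idx, test_idx,
                                     protocol$rule)
      m <- psn_metrics(cc)
    }
    rows[[f]] <- data.frame(fold = f, t(as.numeric(m)))
    names(rows[[f]])[-1] <- names(m)
  }
  per_fold <- do.call(rbind, rows)
  metrics <- per_fold[, -1, drop = FALSE]
  list(per_fold = per_fold,
       mean = colMeans(metrics),
       sd = apply(metrics, 2, stats::sd),
       folds = fold)
}

# patient-level metrics; binary positive class = second factor level,
# multi-class precision/recall/F1 are macro-averaged
label_metrics <- function(pred, truth) {
  acc <- mean(pred == truth)
  lv <- levels(truth)
  per_class <- vapply(lv, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }, numeric(3))
  if (length(lv) == 2) {
    c(accuracy = acc, recall = per_class[2, 2],
      precision = per_class[1, 2], f1 = per_class[3, 2])
  } else {
    c(accuracy = acc, recall = mean(per_class[2, ]),
      precision = mean(per_class[1, ]), f1 = mean(per_class[3, ]))
  }
}

# confusion over test-vs-train pairs only
pairwise_confusion_split <- function(M, outcomes, train_idx, test_idx, rule) {
  pred <- predicted_similar(M, rule)
  same <- outer(as.character(outcomes), as.character(outcomes), "==")
  p <- pred[test_idx, train_idx]
  s <- same[test_idx, train_idx]
  confusion_counts(TP = sum(p & s), FP = sum(p & !s),
                   FN = sum(!p & s), TN = sum(!p & !s))
}

#' Accuracy across a sweep of neighbor fractions
#'
#' Cross-validated patient-KNN accuracy as the voting neighborhood shrinks
#' from the full training fold (p = 100) toward only the most similar few
#' percent, mirroring the top-p%-similar training strategy.
#'
#' @param M similarity [psn_matrix()].
#' @param outcomes labels.
#' @param p_values percentages to evaluate.
#' @param folds,seed protocol parameters.
#' @return data.frame with `p_percent` and mean CV `accuracy`.
#' @export
neighbor_fraction_sweep <- function(M, outcomes,
                                    p_values = c(5, 10, 25, 50, 100),
                                    folds = 5, seed = 1) {
  rows <- lapply(p_values, function(p) {
    cv <- crossvalidate(M, outcomes,
                        eval_protocol("patient_knn", p_percent = p,
                                      folds = folds, seed = seed))
    data.frame(p_percent = p, accuracy = unname(cv$mean["accuracy"]))
  })
  do.call(rbind, rows)
}
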