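#' Per-feature similarity rules and weights
#'
#' A feature spec names a cohort column, the similarity rule applied to it,
#' and its nonnegative weight in the global static similarity score. Rules:
#' \describe{
#'   \item{`age_ratio`}{ratio of the smaller to the larger value, 1 when
#'     equal (including both zero).}
#'   \item{`exact_match`}{1 if equal, 0 otherwise (categorical/boolean).}
#'   \item{`text_onehot`}{cosine similarity of multi-hot token encodings.}
#'   \item{`numeric_passthrough`}{numeric column used verbatim; in weighted
#'     scoring it contributes `1 - |x_i - x_j| / range` and in feature-vector
#'     mode the raw value enters the patient vector.}
#' }
#'
#' @param name cohort column name.
#' @param kind one of `"age_ratio"`, `"exact_match"`, `"text_onehot"`,
#'   `"numeric_passthrough"`.
#' @param weight nonnegative weight.
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("age_ratio", "exact_match",
                                        "text_onehot",
                                        "numeric_passthrough"),
                         weight = 1) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, weight >= 0)
  structure(list(name = name, kind = kind, weight = as.numeric(weight)),
            class = "feature_spec")
}

#' Normalize feature-spec weights to sum to one
#'
#' The global static similarity score requires weights summing to 1; sets of
#' raw prioritization weights (which need not) are renormalized here.
#'
#' @param specs list of [feature_spec()] objects.
#' @return the list with weights rescaled so they sum to 1.
#' @export
normalize_weights <- function(specs) {
  w <- vapply(specs, function(s) s$weight, numeric(1))
  total <- sum(w)
  if (total <= 0) stop("weights sum to zero", call. = FALSE)
  lapply(specs, function(s) { s$weight <- s$weight / total; s })
}

#' Age similarity: smaller-to-larger ratio
#'
#' @param age_i,age_j nonnegative ages (years). Vectorized.
#' @return score in \[0, 1\]; 1 when the ages are equal (including both 0),
#'   0 when exactly one is 0.
#' @export
age_similarity <- function(age_i, age_j) {
  if (any(age_i < 0, na.rm = TRUE) || any(age_j < 0, na.rm = TRUE)) {
    stop("ages must be nonnegative", call. = FALSE)
  }
  hi <- pmax(age_i, age_j)
  lo <- pmin(age_i, age_j)
  ifelse(hi == 0, 1, lo / hi)
}

#' Exact-match similarity for categorical/boolean features
#'
#' @param v_i,v_j values of the same feature for two patients. Vectorized.
#' @return 1 where equal, 0 otherwise; `NA` inputs score 0 (a missing flag is
#'   treated as a non-match).
#' @export
match_similarity <- function(v_i, v_j) {
  s <- as.numeric(v_i == v_j)
  s[is.na(s)] <- 0
  s
}

#' Weighted sum of per-feature scores
#'
#' The dot product of a score vector with a weight vector. With weights
#' summing to 1 and scores in \[0, 1\] this is the global static patient
#' similarity; with integer priority scores it is the weighted-scoring
#' prioritization used to rank candidate feature weightings.
#'
#' @param feature_scores numeric vector.
#' @param weights numeric vector of the same length.
#' @return scalar weighted score.
#' @export
weighted_score <- function(feature_scores, weights) {
  if (length(feature_scores) != length(weights)) {
    stop("feature_scores and weights must have equal length", call. = FALSE)
  }
  sum(feature_scores * weights)
}

#' Rank option score vectors by weighted score
#'
#' @param score_matrix numeric matrix: one row per option, one column per
#'   feature.
#' @param weights per-feature weights.
#' @return data.frame with `option`, `score`, `rank` (descending score, ties
#'   broken by option order).
#' @export
weighted_score_table <- function(score_matrix, weights) {
  score_matrix <- as.matrix(score_matrix)
  scores <- apply(score_matrix, 1, weighted_score, weights = weights)
  ord <- order(-scores, seq_along(scores))
  rank <- integer(length(scores))
  rank[ord] <- seq_along(scores)
  data.frame(option = rownames(score_matrix) %||%
               paste0("Option", seq_along(scores)),
             score = scores, rank = rank, row.names = NULL)
}

# per-feature score column for all unordered pairs, given a spec
feature_pair_scores <- function(cohort, spec, pair_i, pair_j,
                                encoders = list()) {
  v <- cohort$data[[spec$name]]
  if (is.null(v)) {
    stop("feature '", spec$name, "' not found in cohort", call. = FALSE)
  }
  switch(spec$kind,
    age_ratio = {
      v <- impute_mean(as.numeric(v))
      age_similarity(v[pair_i], v[pair_j])
    },
    exact_match = match_similarity(v[pair_i], v[pair_j]),
    numeric_passthrough = {
      v <- impute_mean(as.numeric(v))
      rng <- diff(range(v))
      if (rng == 0) rep(1, length(pair_i))
      else 1 - abs(v[pair_i] - v[pair_j]) / rng
    },
    text_onehot = {
      enc <- encoders[[spec$name]]
      if (is.null(enc)) enc <- fit_vocabulary(as.character(v))
      E <- t(vapply(as.character(v), encode_text, numeric_encoding_len(enc),
                    encoder = enc))
      cosine_pair(E, pair_i, pair_j)
    },
    stop("unhandled feature kind: ", spec$kind, call. = FALSE)
  )
}

numeric_encoding_len <- function(enc) {
  if (inherits(enc, "psn_vocabulary")) numeric(length(enc$tokens))
  else numeric(enc$dim)
}

cosine_pair <- function(E, pair_i, pair_j) {
  nrm <- sqrt(rowSums(E^2))
  dots <- rowSums(E[pair_i, , drop = FALSE] * E[pair_j, , drop = FALSE])
  denom <- nrm[pair_i] * nrm[pair_j]
  s <- ifelse(denom == 0,
              ifelse(nrm[pair_i] == 0 & nrm[pair_j] == 0, 1, 0),
              dots / denom)
  # one-hot cosine is already >= 0; signed embeddings are mapped into [0,1]
  if (any(s < 0)) s <- (1 + s) / 2
  s
}

impute_mean <- function(v) {
  if (anyNA(v)) {
    mu <- mean(v, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    v[is.na(v)] <- mu
  }
  v
}

#' Static patient similarity matrix
#'
#' Builds the N x N static similarity matrix over the specified features.
#' Two construction modes:
#' \describe{
#'   \item{`"stps"`}{the weighted sum of per-feature similarity scores
#'     (weights renormalized to sum to 1); symmetric with unit diagonal.}
#'   \item{`"distance"`}{patients are embedded as numeric feature vectors
#'     (text fields via their encoder, categorical via 0/1, numeric z-scored)
#'     and compared under a geometric distance measure, then converted to
#'     similarity via [distance_to_similarity()].}
#' }
#'
#' @param cohort a [static_cohort()].
#' @param specs list of [feature_spec()]s.
#' @param method `"stps"` or `"distance"`.
#' @param metric a [distance_metric()] (distance mode only).
#' @param encoders optional named list of fitted text encoders, keyed by
#'   feature name; unfitted text features get a vocabulary fitted on the
#'   cohort column.
#' @param conversion distance-to-similarity conversion, see
#'   [distance_to_similarity()].
#' @return A similarity-tagged [psn_matrix()].
#' @export
static_similarity_matrix <- function(cohort, specs,
                                     method = c("stps", "distance"),
                                     metric = distance_metric("euclidean"),
                                     encoders = list(),
                                     conversion = c("inverse", "gaussian")) {
  method <- match.arg(method)
  conversion <- match.arg(conversion)
  if (length(specs) == 0) stop("empty feature spec list", call. = FALSE)
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  n <- n_patients(cohort)
  ids <- cohort$patient_ids

  if (method == "stps") {
    specs <- normalize_weights(specs)
    if (n == 1) return(psn_matrix(matrix(1, 1, 1), ids, "similarity"))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    total <- numeric(nrow(pairs))
    for (sp in specs) {
      total <- total +
        sp$weight * feature_pair_scores(cohort, sp, pairs[, 1], pairs[, 2],
                                        encoders)
    }
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- total
    M <- M + t(M)
    diag(M) <- 1
    psn_matrix(M, ids, "similarity")
  } else {
    X <- static_feature_matrix(cohort, specs, encoders)
    D <- pairwise_distance_matrix(X, metric)
    distance_to_similarity(psn_matrix(D, ids, "distance"),
                           conversion = conversion)
  }
}

#' Numeric feature-vector embedding of a static cohort
#'
#' Stacks the specified features into one numeric matrix (one row per
#' patient): numeric columns are z-scored (constant columns dropped to 0),
#' categorical/boolean columns become exact-match indicators via one-hot
#' levels, text columns expand into their encoder's vector.
#'
#' @inheritParams static_similarity_matrix
#' @return numeric matrix, rows named by patient id. Column blocks carry a
#'   `"block"` attribute mapping columns to feature names (used by the
#'   weighted Manhattan metric to expand per-feature weights).
#' @export
static_feature_matrix <- function(cohort, specs, encoders = list()) {
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  blocks <- list()
  for (sp in specs) {
    v <- cohort$data[[sp$name]]
    if (is.null(v)) stop("feature '", sp$name, "' not found", call. = FALSE)
    b <- switch(sp$kind,
      age_ratio = ,
      numeric_passthrough = {
        x <- impute_mean(as.numeric(v))
        s <- stats::sd(x)
        matrix(if (s > 0) (x - mean(x)) / s else 0, ncol = 1,
               dimnames = list(NULL, sp$name))
      },
      exact_match = {
        f <- factor(v)
        m <- stats::model.matrix(~ f - 1)
        colnames(m) <- paste0(sp$name, "=", levels(f))
        m
      },
      text_onehot = {
        enc <- encoders[[sp$name]]
        if (is.null(enc)) enc <- fit_vocabulary(as.character(v))
        E <- t(vapply(as.character(v), encode_text,
                      numeric_encoding_len(enc), encoder = enc))
        colnames(E) <- paste0(sp$name, "_", seq_len(ncol(E)))
        E
      }
    )
    blocks[[sp$name]] <- b
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- cohort$patient_ids
  attr(X, "block") <- rep(vapply(specs, function(s) s$name, character(1)),
                          vapply(blocks, ncol, integer(1)))
  X
}

#' Geometric distance measures
#'
#' @param name one of `"euclidean"`, `"manhattan"`, `"cosine"`,
#'   `"chebyshev"`, `"weighted_manhattan"`.
#' @param weights per-dimension (or per-feature-block) weights; required for
#'   `weighted_manhattan`, ignored otherwise.
#' @return Object of class `distance_metric`.
#' @export
distance_metric <- function(name = c("euclidean", "manhattan", "cosine",
                                     "chebyshev", "weighted_manhattan"),
                            weights = NULL) {
  name <- match.arg(name)
  if (name == "weighted_manhattan" && is.null(weights)) {
    stop("weighted_manhattan requires a weight vector", call. = FALSE)
  }
  structure(list(name = name, weights = weights), class = "distance_metric")
}

#' Pairwise distance between two numeric vectors
#'
#' Cosine distance is `1 - cosine similarity`; two all-zero vectors are
#' defined as identical (distance 0) with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @param metric a [distance_metric()].
#' @return nonnegative scalar distance.
#' @export
pairwise_distance <- function(x, y, metric = distance_metric("euclidean")) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  switch(metric$name,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    chebyshev = max(abs(x - y)),
    weighted_manhattan = {
      w <- metric$weights
      if (length(w) != length(x)) {
        stop("weighted_manhattan weight vector length ", length(w),
             " does not match vector length ", length(x), call. = FALSE)
      }
      sum(w * abs(x - y))
    },
    cosine = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 && ny == 0) {
        warning("cosine distance of two all-zero vectors defined as 0",
                call. = FALSE)
        return(0)
      }
      if (nx == 0 || ny == 0) return(1)
      max(0, 1 - sum(x * y) / (nx * ny))
    }
  )
}

#' Pairwise distance matrix over the rows of a feature matrix
#'
#' @param X numeric matrix, one row per patient. For `weighted_manhattan`,
#'   metric weights may be given per feature block (named, matching the
#'   `"block"` attribute of [static_feature_matrix()]) or per column.
#' @param metric a [distance_metric()].
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(X,
                                     metric = distance_metric("euclidean")) {
  X <- as.matrix(X)
  n <- nrow(X)
  w <- metric$weights
  if (metric$name == "weighted_manhattan" && !is.null(names(w))) {
    block <- attr(X, "block")
    if (is.null(block)) {
      stop("named metric weights need a feature matrix with a block attribute",
           call. = FALSE)
    }
    miss <- setdiff(unique(block), names(w))
    if (length(miss)) {
      stop("no metric weight for feature(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    w <- unname(w[block])
    metric <- distance_metric("weighted_manhattan", weights = w)
  }
  D <- switch(metric$name,
    euclidean = as.matrix(stats::dist(X, method = "euclidean")),
    manhattan = as.matrix(stats::dist(X, method = "manhattan")),
    chebyshev = as.matrix(stats::dist(X, method = "maximum")),
    # stats::dist has no weighted form; scaling columns by w gives
    # sum_d w_d |x_d - y_d| under the manhattan method
    weighted_manhattan = {
      if (length(w) != ncol(X)) {
        stop("weighted_manhattan weight vector length ", length(w),
             " does not match feature dimension ", ncol(X), call. = FALSE)
      }
      as.matrix(stats::dist(X %*% diag(w, ncol(X)), method = "manhattan"))
    },
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      zero <- nrm == 0
      if (any(zero) && sum(zero) > 1) {
        warning("cosine distance of all-zero vectors defined as 0",
                call. = FALSE)
      }
      nrm[zero] <- 1
      C <- tcrossprod(X / nrm)
      C[zero, ] <- 0; C[, zero] <- 0
      C[zero, zero] <- 1
      D <- 1 - C
      D[D < 0] <- 0
      diag(D) <- 0
      D
    }
  )
  D <- (D + t(D)) / 2  # guard against asymmetric floating-point residue
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Convert a distance matrix to a similarity matrix
#'
#' Two bounded, monotone-decreasing conversions:
#' \describe{
#'   \item{`"inverse"`}{`s = 1 / (1 + d)` — parameter-free, diagonal 1.}
#'   \item{`"gaussian"`}{`s = exp(-d^2 / sigma^2)` with `sigma` the median
#'     off-diagonal distance — the kernel form usual in similarity-network
#'     fusion.}
#' }
#'
#' @param D a distance-tagged [psn_matrix()] (or plain nonnegative matrix).
#' @param conversion `"inverse"` or `"gaussian"`.
#' @return similarity-tagged [psn_matrix()] with unit diagonal.
#' @export
distance_to_similarity <- function(D, conversion = c("inverse", "gaussian")) {
  conversion <- match.arg(conversion)
  if (any(D < 0)) stop("distances must be nonnegative", call. = FALSE)
  S <- if (conversion == "inverse") {
    1 / (1 + unclass_psn(D))
  } else {
    off <- unclass_psn(D)[upper.tri(D)]
    sigma <- stats::median(off)
    if (sigma <= 0) sigma <- 1
    exp(-(unclass_psn(D)^2) / sigma^2)
  }
  diag(S) <- 1
  psn_matrix(S, rownames(D) %||% NULL, "similarity")
}
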