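#' Fusion configuration
#'
#' Parameters of the pairwise weighted-average similarity network fusion.
#'
#' @param K nearest-neighbor count for local-similarity sparsification
#'   (`1 <= K < N`). Alternatively give `p_percent` and K is derived as
#'   `ceiling(p/100 * (N-1))` at fuse time.
#' @param T_iter number of fusion iterations (default 20).
#' @param wts,wtd weights in \[0,1\] expressing the relative significance of
#'   the static and dynamic matrices in the recursion.
#' @param neighbor_source `"self"`: each matrix ranks neighbors by its own
#'   rows; `"union"`: the neighbor set is the union of both matrices' top-K.
#' @param mode `"fixed"` runs exactly `T_iter` iterations; `"converge"` stops
#'   early when the largest elementwise change drops below `tol`.
#' @param tol convergence tolerance (converge mode).
#' @param init state initialization: `"normalized"` (normalized + symmetrized,
#'   pre-sparsification; default), `"localized"`, or `"raw"`.
#' @param p_percent optional percentage of patients to use as K.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(K = NULL, T_iter = 20, wts = 0.5, wtd = 0.5,
                          neighbor_source = c("self", "union"),
                          mode = c("fixed", "converge"), tol = 1e-9,
                          init = c("normalized", "localized", "raw"),
                          p_percent = NULL) {
  neighbor_source <- match.arg(neighbor_source)
  mode <- match.arg(mode)
  init <- match.arg(init)
  if (is.null(K) && is.null(p_percent)) {
    stop("give K or p_percent", call. = FALSE)
  }
  stopifnot(T_iter >= 1, wts >= 0, wts <= 1, wtd >= 0, wtd <= 1)
  structure(list(K = K, T_iter = as.integer(T_iter), wts = wts, wtd = wtd,
                 neighbor_source = neighbor_source, mode = mode, tol = tol,
                 init = init, p_percent = p_percent),
            class = "fusion_config")
}

resolve_K <- function(cfg, n) {
  K <- cfg$K %||% ceiling(cfg$p_percent / 100 * (n - 1))
  K <- as.integer(K)
  if (K < 1 || K >= n) {
    stop("K must satisfy 1 <= K < N; got K=", K, ", N=", n, call. = FALSE)
  }
  K
}

#' Row-stochastic normalization
#'
#' Divides each row by its sum so every row sums to 1. All-zero rows become
#' uniform rows (with a warning) so downstream iterations stay finite.
#'
#' @param M nonnegative square matrix.
#' @return matrix of the same shape with unit row sums.
#' @export
row_normalize <- function(M) {
  if (any(M < 0)) stop("negative entries; expected a similarity matrix",
                       call. = FALSE)
  rs <- rowSums(M)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) replaced by uniform rows",
            call. = FALSE)
    M[zero, ] <- 1 / ncol(M)
    rs[zero] <- 1
  }
  out <- M / rs
  restore_psn(out, M)
}

restore_psn <- function(out, template) {
  dimnames(out) <- dimnames(template)
  if (inherits(template, "psn_matrix")) {
    attr(out, "psn_type") <- psn_type(template)
    class(out) <- c("psn_matrix", class(out))
  }
  out
}

#' Symmetrize a matrix
#'
#' `(W + t(W)) / 2`; exactly symmetric and idempotent.
#'
#' @param M square matrix.
#' @return symmetric matrix.
#' @export
symmetrize <- function(M) {
  if (nrow(M) != ncol(M)) stop("matrix must be square", call. = FALSE)
  restore_psn((unclass_psn_safe(M) + t(unclass_psn_safe(M))) / 2, M)
}

unclass_psn_safe <- function(m) {
  if (inherits(m, "psn_matrix")) unclass_psn(m) else m
}

#' K-nearest-neighbor local similarity
#'
#' Keeps, in each row, only that patient's K strongest links (diagonal
#' excluded from candidacy) and divides the kept weights by their sum, so the
#' kept entries of each row sum to 1; everything else becomes 0. Ties at the
#' K-th neighbor are broken toward the lower patient index. The output is in
#' general asymmetric; no re-symmetrization is applied here.
#'
#' @param M symmetric nonnegative similarity matrix.
#' @param K neighbors to keep per row, `1 <= K < N`.
#' @param neighbor_idx optional list of per-row neighbor index vectors
#'   overriding the row's own ranking (used for union-of-matrices neighbor
#'   sets); kept entries are still renormalized by their sum.
#' @return localized matrix (zero diagonal).
#' @export
knn_localize <- function(M, K, neighbor_idx = NULL) {
  n <- nrow(M)
  if (is.null(neighbor_idx)) {
    if (K < 1 || K >= n) {
      stop("K must satisfy 1 <= K < N; got K=", K, ", N=", n, call. = FALSE)
    }
    neighbor_idx <- top_k_neighbors(M, K)
  }
  out <- matrix(0, n, n)
  raw <- unclass_psn_safe(M)
  for (i in seq_len(n)) {
    nb <- neighbor_idx[[i]]
    w <- raw[i, nb]
    s <- sum(w)
    out[i, nb] <- if (s > 0) w / s else 1 / length(nb)
  }
  restore_psn(out, M)
}

# per-row top-K off-diagonal indices, ties toward the lower index
top_k_neighbors <- function(M, K) {
  n <- nrow(M)
  raw <- unclass_psn_safe(M)
  lapply(seq_len(n), function(i) {
    w <- raw[i, ]
    w[i] <- -Inf
    order(-w, seq_len(n))[seq_len(K)]
  })
}

#' Pairwise weighted-average similarity network fusion
#'
#' Fuses a static and a dynamic similarity matrix into one network. The
#' pipeline: row-normalize and symmetrize both inputs; sparsify each with
#' [knn_localize()] to suppress weak links; then iterate the coupled
#' recursion
#' \deqn{MP^1_{t+1} = (wts \cdot S' + (1 - wts) MP^2_t)/2}
#' \deqn{MP^2_{t+1} = (wtd \cdot D' + (1 - wtd) MP^1_t)/2}
#' where \eqn{S', D'} are the localized matrices, and finally average:
#' \eqn{FM = (MP^1_T + MP^2_T)/2}, symmetrized. The recursion is linear and
#' contracts toward a unique fixed point (see [snf_fixed_point()]), so FM is
#' interpreted ordinally (as a ranking of pairs), not as a calibrated
#' similarity.
#'
#' @param S,D similarity-tagged [psn_matrix()] objects on the same patients.
#' @param cfg a [fusion_config()].
#' @return fused similarity [psn_matrix()] with attributes `iterations`
#'   (iterations actually run) and `converged`.
#' @export
snf_fuse <- function(S, D, cfg) {
  if (!all(dim(S) == dim(D))) stop("shape mismatch", call. = FALSE)
  if (!is.null(rownames(S)) && !is.null(rownames(D)) &&
      !identical(rownames(S), rownames(D))) {
    stop("patient index mismatch between S and D", call. = FALSE)
  }
  n <- nrow(S)
  K <- resolve_K(cfg, n)

  Sn <- symmetrize(row_normalize(unclass_psn_safe(S)))
  Dn <- symmetrize(row_normalize(unclass_psn_safe(D)))

  if (cfg$neighbor_source == "self") {
    Sp <- knn_localize(Sn, K)
    Dp <- knn_localize(Dn, K)
  } else {
    nb_s <- top_k_neighbors(Sn, K)
    nb_d <- top_k_neighbors(Dn, K)
    nb <- Map(function(a, b) sort(union(a, b)), nb_s, nb_d)
    Sp <- knn_localize(Sn, K, neighbor_idx = nb)
    Dp <- knn_localize(Dn, K, neighbor_idx = nb)
  }

  mp1 <- switch(cfg$init, normalized = Sn, localized = Sp,
                raw = unclass_psn_safe(S))
  mp2 <- switch(cfg$init, normalized = Dn, localized = Dp,
                raw = unclass_psn_safe(D))

  iterations <- 0L
  converged <- FALSE
  for (t in seq_len(cfg$T_iter)) {
    new1 <- (cfg$wts * Sp + (1 - cfg$wts) * mp2) / 2
    new2 <- (cfg$wtd * Dp + (1 - cfg$wtd) * mp1) / 2
    delta <- max(abs(new1 - mp1), abs(new2 - mp2))
    mp1 <- new1; mp2 <- new2
    iterations <- t
    if (cfg$mode == "converge" && delta < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  FM <- symmetrize((mp1 + mp2) / 2)
  FM <- psn_matrix(pmax(FM, 0), rownames(S) %||% rownames(D), "similarity")
  attr(FM, "iterations") <- iterations
  attr(FM, "converged") <- converged
  FM
}

#' Analytic fixed point of the fusion recursion
#'
#' The fusion recursion is linear in the pair of state matrices, so its fixed
#' point solves, elementwise,
#' `p = (wts*S' + (1-wts)*q)/2` and `q = (wtd*D' + (1-wtd)*p)/2`,
#' giving `p = (A + a*B) / (1 - a*b)` with `A = wts*S'/2`, `B = wtd*D'/2`,
#' `a = (1-wts)/2`, `b = (1-wtd)/2`, and the fused matrix `(p + q)/2`. Used
#' as an independent closed-form check of the iterative [snf_fuse()].
#'
#' @param Sp,Dp the (already normalized/localized) static terms of the
#'   recursion.
#' @param cfg a [fusion_config()] (only `wts`, `wtd` are used).
#' @return list with `p`, `q`, and `FM` (the fixed-point fused matrix,
#'   symmetrized like [snf_fuse()]'s output).
#' @export
snf_fixed_point <- function(Sp, Dp, cfg) {
  A <- cfg$wts * unclass_psn_safe(Sp) / 2
  B <- cfg$wtd * unclass_psn_safe(Dp) / 2
  a <- (1 - cfg$wts) / 2
  b <- (1 - cfg$wtd) / 2
  p <- (A + a * B) / (1 - a * b)
  q <- B + b * p
  list(p = p, q = q, FM = symmetrize((p + q) / 2))
}

#' Localized inputs of the fusion pipeline
#'
#' Exposes the normalize -> symmetrize -> KNN-localize preprocessing applied
#' by [snf_fuse()], for inspection and for feeding [snf_fixed_point()].
#'
#' @inheritParams snf_fuse
#' @return list with `Sn`, `Dn` (normalized, symmetrized) and `Sp`, `Dp`
#'   (localized).
#' @export
snf_preprocess <- function(S, D, cfg) {
  n <- nrow(S)
  K <- resolve_K(cfg, n)
  Sn <- symmetrize(row_normalize(unclass_psn_safe(S)))
  Dn <- symmetrize(row_normalize(unclass_psn_safe(D)))
  if (cfg$neighbor_source == "self") {
    Sp <- knn_localize(Sn, K); Dp <- knn_localize(Dn, K)
  } else {
    nb <- Map(function(a, b) sort(union(a, b)),
              top_k_neighbors(Sn, K), top_k_neighbors(Dn, K))
    Sp <- knn_localize(Sn, K, neighbor_idx = nb)
    Dp <- knn_localize(Dn, K, neighbor_idx = nb)
  }
  list(Sn = Sn, Dn = Dn, Sp = Sp, Dp = Dp)
}
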