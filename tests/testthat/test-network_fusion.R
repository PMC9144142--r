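test_that("row normalization makes rows stochastic and is idempotent", {
  M <- matrix(c(1, 2, 1, 2), 2, 2)
  N <- row_normalize(M)
  expect_equal(unname(N), matrix(0.5, 2, 2))
  expect_equal(row_normalize(N), N)
  expect_error(row_normalize(matrix(c(1, -1, 0, 1), 2, 2)), "negative")
})

test_that("all-zero rows become uniform with a warning", {
  M <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 1), c(2, 0, 0, 2), c(0, 4, 0, 0))
  expect_warning(N <- row_normalize(M), "all-zero")
  expect_equal(N[1, ], rep(0.25, 4))
  expect_equal(rowSums(N), rep(1, 4), tolerance = 1e-12)
})

test_that("symmetrize averages with the transpose and is idempotent", {
  M <- matrix(c(0, 0, 1, 0), 2, 2)
  S <- symmetrize(M)
  expect_equal(unname(S), matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_identical(symmetrize(S), S)
  sym_in <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_equal(symmetrize(sym_in), sym_in)
})

test_that("knn localization keeps top-K rows renormalized to sum 1", {
  M <- rbind(c(1, 0.6, 0.4), c(0.6, 1, 0.2), c(0.4, 0.2, 1))
  L1 <- knn_localize(M, K = 1)
  expect_equal(unname(L1[1, ]), c(0, 1, 0))  # 0.6 / 0.6
  expect_equal(unname(diag(L1)), rep(0, 3))
  L2 <- knn_localize(M, K = 2)
  expect_equal(unname(L2[1, ]), c(0, 0.6, 0.4))
  expect_equal(rowSums(L2), rep(1, 3), tolerance = 1e-12)
  expect_error(knn_localize(M, K = 3), "K must satisfy")
})

test_that("K = N-1 reduces to row normalization of off-diagonal entries", {
  M <- rand_similarity(6, seed = 2)
  L <- knn_localize(M, K = 5)
  off <- unclass(M); diag(off) <- 0
  expect_equal(unclass(L), unclass(off / rowSums(off)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ties at the K-th neighbor break toward the lower index", {
  M <- rbind(c(1, 0.5, 0.5, 0.2),
             c(0.5, 1, 0.1, 0.1),
             c(0.5, 0.1, 1, 0.1),
             c(0.2, 0.1, 0.1, 1))
  L <- knn_localize(M, K = 1)
  expect_equal(unname(L[1, ]), c(0, 1, 0, 0))  # index 2 beats tied index 3
})

test_that("knn localization preserves each row's top-K rank order", {
  M <- rand_similarity(12, seed = 3)
  K <- 4
  L <- knn_localize(M, K)
  for (i in 1:12) {
    kept <- which(L[i, ] > 0)
    expect_length(kept, K)
    raw <- unclass(M)[i, ]; raw[i] <- -Inf
    expect_setequal(kept, order(-raw, 1:12)[1:K])
    expect_equal(order(-L[i, kept]), order(-raw[kept]))
  }
})

test_that("scalar fusion recursion converges to the 1/3 fixed point", {
  # S' = D' = 1, wts = wtd = 0.5, MP0 = 1
  p <- 1; q <- 1
  for (t in 1:200) {
    pn <- (0.5 * 1 + 0.5 * q) / 2
    qn <- (0.5 * 1 + 0.5 * p) / 2
    p <- pn; q <- qn
  }
  expect_equal((p + q) / 2, 1 / 3, tolerance = 1e-12)
  fx <- snf_fixed_point(matrix(1), matrix(1), fusion_config(K = 1))
  expect_equal(fx$FM[1, 1], 1 / 3, tolerance = 1e-12)
})

test_that("one fusion step matches hand iteration of the recursion", {
  S <- rand_similarity(5, seed = 4)
  D <- rand_similarity(5, seed = 5)
  cfg <- fusion_config(K = 2, T_iter = 1, wts = 0.3, wtd = 0.7)
  pre <- snf_preprocess(S, D, cfg)
  mp1 <- (0.3 * pre$Sp + 0.7 * pre$Dn) / 2
  mp2 <- (0.7 * pre$Dp + 0.3 * pre$Sn) / 2
  by_hand <- symmetrize((mp1 + mp2) / 2)
  expect_equal(unclass(snf_fuse(S, D, cfg)), unclass(by_hand),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("iterated fusion matches the analytic fixed point", {
  S <- rand_similarity(8, seed = 6)
  D <- rand_similarity(8, seed = 7)
  cfg <- fusion_config(K = 3, T_iter = 300, wts = 0.3, wtd = 0.7)
  FM <- snf_fuse(S, D, cfg)
  pre <- snf_preprocess(S, D, cfg)
  fx <- snf_fixed_point(pre$Sp, pre$Dp, cfg)
  expect_equal(unclass(FM), unclass(pmax(fx$FM, 0)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("role weights 1/1 decouple the recursion to (S'+D')/4", {
  S <- rand_similarity(6, seed = 8)
  D <- rand_similarity(6, seed = 9)
  cfg <- fusion_config(K = 2, T_iter = 50, wts = 1, wtd = 1)
  FM <- snf_fuse(S, D, cfg)
  pre <- snf_preprocess(S, D, cfg)
  expect_equal(unclass(FM), unclass(symmetrize((pre$Sp + pre$Dp) / 4)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fusion is exchange-symmetric under matrix/weight swap", {
  S <- rand_similarity(7, seed = 10)
  D <- rand_similarity(7, seed = 11)
  F1 <- snf_fuse(S, D, fusion_config(K = 3, T_iter = 40, wts = 0.2,
                                     wtd = 0.6))
  F2 <- snf_fuse(D, S, fusion_config(K = 3, T_iter = 40, wts = 0.6,
                                     wtd = 0.2))
  expect_equal(unclass(F1), unclass(F2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fusion iteration contracts geometrically toward the fixed point", {
  S <- rand_similarity(10, seed = 12)
  D <- rand_similarity(10, seed = 13)
  cfg <- fusion_config(K = 4, wts = 0.4, wtd = 0.6)
  pre <- snf_preprocess(S, D, cfg)
  fx <- snf_fixed_point(pre$Sp, pre$Dp, cfg)
  mp1 <- pre$Sn; mp2 <- pre$Dn
  errs <- numeric(10)
  for (t in 1:10) {
    new1 <- (cfg$wts * pre$Sp + (1 - cfg$wts) * mp2) / 2
    new2 <- (cfg$wtd * pre$Dp + (1 - cfg$wtd) * mp1) / 2
    mp1 <- new1; mp2 <- new2
    errs[t] <- max(abs(mp1 - fx$p), abs(mp2 - fx$q))
  }
  ratio_bound <- max(1 - cfg$wts, 1 - cfg$wtd) / 2
  # per two-step cycle the error shrinks at least by the bound
  expect_true(all(errs[seq(3, 9, 2)] <=
                    errs[seq(1, 7, 2)] * ratio_bound + 1e-15))
})

test_that("fused output is nonnegative, symmetric, and converge mode stops
           early", {
  S <- rand_similarity(9, seed = 14)
  D <- rand_similarity(9, seed = 15)
  cfg <- fusion_config(K = 3, T_iter = 500, mode = "converge", tol = 1e-11)
  FM <- snf_fuse(S, D, cfg)
  expect_true(all(FM >= 0))
  expect_true(isSymmetric(unclass(FM)))
  expect_true(attr(FM, "converged"))
  expect_lt(attr(FM, "iterations"), 500)
})

test_that("shape or index mismatch is a hard error", {
  S <- rand_similarity(5, seed = 1)
  D <- rand_similarity(6, seed = 1)
  expect_error(snf_fuse(S, D, fusion_config(K = 2)), "shape")
  D5 <- rand_similarity(5, seed = 2)
  rownames(D5) <- colnames(D5) <- paste0("Q", 1:5)
  expect_error(snf_fuse(S, D5, fusion_config(K = 2)), "index mismatch")
})
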