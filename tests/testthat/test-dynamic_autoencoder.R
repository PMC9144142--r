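# numerical gradient of the masked reconstruction loss by central
# finite differences: the independent oracle for the analytic backward pass
numerical_gradient <- function(params, X, mask, cfg, eps = 1e-5) {
  loss_at <- function(p) psnfuse:::ae_forward(p, X, mask, cfg)$loss
  lapply(names(params), function(k) {
    g <- params[[k]] * 0
    for (i in seq_along(params[[k]])) {
      up <- params; up[[k]][i] <- up[[k]][i] + eps
      dn <- params; dn[[k]][i] <- dn[[k]][i] - eps
      g[i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    g
  }) |> stats::setNames(names(params))
}

test_that("analytic gradients match central finite differences", {
  cfg <- autoencoder_config(n_features = 2, n_embed = 3, seed = 9)
  params <- withr::with_seed(9, psnfuse:::init_params(cfg))
  # variable-length batch of 4 patients, lengths 3/2/1/3
  seqs <- withr::with_seed(4, list(
    matrix(rnorm(6), 3, 2), matrix(rnorm(4), 2, 2),
    matrix(rnorm(2), 1, 2), matrix(rnorm(6), 3, 2)
  ))
  batch <- psnfuse:::pad_batch(seqs)
  fw <- psnfuse:::ae_forward(params, batch$X, batch$mask, cfg,
                             want_cache = TRUE)
  analytic <- psnfuse:::ae_backward(params, batch$X, batch$mask, cfg, fw)
  numeric <- numerical_gradient(params, batch$X, batch$mask, cfg)
  for (k in names(params)) {
    denom <- max(abs(numeric[[k]]), 1e-8)
    expect_lt(max(abs(analytic[[k]] - numeric[[k]])) / denom, 1e-5)
  }
})

test_that("training is deterministic under a fixed seed", {
  lc <- make_longitudinal_cohort(cohort_recipe(n_patients = 20, seed = 2))
  cfg <- autoencoder_config(9, n_embed = 6, n_iter = 15, seed = 5)
  m1 <- train_autoencoder(lc$visits, cfg)
  m2 <- train_autoencoder(lc$visits, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("constant per-patient sequences are reconstructed accurately", {
  seqs <- withr::with_seed(8, lapply(1:50, function(i) {
    visits <- sample(2:5, 1)
    matrix(rep(rnorm(3), each = visits), visits, 3)
  }))
  names(seqs) <- paste0("P", 1:50)
  vs <- visit_sequences(seqs)
  cfg <- autoencoder_config(3, n_embed = 8, n_iter = 500,
                            learning_rate = 0.01, seed = 1)
  model <- train_autoencoder(vs, cfg)
  expect_lt(reconstruction_mse(model, vs), 0.05)
})

test_that("loss history trends downward on learnable data", {
  lc <- make_longitudinal_cohort(cohort_recipe(n_patients = 40, seed = 3))
  cfg <- autoencoder_config(9, n_embed = 8, n_iter = 120, seed = 2)
  model <- train_autoencoder(lc$visits, cfg)
  head_mean <- mean(model$loss_history[1:20])
  tail_mean <- mean(utils::tail(model$loss_history, 20))
  expect_lt(tail_mean, head_mean)
})

test_that("embedding collapses visits to one row per patient", {
  lc <- make_longitudinal_cohort(cohort_recipe(n_patients = 25, seed = 6))
  cfg <- autoencoder_config(9, n_embed = 5, n_iter = 10, seed = 1)
  model <- train_autoencoder(lc$visits, cfg)
  emb <- embed_patients(lc$visits, model)
  expect_equal(dim(emb), c(25L, 5L))
  expect_identical(rownames(emb), lc$visits$patient_ids)
  expect_true(all(is.finite(emb)))
})

test_that("identical sequences give identical embeddings and reordering
           permutes them", {
  base <- matrix(seq(1, 12), 4, 3)
  vs <- visit_sequences(list(A = base, B = base * 2, C = base))
  cfg <- autoencoder_config(3, n_embed = 4, n_iter = 20, seed = 3)
  model <- train_autoencoder(vs, cfg)
  emb <- embed_patients(vs, model)
  expect_equal(emb["A", ], emb["C", ])

  vs_perm <- visit_sequences(list(C = base, A = base, B = base * 2))
  emb_perm <- embed_patients(vs_perm, model)
  expect_equal(emb_perm[c("A", "B", "C"), ], emb[c("A", "B", "C"), ])
})

test_that("untrained input or wrong width is rejected", {
  vs <- tiny_visits()
  expect_error(embed_patients(vs, list()), "trained")
  cfg <- autoencoder_config(5, n_embed = 4)
  expect_error(train_autoencoder(vs, cfg), "width")
})

test_that("dynamic similarity matrix matches hand conversion of distances", {
  emb <- rbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  M <- dynamic_similarity_matrix(emb)
  expect_equal(M["a", "b"], 1 / 6)     # d = 5
  expect_equal(M["a", "c"], 1 / 11)    # d = 10
  expect_equal(M["b", "c"], 1 / 6)
  expect_equal(diag(unclass(M)), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(unclass(M)))

  col_emb <- rbind(a = c(1, 2), b = c(2, 4), c = c(4, 8))
  Mc <- dynamic_similarity_matrix(col_emb,
                                  metric = distance_metric("cosine"))
  expect_equal(Mc["a", "b"], 1, tolerance = 1e-9)  # collinear embeddings
})

test_that("autoencoder survives a JSON save/load round trip", {
  lc <- make_longitudinal_cohort(cohort_recipe(n_patients = 15, seed = 4))
  cfg <- autoencoder_config(9, n_embed = 4, n_iter = 5, seed = 2)
  model <- train_autoencoder(lc$visits, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_autoencoder(model, path)
  model2 <- load_autoencoder(path)
  expect_equal(embed_patients(lc$visits, model2),
               embed_patients(lc$visits, model), tolerance = 1e-12)
})

test_that("well-separated latent regimes give higher within-group
           similarity", {
  lc <- make_longitudinal_cohort(cohort_recipe(n_patients = 200,
                                               beta_dynamic = 1,
                                               seed = 11))
  cfg <- autoencoder_config(9, n_embed = 16, n_iter = 250, seed = 1)
  model <- train_autoencoder(lc$visits, cfg)
  emb <- embed_patients(lc$visits, model)
  M <- dynamic_similarity_matrix(emb)
  grp <- lc$cohort$outcome
  same <- outer(grp, grp, "==")
  ut <- upper.tri(M)
  within <- M[ut & same]
  between <- M[ut & !same]
  wt <- stats::wilcox.test(within, between, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
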