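#' Autoencoder configuration
#'
#' Hyperparameters of the sequence autoencoder that compresses each patient's
#' variable-length visit sequence into one fixed-length embedding vector (the
#' encoder's final hidden state).
#'
#' @param n_features width of each visit vector (number of measurements).
#' @param n_embed embedding / hidden-state dimension (default 32; 5-64 are
#'   the sensible range for visit data of this width).
#' @param activation activation of the learned visit-embedding layer applied
#'   before the recurrence: `"relu"` (default) or `"linear"`.
#' @param batch_size minibatch size (default 32).
#' @param n_iter number of parameter updates (minibatch steps). Reconstruction
#'   loss on cohorts of this shape typically stabilizes within a few thousand
#'   iterations; tests and examples use far fewer.
#' @param learning_rate Adam step size.
#' @param clip_norm global gradient-norm clip.
#' @param seed integer seed fixing weight initialization and batch shuffling.
#' @return Object of class `autoencoder_config`.
#' @export
autoencoder_config <- function(n_features, n_embed = 32,
                               activation = c("relu", "linear"),
                               batch_size = 32, n_iter = 3000,
                               learning_rate = 1e-3, clip_norm = 5,
                               seed = 1) {
  activation <- match.arg(activation)
  stopifnot(n_features >= 1, n_embed >= 1, batch_size >= 1, n_iter >= 1,
            learning_rate > 0)
  structure(list(n_features = as.integer(n_features),
                 n_embed = as.integer(n_embed), activation = activation,
                 batch_size = as.integer(batch_size),
                 n_iter = as.integer(n_iter),
                 learning_rate = learning_rate, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform init scaled by fan-in, the usual recurrent-net default
init_mat <- function(nr, nc) {
  s <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

init_params <- function(cfg) {
  f <- cfg$n_features; h <- cfg$n_embed
  p <- list(
    Wv = init_mat(f, f), bv = numeric(f),            # visit embedding layer
    We = init_mat(h + f, 4 * h), be = numeric(4 * h), # encoder LSTM
    Wd = init_mat(2 * h, 4 * h), bd = numeric(4 * h), # decoder LSTM
    Wy = init_mat(h, f), by = numeric(f)              # reconstruction head
  )
  # forget-gate bias 1: standard trick so memory persists early in training
  p$be[(h + 1):(2 * h)] <- 1
  p$bd[(h + 1):(2 * h)] <- 1
  p
}

# pad a list of T_i x F matrices into an N x Tmax x F array plus N x Tmax mask
pad_batch <- function(seq_list) {
  n <- length(seq_list)
  lens <- vapply(seq_list, nrow, integer(1))
  tmax <- max(lens)
  f <- ncol(seq_list[[1]])
  X <- array(0, c(n, tmax, f))
  M <- matrix(0, n, tmax)
  for (i in seq_len(n)) {
    X[i, seq_len(lens[i]), ] <- seq_list[[i]]
    M[i, seq_len(lens[i])] <- 1
  }
  list(X = X, mask = M, lens = lens)
}

# one masked LSTM step; padded rows carry state through unchanged
lstm_step <- function(hprev, cprev, xin, W, b, mask) {
  h <- ncol(hprev)
  z <- cbind(hprev, xin)
  gates <- z %*% W + rep(1, nrow(z)) %o% b
  i <- sigmoid(gates[, 1:h, drop = FALSE])
  f <- sigmoid(gates[, (h + 1):(2 * h), drop = FALSE])
  o <- sigmoid(gates[, (2 * h + 1):(3 * h), drop = FALSE])
  g <- tanh(gates[, (3 * h + 1):(4 * h), drop = FALSE])
  cnew <- f * cprev + i * g
  hnew <- o * tanh(cnew)
  cc <- mask * cnew + (1 - mask) * cprev
  hh <- mask * hnew + (1 - mask) * hprev
  list(h = hh, c = cc, i = i, f = f, o = o, g = g, cnew = cnew,
       z = z, cprev = cprev, hprev = hprev, mask = mask)
}

# backward through one masked LSTM step.
# dh, dc: gradients w.r.t. the carried (post-mask) h and c.
lstm_step_backward <- function(cache, dh, dc, W) {
  h <- ncol(dh)
  m <- cache$mask
  dh_new <- m * dh
  dh_prev_carry <- (1 - m) * dh
  dc_new <- m * dc
  dc_prev_carry <- (1 - m) * dc

  tc <- tanh(cache$cnew)
  do_ <- dh_new * tc
  dc_new <- dc_new + dh_new * cache$o * (1 - tc^2)
  di <- dc_new * cache$g
  dg <- dc_new * cache$i
  df <- dc_new * cache$cprev
  dc_prev <- dc_new * cache$f + dc_prev_carry

  dgates <- cbind(di * cache$i * (1 - cache$i),
                  df * cache$f * (1 - cache$f),
                  do_ * cache$o * (1 - cache$o),
                  dg * (1 - cache$g^2))
  dW <- crossprod(cache$z, dgates)
  db <- colSums(dgates)
  dz <- tcrossprod(dgates, W)
  dh_prev <- dz[, 1:h, drop = FALSE] + dh_prev_carry
  dx <- dz[, (h + 1):ncol(dz), drop = FALSE]
  list(dW = dW, db = db, dh_prev = dh_prev, dc_prev = dc_prev, dx = dx)
}

# full forward pass over a padded batch; returns loss, embeddings, and (if
# want_grad) every intermediate needed by ae_backward
ae_forward <- function(params, X, mask, cfg, want_cache = FALSE) {
  n <- dim(X)[1]; tmax <- dim(X)[2]; f <- dim(X)[3]; h <- cfg$n_embed
  ones <- rep(1, n)

  enc_cache <- vector("list", tmax)
  proj_cache <- vector("list", tmax)
  hh <- matrix(0, n, h); cc <- matrix(0, n, h)
  for (t in seq_len(tmax)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(n, f)
    pre <- xt %*% params$Wv + ones %o% params$bv
    xe <- if (cfg$activation == "relu") pmax(pre, 0) else pre
    st <- lstm_step(hh, cc, xe, params$We, params$be, mask[, t])
    hh <- st$h; cc <- st$c
    if (want_cache) { enc_cache[[t]] <- st; proj_cache[[t]] <- pre }
  }
  emb <- hh  # encoder final hidden state = patient embedding

  dec_cache <- vector("list", tmax)
  hd <- matrix(0, n, h); cd <- matrix(0, n, h)
  loss <- 0
  denom <- sum(mask) * f
  dY <- if (want_cache) vector("list", tmax) else NULL
  for (t in seq_len(tmax)) {
    st <- lstm_step(hd, cd, emb, params$Wd, params$bd, mask[, t])
    hd <- st$h; cd <- st$c
    y <- st$h %*% params$Wy + ones %o% params$by
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(n, f)
    err <- (y - xt) * mask[, t]
    loss <- loss + sum(err^2)
    if (want_cache) { dec_cache[[t]] <- st; dY[[t]] <- 2 * err / denom }
  }
  list(loss = loss / denom, emb = emb,
       enc_cache = enc_cache, proj_cache = proj_cache,
       dec_cache = dec_cache, dY = dY, denom = denom)
}

ae_backward <- function(params, X, mask, cfg, fw) {
  n <- dim(X)[1]; tmax <- dim(X)[2]; f <- dim(X)[3]; h <- cfg$n_embed
  g <- lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))

  # decoder: backward through time; embedding receives gradient at every step
  dh <- matrix(0, n, h); dc <- matrix(0, n, h)
  demb <- matrix(0, n, h)
  for (t in rev(seq_len(tmax))) {
    st <- fw$dec_cache[[t]]
    dy <- fw$dY[[t]]
    g$Wy <- g$Wy + crossprod(st$h, dy)
    g$by <- g$by + colSums(dy)
    dh <- dh + tcrossprod(dy, params$Wy)
    bk <- lstm_step_backward(st, dh, dc, params$Wd)
    g$Wd <- g$Wd + bk$dW; g$bd <- g$bd + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
    demb <- demb + bk$dx
  }

  # encoder: gradient enters at the final hidden state
  dh <- demb; dc <- matrix(0, n, h)
  for (t in rev(seq_len(tmax))) {
    st <- fw$enc_cache[[t]]
    bk <- lstm_step_backward(st, dh, dc, params$We)
    g$We <- g$We + bk$dW; g$be <- g$be + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
    dxe <- bk$dx
    if (cfg$activation == "relu") dxe <- dxe * (fw$proj_cache[[t]] > 0)
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(n, f)
    g$Wv <- g$Wv + crossprod(xt, dxe)
    g$bv <- g$bv + colSums(dxe)
  }
  g
}

adam_update <- function(params, grads, state, lr, t, clip_norm,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(clip_norm) && gn > clip_norm) clip_norm / gn else 1
  for (k in names(params)) {
    g <- grads[[k]] * scale
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Standardize visit sequences
#'
#' z-scores each feature over all visits of all patients (the training
#' statistics are stored so new sequences can reuse them).
#'
#' @param seqs a [visit_sequences()].
#' @param center,scale optional precomputed per-feature statistics.
#' @return `visit_sequences` with attributes `center` and `scale`.
#' @export
standardize_sequences <- function(seqs, center = NULL, scale = NULL) {
  all_rows <- do.call(rbind, seqs$seqs)
  if (is.null(center)) center <- colMeans(all_rows)
  if (is.null(scale)) {
    scale <- apply(all_rows, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  out <- seqs
  out$seqs <- lapply(seqs$seqs, function(m) {
    sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  })
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Train the sequence autoencoder
#'
#' An LSTM encoder reads each patient's (z-scored) visit sequence and its
#' final hidden state — the patient embedding — is repeated at every step as
#' input to an LSTM decoder whose linear head reconstructs the sequence.
#' Training minimizes mean squared reconstruction error over real (unpadded)
#' steps with Adam. Padded steps are masked out of both the recurrence and
#' the loss. Fully deterministic under `cfg$seed`.
#'
#' @param seqs a [visit_sequences()]; features should be standardized
#'   ([standardize_sequences()] is applied automatically unless
#'   `standardize = FALSE`).
#' @param cfg an [autoencoder_config()].
#' @param standardize z-score features before training (default TRUE).
#' @return Object of class `psn_autoencoder`: trained parameters, config,
#'   standardization statistics, and `loss_history` (per-iteration masked
#'   MSE of the minibatch).
#' @export
train_autoencoder <- function(seqs, cfg, standardize = TRUE) {
  stopifnot(inherits(seqs, "visit_sequences"),
            inherits(cfg, "autoencoder_config"))
  if (length(seqs$seqs) < 2) stop("need at least 2 patients", call. = FALSE)
  if (seqs$n_features != cfg$n_features) {
    stop("sequence width ", seqs$n_features, " does not match cfg n_features ",
         cfg$n_features, call. = FALSE)
  }
  center <- NULL; scale <- NULL
  if (standardize) {
    seqs <- standardize_sequences(seqs)
    center <- attr(seqs, "center"); scale <- attr(seqs, "scale")
  }

  withr::with_seed(cfg$seed, {
    params <- init_params(cfg)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    n <- length(seqs$seqs)
    loss_history <- numeric(cfg$n_iter)
    order_pool <- integer(0)
    for (it in seq_len(cfg$n_iter)) {
      if (length(order_pool) < cfg$batch_size) {
        order_pool <- c(order_pool, sample.int(n))
      }
      take <- seq_len(min(cfg$batch_size, n))
      idx <- order_pool[take]
      order_pool <- order_pool[-take]
      batch <- pad_batch(seqs$seqs[idx])
      fw <- ae_forward(params, batch$X, batch$mask, cfg, want_cache = TRUE)
      if (!is.finite(fw$loss)) {
        stop("NaN/Inf loss at iteration ", it,
             "; lower the learning rate or check inputs", call. = FALSE)
      }
      grads <- ae_backward(params, batch$X, batch$mask, cfg, fw)
      upd <- adam_update(params, grads, state, cfg$learning_rate, it,
                         cfg$clip_norm)
      params <- upd$params; state <- upd$state
      loss_history[it] <- fw$loss
    }
    structure(list(params = params, config = cfg,
                   center = center, scale = scale,
                   feature_names = seqs$feature_names,
                   loss_history = loss_history),
              class = "psn_autoencoder")
  })
}

#' @export
print.psn_autoencoder <- function(x, ...) {
  cat("psn_autoencoder:", x$config$n_features, "features ->",
      x$config$n_embed, "dims;", length(x$loss_history),
      "iterations; final minibatch MSE",
      format(utils::tail(x$loss_history, 1), digits = 4), "\n")
  invisible(x)
}

#' Reconstruction MSE of a trained autoencoder on a sequence set
#'
#' Masked mean squared error over all real visit steps, on the standardized
#' scale used in training.
#'
#' @param model a trained `psn_autoencoder`.
#' @param seqs a [visit_sequences()] on the original measurement scale.
#' @return scalar MSE.
#' @export
reconstruction_mse <- function(model, seqs) {
  seqs <- apply_model_scaling(model, seqs)
  batch <- pad_batch(seqs$seqs)
  ae_forward(model$params, batch$X, batch$mask, model$config)$loss
}

#' Mean-predictor baseline MSE
#'
#' MSE of predicting, for every visit step, the per-feature mean over all
#' visits — the natural no-model baseline for reconstruction error, computed
#' on the same standardized scale as [reconstruction_mse()].
#'
#' @param model a trained `psn_autoencoder` (supplies the scaling).
#' @param seqs a [visit_sequences()].
#' @return scalar MSE.
#' @export
baseline_mse <- function(model, seqs) {
  seqs <- apply_model_scaling(model, seqs)
  all_rows <- do.call(rbind, seqs$seqs)
  mu <- colMeans(all_rows)
  mean(sweep(all_rows, 2, mu, "-")^2)
}

apply_model_scaling <- function(model, seqs) {
  if (is.null(model$center)) return(seqs)
  standardize_sequences(seqs, center = model$center, scale = model$scale)
}

#' Embed patients with a trained encoder
#'
#' Runs the encoder over each patient's sequence and returns the final hidden
#' state per patient: the visit table collapses from one row per visit to one
#' row per patient.
#'
#' @param seqs a [visit_sequences()] on the original measurement scale.
#' @param model a trained `psn_autoencoder`.
#' @return numeric matrix, one row per patient (rownames = patient ids),
#'   `n_embed` columns.
#' @export
embed_patients <- function(seqs, model) {
  if (!inherits(model, "psn_autoencoder")) {
    stop("model must be a trained psn_autoencoder", call. = FALSE)
  }
  if (seqs$n_features != model$config$n_features) {
    stop("sequence width does not match the trained model", call. = FALSE)
  }
  seqs <- apply_model_scaling(model, seqs)
  batch <- pad_batch(seqs$seqs)
  emb <- ae_forward(model$params, batch$X, batch$mask, model$config)$emb
  rownames(emb) <- seqs$patient_ids
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  emb
}

#' Dynamic similarity matrix from patient embeddings
#'
#' Pairwise distances between embeddings (Euclidean by default) converted to
#' similarities; symmetric with unit diagonal.
#'
#' @param emb embedding matrix from [embed_patients()].
#' @param metric a [distance_metric()].
#' @param conversion see [distance_to_similarity()].
#' @return similarity-tagged [psn_matrix()].
#' @export
dynamic_similarity_matrix <- function(emb,
                                      metric = distance_metric("euclidean"),
                                      conversion = c("inverse", "gaussian")) {
  emb <- as.matrix(emb)
  D <- pairwise_distance_matrix(emb, metric)
  distance_to_similarity(psn_matrix(D, rownames(emb), "distance"),
                         conversion = match.arg(conversion))
}

#' Save / load a trained autoencoder as plain text
#'
#' Serializes parameters, config, and scaling to a JSON artifact so a trained
#' encoder can be reused across sessions.
#'
#' @param model a `psn_autoencoder`.
#' @param path output JSON path.
#' @export
save_autoencoder <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    center = model$center, scale = model$scale,
    feature_names = model$feature_names,
    loss_history = model$loss_history,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
      else list(dim = NULL, values = as.numeric(p))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_autoencoder
#' @return `load_autoencoder` returns the restored `psn_autoencoder`.
#' @export
load_autoencoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(autoencoder_config, obj$config[
    c("n_features", "n_embed", "activation", "batch_size", "n_iter",
      "learning_rate", "clip_norm", "seed")])
  params <- lapply(obj$params, function(p) {
    v <- as.numeric(p$values)
    if (!is.null(p$dim) && length(p$dim)) {
      matrix(v, p$dim[1], p$dim[2])
    } else v
  })
  structure(list(params = params, config = cfg,
                 center = obj$center, scale = obj$scale,
                 feature_names = obj$feature_names,
                 loss_history = obj$loss_history),
            class = "psn_autoencoder")
}
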