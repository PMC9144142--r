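#' Default feature specs for the synthetic cohort shapes
#'
#' Line-list shaped cohorts get age / gender / symptom-text / chronic
#' features; longitudinal cohorts get their static profile features.
#'
#' @param cohort a [static_cohort()].
#' @return list of [feature_spec()]s covering the cohort's typed columns,
#'   equally weighted, with rules chosen by declared type (`age` columns get
#'   `age_ratio`; text columns `text_onehot`; boolean/categorical
#'   `exact_match`; other numerics `numeric_passthrough`).
#' @export
default_feature_specs <- function(cohort) {
  specs <- lapply(names(cohort$col_types), function(cn) {
    kind <- switch(cohort$col_types[[cn]],
                   numeric = if (grepl("age", cn)) "age_ratio"
                             else "numeric_passthrough",
                   boolean = ,
                   categorical = "exact_match",
                   text = "text_onehot")
    feature_spec(cn, kind, weight = 1)
  })
  if (!length(specs)) stop("cohort has no typed columns", call. = FALSE)
  specs
}

specs_from_config <- function(cfg_list) {
  lapply(cfg_list, function(s) {
    feature_spec(s$name, s$kind, weight = s$weight %||% 1)
  })
}

#' Run the static PSN stage
#'
#' Builds the static similarity matrix for a cohort, evaluates it against the
#' outcome by cross-validated patient-KNN, and (optionally) writes the matrix
#' and a metrics summary.
#'
#' @param cohort a [static_cohort()].
#' @param specs feature specs (default [default_feature_specs()]).
#' @param method,metric,conversion see [static_similarity_matrix()].
#' @param protocol an [eval_protocol()].
#' @param out_dir optional output directory; when given, writes
#'   `static_matrix.csv` and `static_metrics.json`.
#' @return list with `matrix` and `cv` (cross-validation results).
#' @export
run_static_stage <- function(cohort, specs = default_feature_specs(cohort),
                             method = "stps",
                             metric = distance_metric("euclidean"),
                             conversion = "inverse",
                             protocol = eval_protocol("patient_knn", K = 5),
                             out_dir = NULL) {
  M <- static_similarity_matrix(cohort, specs, method = method,
                                metric = metric, conversion = conversion)
  cv <- crossvalidate(M, cohort$outcome, protocol)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_similarity_matrix(M, file.path(out_dir, "static_matrix.csv"))
    write_metrics_json(cv, file.path(out_dir, "static_metrics.json"),
                       protocol)
  }
  list(matrix = M, cv = cv)
}

#' Run the dynamic PSN stage
#'
#' Trains the sequence autoencoder, embeds every patient, builds the dynamic
#' similarity matrix, and evaluates it.
#'
#' @param visits a [visit_sequences()].
#' @param outcomes per-patient labels aligned with `visits$patient_ids`.
#' @param ae_config an [autoencoder_config()].
#' @param metric,conversion distance handling for the embedding matrix.
#' @param protocol an [eval_protocol()].
#' @param out_dir optional output directory; writes `embeddings.csv`,
#'   `dynamic_matrix.csv`, `loss_history.csv`, `dynamic_metrics.json`.
#' @return list with `model`, `embeddings`, `matrix`, `cv`.
#' @export
run_dynamic_stage <- function(visits, outcomes,
                              ae_config = autoencoder_config(
                                n_features = visits$n_features),
                              metric = distance_metric("euclidean"),
                              conversion = "inverse",
                              protocol = eval_protocol("patient_knn", K = 5),
                              out_dir = NULL) {
  model <- train_autoencoder(visits, ae_config)
  emb <- embed_patients(visits, model)
  M <- dynamic_similarity_matrix(emb, metric, conversion)
  cv <- crossvalidate(M, outcomes, protocol)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(id = rownames(emb), emb,
                                check.names = FALSE),
                     file.path(out_dir, "embeddings.csv"), row.names = FALSE)
    utils::write.csv(data.frame(iteration = seq_along(model$loss_history),
                                mse = model$loss_history),
                     file.path(out_dir, "loss_history.csv"),
                     row.names = FALSE)
    write_similarity_matrix(M, file.path(out_dir, "dynamic_matrix.csv"))
    write_metrics_json(cv, file.path(out_dir, "dynamic_metrics.json"),
                       protocol)
  }
  list(model = model, embeddings = emb, matrix = M, cv = cv)
}

#' Run the fusion stage
#'
#' Fuses a static and a dynamic similarity matrix and evaluates all three
#' networks under the same protocol for comparison.
#'
#' @param S,D similarity matrices on the same patients.
#' @param outcomes per-patient labels.
#' @param fusion a [fusion_config()].
#' @param protocol an [eval_protocol()].
#' @param out_dir optional output directory; writes `fused_matrix.csv`,
#'   `fused_edges.csv`, `fusion_metrics.json`.
#' @return list with `matrix` (fused), `cv` (list: static, dynamic, fused),
#'   and `comparison` (data.frame of mean metrics by channel).
#' @export
run_fusion_stage <- function(S, D, outcomes,
                             fusion = fusion_config(K = 20),
                             protocol = eval_protocol("patient_knn", K = 5),
                             out_dir = NULL) {
  FM <- snf_fuse(S, D, fusion)
  cv <- list(static = crossvalidate(S, outcomes, protocol),
             dynamic = crossvalidate(D, outcomes, protocol),
             fused = crossvalidate(FM, outcomes, protocol))
  comparison <- do.call(rbind, lapply(names(cv), function(ch) {
    data.frame(channel = ch, t(cv[[ch]]$mean))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_similarity_matrix(FM, file.path(out_dir, "fused_matrix.csv"))
    write_edge_list(FM, file.path(out_dir, "fused_edges.csv"))
    jsonlite::write_json(
      list(iterations = attr(FM, "iterations"),
           converged = attr(FM, "converged"),
           comparison = comparison),
      file.path(out_dir, "fusion_metrics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(matrix = FM, cv = cv, comparison = comparison)
}

write_metrics_json <- function(cv, path, protocol) {
  jsonlite::write_json(
    list(mode = protocol$mode, folds = protocol$folds,
         seed = protocol$seed, K = protocol$K,
         p_percent = protocol$p_percent,
         mean = as.list(cv$mean), sd = as.list(cv$sd),
         per_fold = cv$per_fold),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Sweep distance metrics over a static cohort
#'
#' Builds a distance-based static PSN under each named metric and reports
#' cross-validated accuracy, the comparison usually run before settling on a
#' metric.
#'
#' @param cohort a [static_cohort()].
#' @param specs feature specs.
#' @param metrics metric names to sweep.
#' @param weighted_weights per-feature weights for `weighted_manhattan`
#'   (named by feature); defaults to equal weights.
#' @param protocol an [eval_protocol()].
#' @return data.frame of mean CV metrics per distance measure.
#' @export
metric_sweep <- function(cohort, specs = default_feature_specs(cohort),
                         metrics = c("euclidean", "manhattan", "cosine",
                                     "chebyshev", "weighted_manhattan"),
                         weighted_weights = NULL,
                         protocol = eval_protocol("patient_knn", K = 5)) {
  rows <- lapply(metrics, function(mn) {
    metric <- if (mn == "weighted_manhattan") {
      w <- weighted_weights
      if (is.null(w)) {
        w <- stats::setNames(rep(1, length(specs)),
                             vapply(specs, `[[`, character(1), "name"))
      }
      distance_metric(mn, weights = w)
    } else distance_metric(mn)
    M <- static_similarity_matrix(cohort, specs, method = "distance",
                                  metric = metric)
    cv <- crossvalidate(M, cohort$outcome, protocol)
    data.frame(metric = mn, t(cv$mean))
  })
  do.call(rbind, rows)
}
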