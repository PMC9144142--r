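# tiny in-code fixtures shared across tests

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_static_df <- function() {
  data.frame(
    id = c("P1", "P2", "P3"),
    age = c(20, 40, 40),
    gender = c("F", "F", "M"),
    symptoms = c("fever, cough", "cough", "rash"),
    chronic = c(TRUE, TRUE, FALSE),
    outcome = c("died", "recovered", "recovered"),
    stringsAsFactors = FALSE
  )
}

tiny_cohort <- function() {
  static_cohort(tiny_static_df(), id_col = "id", outcome_col = "outcome",
                col_types = c(age = "numeric", gender = "categorical",
                              symptoms = "text", chronic = "boolean"))
}

tiny_visits <- function() {
  visit_sequences(list(
    A = matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE),
    B = matrix(c(7, 8, 9, 10), nrow = 2, byrow = TRUE)
  ), feature_names = c("x1", "x2"))
}

# deterministic small similarity matrix with planted 2-block structure
block_matrix <- function(sizes = c(4, 4), within = 0.9, between = 0.1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  M <- ifelse(outer(lab, lab, "=="), within, between)
  diag(M) <- 1
  psn_matrix(M, ids = paste0("P", seq_len(n)), type = "similarity")
}

rand_similarity <- function(n, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(stats::runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    psn_matrix(M, ids = paste0("P", seq_len(n)), type = "similarity")
  })
}
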