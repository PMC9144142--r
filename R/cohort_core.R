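#' Construct a static cohort
#'
#' A static cohort is one row per patient: an identifier, a set of typed
#' clinical columns (numeric, boolean, categorical, or free text), and an
#' outcome class label. All similarity matrices built from a cohort share its
#' patient order (order of first appearance).
#'
#' @param data data.frame with one row per patient.
#' @param id_col name of the patient identifier column.
#' @param outcome_col name of the outcome column, or `NULL` for an unlabeled
#'   cohort.
#' @param col_types named character vector mapping the remaining modeled
#'   columns to one of `"numeric"`, `"boolean"`, `"categorical"`, `"text"`.
#'   Columns of `data` not named here are carried along untyped.
#' @return An object of class `static_cohort`: a list with `data`,
#'   `patient_ids`, `col_types`, and `outcome` (factor or `NULL`).
#' @details Patients with a missing outcome are dropped with a warning, since
#'   outcome-based evaluation is undefined for them.
#' @export
static_cohort <- function(data, id_col = "id", outcome_col = "outcome",
                          col_types = character()) {
  stopifnot(is.data.frame(data))
  if (!id_col %in% names(data)) {
    stop("id column '", id_col, "' not found", call. = FALSE)
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate patient ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(col_types), names(data))
  if (length(unknown)) {
    stop("schema columns absent from data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(col_types, c("numeric", "boolean", "categorical", "text"))
  if (length(bad_type)) {
    stop("unknown column types: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }

  outcome <- NULL
  if (!is.null(outcome_col)) {
    if (!outcome_col %in% names(data)) {
      stop("outcome column '", outcome_col, "' not found", call. = FALSE)
    }
    oc <- data[[outcome_col]]
    missing_oc <- is.na(oc) | (is.character(oc) & !nzchar(trimws(oc)))
    if (any(missing_oc)) {
      warning(sum(missing_oc), " patient(s) excluded for missing outcome",
              call. = FALSE)
      data <- data[!missing_oc, , drop = FALSE]
      ids <- ids[!missing_oc]
      oc <- oc[!missing_oc]
    }
    outcome <- factor(oc)
  }

  # coerce typed columns; unparseable numeric cells become NA with one warning
  n_bad <- 0L
  for (cn in names(col_types)) {
    v <- data[[cn]]
    if (col_types[[cn]] == "numeric" && !is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      n_bad <- n_bad + sum(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
      data[[cn]] <- parsed
    } else if (col_types[[cn]] == "boolean" && !is.logical(v)) {
      data[[cn]] <- parse_boolean(v)
    } else if (col_types[[cn]] == "text") {
      data[[cn]] <- as.character(v)
    }
  }
  if (n_bad > 0) {
    warning(n_bad, " numeric cell(s) could not be parsed; set to NA",
            call. = FALSE)
  }

  structure(
    list(data = data, patient_ids = ids, id_col = id_col,
         col_types = col_types, outcome = outcome),
    class = "static_cohort"
  )
}

parse_boolean <- function(v) {
  if (is.numeric(v)) return(v != 0)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[s %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' @export
print.static_cohort <- function(x, ...) {
  cat("static_cohort:", length(x$patient_ids), "patients,",
      length(x$col_types), "typed columns")
  if (!is.null(x$outcome)) {
    cat(",", nlevels(x$outcome), "outcome classes")
  }
  cat("\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `static_cohort`.
#' @return integer patient count.
#' @export
n_patients <- function(cohort) length(cohort$patient_ids)

#' Read a static cohort from CSV
#'
#' @param path CSV file with a header row (RFC-4180, UTF-8).
#' @inheritParams static_cohort
#' @return A [static_cohort()].
#' @export
read_static_cohort <- function(path, id_col = "id", outcome_col = "outcome",
                               col_types = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  static_cohort(df, id_col = id_col, outcome_col = outcome_col,
                col_types = col_types)
}

#' Write a static cohort to CSV
#' @param cohort a `static_cohort`.
#' @param path output file.
#' @export
write_static_cohort <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE)
  invisible(path)
}

#' Construct visit sequences
#'
#' Ordered, variable-length sequences of fixed-width numeric visit vectors,
#' one sequence per patient. All sequences must share the same feature width.
#'
#' @param seqs named list of numeric matrices, one per patient; rows are
#'   visits in time order, columns are the measured features.
#' @param feature_names optional feature (column) names.
#' @return Object of class `visit_sequences`.
#' @export
visit_sequences <- function(seqs, feature_names = NULL) {
  stopifnot(is.list(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("seqs must be a named list with unique patient ids", call. = FALSE)
  }
  seqs <- lapply(seqs, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  widths <- vapply(seqs, ncol, integer(1))
  if (length(unique(widths)) != 1) {
    stop("all visit vectors must have identical width; got widths ",
         paste(sort(unique(widths)), collapse = ", "), call. = FALSE)
  }
  if (any(vapply(seqs, nrow, integer(1)) < 1)) {
    stop("every patient needs at least one visit", call. = FALSE)
  }
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == widths[[1]])
    seqs <- lapply(seqs, function(m) { colnames(m) <- feature_names; m })
  }
  structure(
    list(seqs = seqs, patient_ids = names(seqs), n_features = widths[[1]],
         feature_names = feature_names %||% colnames(seqs[[1]])),
    class = "visit_sequences"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.visit_sequences <- function(x, ...) {
  lens <- vapply(x$seqs, nrow, integer(1))
  cat("visit_sequences:", length(x$seqs), "patients,", sum(lens),
      "visits total,", x$n_features, "features, lengths",
      min(lens), "-", max(lens), "\n")
  invisible(x)
}

#' Read a long-format visit table from CSV
#'
#' One row per visit; rows are grouped by patient and sorted ascending by the
#' order column (integer visit index or fractional time — only the ordering is
#' used downstream).
#'
#' @param path CSV path.
#' @param id_col patient identifier column.
#' @param order_col visit-order column.
#' @param feature_cols character vector of numeric measurement columns.
#' @return A [visit_sequences()] object. Patients appear in order of first
#'   appearance in the file.
#' @export
read_visit_table <- function(path, id_col = "pid", order_col = "visit",
                             feature_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  visit_table_to_sequences(df, id_col, order_col, feature_cols)
}

#' Convert an in-memory long-format visit table to sequences
#' @param df data.frame, one row per visit.
#' @inheritParams read_visit_table
#' @return A [visit_sequences()].
#' @export
visit_table_to_sequences <- function(df, id_col = "pid", order_col = "visit",
                                     feature_cols) {
  need <- c(id_col, order_col, feature_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("visit table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (fc in feature_cols) {
    if (!is.numeric(df[[fc]])) {
      parsed <- suppressWarnings(as.numeric(df[[fc]]))
      if (anyNA(parsed) && !all(is.na(df[[fc]]) == is.na(parsed))) {
        stop("non-numeric values in feature column '", fc, "'", call. = FALSE)
      }
      df[[fc]] <- parsed
    }
  }
  ids <- as.character(df[[id_col]])
  uid <- unique(ids)
  seqs <- lapply(uid, function(pid) {
    rows <- df[ids == pid, , drop = FALSE]
    rows <- rows[order(rows[[order_col]]), , drop = FALSE]
    m <- as.matrix(rows[, feature_cols, drop = FALSE])
    rownames(m) <- NULL
    m
  })
  names(seqs) <- uid
  visit_sequences(seqs, feature_names = feature_cols)
}

#' Construct a similarity (or distance) matrix
#'
#' Square matrix of pairwise patient scores, indexed by patient id, tagged as
#' either `"similarity"` or `"distance"`.
#'
#' @param m square numeric matrix; dimnames set to patient ids.
#' @param ids patient ids (defaults to rownames of `m`).
#' @param type `"similarity"` or `"distance"`.
#' @return Object of class `psn_matrix`: the matrix with a `psn_type`
#'   attribute.
#' @export
psn_matrix <- function(m, ids = rownames(m),
                       type = c("similarity", "distance")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  if (length(ids) != nrow(m)) {
    stop("ids length does not match matrix dimension", call. = FALSE)
  }
  if (type == "similarity" && any(m < 0, na.rm = TRUE)) {
    stop("similarity-tagged matrix must be nonnegative", call. = FALSE)
  }
  dimnames(m) <- list(ids, ids)
  attr(m, "psn_type") <- type
  class(m) <- c("psn_matrix", class(m))
  m
}

#' @export
print.psn_matrix <- function(x, ...) {
  cat("psn_matrix (", attr(x, "psn_type"), "), ", nrow(x), " x ", ncol(x),
      "\n", sep = "")
  print(unclass_psn(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))),
                       drop = FALSE])
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

unclass_psn <- function(m) {
  attr(m, "psn_type") <- NULL
  class(m) <- setdiff(class(m), "psn_matrix")
  m
}

psn_type <- function(m) attr(m, "psn_type") %||% "similarity"

#' Write a similarity matrix to CSV
#'
#' The CSV carries the patient ids as both header row and first column so a
#' round trip through [read_similarity_matrix()] restores the matrix exactly
#' (to numeric print precision, 1e-12 or better).
#'
#' @param m a `psn_matrix` (or plain matrix with dimnames).
#' @param path output CSV path.
#' @export
write_similarity_matrix <- function(m, path) {
  if (anyNA(m) || any(!is.finite(m))) {
    stop("matrix contains NaN/NA/Inf entries; refusing to write",
         call. = FALSE)
  }
  df <- data.frame(id = rownames(m), format(unclass_psn(m), digits = 17,
                                            scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#' @param path CSV path.
#' @param type semantics tag of the stored matrix.
#' @return A [psn_matrix()].
#' @export
read_similarity_matrix <- function(path, type = c("similarity", "distance")) {
  type <- match.arg(type)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  psn_matrix(m, ids = ids, type = type)
}

#' Export the upper triangle of a PSN as a weighted edge list
#'
#' @param m a `psn_matrix`.
#' @param path output CSV path (columns `id_i,id_j,weight`).
#' @param min_weight drop edges at or below this weight (default 0: zero-weight
#'   edges from KNN pruning are omitted).
#' @export
write_edge_list <- function(m, path, min_weight = 0) {
  ids <- rownames(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  keep <- w > min_weight
  df <- data.frame(id_i = ids[ut[keep, 1]], id_j = ids[ut[keep, 2]],
                   weight = w[keep], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
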