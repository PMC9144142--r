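#' Tokenize a clinical free-text field
#'
#' Line-list style fields ("fever, cough; fatigue") are split on commas,
#' semicolons, and whitespace, lower-cased, and stripped of punctuation.
#'
#' @param text character vector.
#' @return list of character vectors of normalized tokens (may be empty).
#' @export
tokenize_text <- function(text) {
  text <- tolower(as.character(text))
  text[is.na(text)] <- ""
  lapply(strsplit(text, "[,;[:space:]]+"), function(tok) {
    tok <- gsub("[^a-z0-9_]", "", tok)
    tok[nzchar(tok)]
  })
}

#' Fit a bag-of-tokens vocabulary
#'
#' @param texts character vector of training texts (empty strings allowed).
#' @return Object of class `psn_vocabulary`: sorted unique token list plus a
#'   token-to-index map. Fitting is case-insensitive. A vocabulary fitted on a
#'   training fold is frozen: encoding unseen tokens later never grows it.
#' @export
fit_vocabulary <- function(texts) {
  stopifnot(length(texts) >= 1)
  tokens <- sort(unique(unlist(tokenize_text(texts))))
  idx <- seq_along(tokens)
  names(idx) <- tokens
  structure(list(tokens = tokens, index = idx), class = "psn_vocabulary")
}

#' @export
print.psn_vocabulary <- function(x, ...) {
  cat("psn_vocabulary:", length(x$tokens), "tokens\n")
  invisible(x)
}

#' Multi-hot encode a text against a fitted vocabulary
#'
#' Presence indicator (not counts) of each vocabulary token in the text.
#' Out-of-vocabulary tokens are ignored; their count is attached as the
#' `"oov"` attribute.
#'
#' @param text a single character string.
#' @param vocab a fitted [fit_vocabulary()] object.
#' @return binary numeric vector of length `length(vocab$tokens)`.
#' @export
encode_onehot <- function(text, vocab) {
  stopifnot(inherits(vocab, "psn_vocabulary"))
  toks <- unique(tokenize_text(text)[[1]])
  v <- numeric(length(vocab$tokens))
  hit <- vocab$index[toks]
  oov <- sum(is.na(hit))
  hit <- hit[!is.na(hit)]
  v[hit] <- 1
  attr(v, "oov") <- oov
  v
}

#' File-backed embedding adapter
#'
#' Contract for plugging externally computed contextual text embeddings (e.g.
#' from a clinical language model run elsewhere) into the similarity pipeline:
#' a pure function `text -> fixed-length numeric vector`. This constructor
#' builds one from a CSV of precomputed embeddings with columns
#' `text` followed by `dim1..dimD`; texts are matched after normalization.
#'
#' @param path CSV of precomputed embeddings.
#' @param on_missing value for unmatched texts: `"error"` or `"zero"`.
#' @return Object of class `embedder_adapter` with elements `fn(text)` and
#'   `dim`.
#' @export
file_embedder <- function(path, on_missing = c("error", "zero")) {
  on_missing <- match.arg(on_missing)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"text" %in% names(df) || ncol(df) < 2) {
    stop("embedding file needs a 'text' column plus numeric dimensions",
         call. = FALSE)
  }
  keys <- normalize_text_key(df$text)
  emb <- as.matrix(df[, setdiff(names(df), "text"), drop = FALSE])
  storage.mode(emb) <- "double"
  d <- ncol(emb)
  embedder_adapter(function(text) {
    i <- match(normalize_text_key(text), keys)
    if (is.na(i)) {
      if (on_missing == "error") {
        stop("no precomputed embedding for text: ", text, call. = FALSE)
      }
      return(numeric(d))
    }
    emb[i, ]
  }, dim = d)
}

normalize_text_key <- function(text) {
  vapply(tokenize_text(text), paste, character(1), collapse = " ")
}

#' Wrap a function as an embedding adapter
#' @param fn pure function mapping one character string to a numeric vector.
#' @param dim declared embedding dimension.
#' @return `embedder_adapter` object.
#' @export
embedder_adapter <- function(fn, dim) {
  stopifnot(is.function(fn), dim >= 1)
  structure(list(fn = fn, dim = as.integer(dim)), class = "embedder_adapter")
}

encode_text <- function(text, encoder) {
  if (inherits(encoder, "psn_vocabulary")) {
    as.numeric(encode_onehot(text, encoder))
  } else if (inherits(encoder, "embedder_adapter")) {
    v <- encoder$fn(text)
    if (length(v) != encoder$dim) {
      stop("adapter returned length ", length(v), ", declared dim ",
           encoder$dim, call. = FALSE)
    }
    as.numeric(v)
  } else {
    stop("encoder must be a psn_vocabulary or embedder_adapter", call. = FALSE)
  }
}

#' Similarity of two free-text fields
#'
#' Cosine similarity of the two encodings. Two empty encodings (e.g. both
#' patients symptom-free) count as fully similar (1.0). With the built-in
#' multi-hot encoder the score is always in \[0, 1\].
#'
#' @param text_i,text_j character strings.
#' @param encoder a fitted [fit_vocabulary()] or an [embedder_adapter()].
#' @return cosine similarity score.
#' @export
text_field_similarity <- function(text_i, text_j, encoder) {
  vi <- encode_text(text_i, encoder)
  vj <- encode_text(text_j, encoder)
  ni <- sqrt(sum(vi^2)); nj <- sqrt(sum(vj^2))
  if (ni == 0 && nj == 0) return(1)
  if (ni == 0 || nj == 0) return(0)
  sum(vi * vj) / (ni * nj)
}
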