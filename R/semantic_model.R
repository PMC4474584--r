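#' Fit a distributional semantic model of the corpus vocabulary
#'
#' Central fitting function of the package: trains one of six semantic
#' models mapping each vocabulary word to a dense vector of fixed
#' dimensionality.
#'
#' * `"ri-word"` — random indexing over word co-occurrence: each word's
#'   context vector accumulates the (direction-shifted, distance-weighted)
#'   index vectors of its neighbours within a sliding window.
#' * `"ri-note"` — random indexing over note membership: each word
#'   accumulates the index vector of every note it occurs in.
#' * `"ri-icd"` — ICD-10-supervised random indexing: each word in a coded
#'   note accumulates the index vectors of the note's primary code and of
#'   all its taxonomy ancestors, the weight halving per step upward.
#' * `"ri-index"` — the sparse random index vectors themselves, densified
#'   (a randomized bag-of-words projection; no training).
#' * `"w2v"` — CBOW word2vec with a hierarchical soft-max output layer.
#' * `"w2v-icd"` — word2vec variant predicting the weighted ICD-10 code
#'   segments of the note containing each input word.
#'
#' @param corpus A preprocessed `care_corpus`.
#' @param method Model type; see Details.
#' @param config An [ri_config()] (RI methods) or [w2v_config()] (word2vec
#'   methods); defaults follow the method's standard settings.
#' @param ... Passed to the default config constructor when `config` is
#'   `NULL` (e.g. `dim`, `seed`).
#' @return An object of class `semantic_model` with elements `method`,
#'   `vectors` (words x dim matrix), `config`, `vocab` and `skipped`
#'   (diagnostic counts, e.g. notes skipped for missing codes).
#' @seealso [apply_weighting()] to produce retrieval-ready vectors,
#'   [write_embeddings()] for the plain-text export.
#' @export
semantic_model <- function(corpus,
                           method = c("ri-word", "ri-note", "ri-icd",
                                      "ri-index", "w2v", "w2v-icd"),
                           config = NULL, ...) {
  method <- match.arg(method)
  if (is.null(config)) {
    config <- switch(method,
      "w2v" = w2v_config(epochs = 5L, initial_lr = 0.025, ...),
      "w2v-icd" = w2v_config(epochs = 10L, initial_lr = 0.04, ...),
      ri_config(...))
  }
  expected <- if (method %in% c("w2v", "w2v-icd")) "w2v_config" else "ri_config"
  if (!inherits(config, expected))
    stop("method '", method, "' needs a ", expected)
  fit <- switch(method,
    "ri-word"  = train_ri_word(corpus, config),
    "ri-note"  = train_ri_note(corpus, config),
    "ri-icd"   = train_ri_icd(corpus, config),
    "ri-index" = train_ri_index(corpus, config),
    "w2v"      = train_w2v_cbow(corpus, config),
    "w2v-icd"  = train_w2v_icd(corpus, config))
  structure(list(method = method, vectors = fit$vectors, config = config,
                 vocab = fit$vocab, skipped = fit$skipped, hs = fit$hs),
            class = "semantic_model")
}

#' @export
print.semantic_model <- function(x, ...) {
  cat("<semantic_model> method=", x$method, ", ", nrow(x$vectors),
      " words x ", ncol(x$vectors), " dims\n", sep = "")
  invisible(x)
}

#' @export
summary.semantic_model <- function(object, ...) {
  norms <- sqrt(rowSums(object$vectors^2))
  out <- list(method = object$method, n_words = nrow(object$vectors),
              dim = ncol(object$vectors),
              norm_range = range(norms),
              skipped = object$skipped)
  class(out) <- "summary.semantic_model"
  out
}

#' @export
print.summary.semantic_model <- function(x, ...) {
  cat("Semantic model (", x$method, ")\n", sep = "")
  cat("  vocabulary: ", x$n_words, " words, dimensionality ", x$dim, "\n",
      sep = "")
  if (x$n_words)
    cat("  context-vector norms: ", format(x$norm_range[1], digits = 4),
        " .. ", format(x$norm_range[2], digits = 4), "\n", sep = "")
  if (length(x$skipped))
    for (nm in names(x$skipped))
      cat("  skipped ", nm, ": ", x$skipped[[nm]], "\n", sep = "")
  invisible(x)
}

#' @export
coef.semantic_model <- function(object, ...) object$vectors

#' Look up word vectors
#'
#' @param object A `semantic_model` (or `weighted_model`).
#' @param newdata Character vector of words.
#' @param ... Unused.
#' @return Matrix with one row per word; out-of-vocabulary words give
#'   all-`NA` rows.
#' @export
predict.semantic_model <- function(object, newdata, ...) {
  idx <- match(newdata, rownames(object$vectors))
  out <- object$vectors[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  out[is.na(idx), ] <- NA_real_
  rownames(out) <- newdata
  out
}

#' Export word vectors in the plain-text word2vec format
#'
#' First line `"<n_words> <dim>"`, then one `"word v1 ... vDim"` line per
#' word, for interoperability with standard embedding tooling.
#'
#' @param model A `semantic_model` or `weighted_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  m <- model$vectors
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i],
                     paste(sprintf("%.17g", m[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Read word vectors from the plain-text word2vec format
#'
#' @param path Path to a file written by [write_embeddings()] or any
#'   word2vec-text-format exporter.
#' @param weighted If `TRUE` the vectors are treated as already
#'   retrieval-ready and returned as a `weighted_model`.
#' @return A `semantic_model` (method `"imported"`) or `weighted_model`.
#' @export
read_embeddings <- function(path, weighted = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  n <- hdr[1L]; d <- hdr[2L]
  parts <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1L)
  m <- matrix(0, n, d, dimnames = list(words, NULL))
  for (i in seq_len(n)) m[i, ] <- as.numeric(parts[[i]][-1L])
  if (weighted)
    structure(list(vectors = m, method = "imported", weighting = "imported",
                   boost = NA_real_),
              class = "weighted_model")
  else
    structure(list(method = "imported", vectors = m, config = NULL,
                   vocab = NULL, skipped = list()),
              class = "semantic_model")
}
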