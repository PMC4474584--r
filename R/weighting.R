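#' Inverse document frequency over clinical notes
#'
#' `idf(w) = log(N / df(w))` with document frequency counted over notes, so
#' words occurring in few notes get more weight and words present in every
#' note are zeroed out. An alternative smoothed form `log(1 + N/df)` is
#' available.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param scheme `"ln"` (default) or `"ln1p"` for `log(1 + N/df)`.
#' @return Named numeric vector of IDF weights.
#' @export
compute_idf <- function(vocab, scheme = c("ln", "ln1p")) {
  scheme <- match.arg(scheme)
  if (vocab$n_notes < 1L) stop("vocabulary covers no notes")
  ratio <- vocab$n_notes / vocab$df
  stats::setNames(if (scheme == "ln") log(ratio) else log1p(ratio),
                  names(vocab$df))
}

#' Metathesaurus term list
#'
#' Curated health-vocabulary terms whose IDF weight is boosted (doubled by
#' default) during word-vector weighting.
#'
#' @param terms Character vector of lowercase terms.
#' @param boost Multiplicative boost factor (> 0).
#' @return An object of class `metathesaurus`.
#' @export
metathesaurus <- function(terms, boost = 2.0) {
  stopifnot(boost > 0)
  structure(list(terms = unique(tolower(terms)), boost = boost),
            class = "metathesaurus")
}

#' Weight a semantic model for retrieval
#'
#' Each context vector is unit-normalized and multiplied by the word's IDF;
#' words found in a metathesaurus additionally get their IDF multiplied by
#' the boost factor (the IDF*Metathesaurus scheme). Words with a zero
#' context vector stay zero (counted in `zero_vectors`). Re-weighting an
#' already weighted model is rejected.
#'
#' @param model A `semantic_model`.
#' @param idf Named IDF vector from [compute_idf()]; must cover the model
#'   vocabulary.
#' @param thesaurus Optional [metathesaurus()]; `NULL` gives plain IDF
#'   weighting.
#' @return An object of class `weighted_model`: `vectors`, `method`,
#'   `weighting` (`"idf"` or `"idf_meta"`), `boost`, `zero_vectors`.
#' @export
apply_weighting <- function(model, idf, thesaurus = NULL) {
  if (inherits(model, "weighted_model"))
    stop("model is already weighted; re-weighting is not allowed")
  stopifnot(inherits(model, "semantic_model"))
  words <- rownames(model$vectors)
  if (!length(words)) stop("cannot weight an empty model")
  missing_idf <- setdiff(words, names(idf))
  if (length(missing_idf))
    stop("no IDF weight for word(s): ",
         paste(utils::head(missing_idf, 5L), collapse = ", "))
  w <- unname(idf[words])
  if (!is.null(thesaurus)) {
    stopifnot(inherits(thesaurus, "metathesaurus"))
    w <- w * ifelse(words %in% thesaurus$terms, thesaurus$boost, 1)
  }
  norms <- sqrt(rowSums(model$vectors^2))
  zero <- norms == 0
  if (any(zero))
    warning(sum(zero), " word(s) with zero context vectors map to zero")
  scale <- ifelse(zero, 0, w / ifelse(zero, 1, norms))
  structure(list(vectors = model$vectors * scale,
                 method = model$method,
                 weighting = if (is.null(thesaurus)) "idf" else "idf_meta",
                 boost = if (is.null(thesaurus)) 1 else thesaurus$boost,
                 zero_vectors = sum(zero)),
            class = "weighted_model")
}

#' @export
print.weighted_model <- function(x, ...) {
  cat("<weighted_model> ", x$method, " + ", x$weighting, ", ",
      nrow(x$vectors), " words x ", ncol(x$vectors), " dims\n", sep = "")
  invisible(x)
}

#' @export
predict.weighted_model <- function(object, newdata, ...) {
  predict.semantic_model(object, newdata, ...)
}
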