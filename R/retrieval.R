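new_ranked_list <- function(query_id, ids, scores, provenance = "") {
  ord <- order(is.na(scores), -ifelse(is.na(scores), -Inf, scores), ids)
  structure(data.frame(episode_id = ids[ord], score = scores[ord],
                       stringsAsFactors = FALSE),
            query_id = query_id, provenance = provenance,
            class = c("ranked_list", "data.frame"))
}

#' Rank a collection of care episodes against a query
#'
#' Scores every collection episode (the query itself excluded) with the
#' chosen episode-similarity scheme and returns the descending ranking, ties
#' broken by ascending episode id. Undefined similarities (episodes with no
#' in-vocabulary text) are ranked last.
#'
#' @param query A query `care_episode` (see [build_query_episode()]).
#' @param collection A `care_corpus` (or list of episodes).
#' @param scheme `"single"`, `"avg"`, `"ha"` or `"nw"`.
#' @param wm A `weighted_model`.
#' @param limit Optional truncation of the returned list.
#' @param episode_matrix Optional precomputed matrix of pooled collection
#'   episode vectors (rows named by episode id) to accelerate `"single"`.
#' @return A `ranked_list` data frame with columns `episode_id`, `score`.
#' @export
rank_collection <- function(query, collection, scheme = "single", wm,
                            limit = NULL, episode_matrix = NULL) {
  ids <- vapply(collection, `[[`, character(1), "episode_id")
  keep <- ids != query$episode_id
  collection <- collection[keep]; ids <- ids[keep]
  if (!length(ids))
    return(new_ranked_list(query$episode_id, character(0), numeric(0),
                           scheme))
  if (scheme == "single" && !is.null(episode_matrix)) {
    qv <- episode_vector(query, wm)
    if (attr(qv, "n_tokens") == 0L) {
      scores <- rep(NA_real_, length(ids))
    } else {
      M <- episode_matrix[ids, , drop = FALSE]
      nq <- sqrt(sum(qv^2))
      nm <- sqrt(rowSums(M^2))
      scores <- as.numeric(M %*% qv) / (nq * nm)
      scores[nm == 0] <- NA_real_
    }
  } else {
    scores <- vapply(collection, function(ep)
      episode_similarity(query, ep, scheme, wm), numeric(1))
  }
  rl <- new_ranked_list(query$episode_id, ids, scores, scheme)
  if (!is.null(limit) && nrow(rl) > limit) {
    att <- attributes(rl)
    rl <- rl[seq_len(limit), ]
    attr(rl, "query_id") <- att$query_id
    attr(rl, "provenance") <- att$provenance
    class(rl) <- c("ranked_list", "data.frame")
  }
  rl
}

#' Precompute pooled episode vectors for a collection
#'
#' @param collection A `care_corpus`.
#' @param wm A `weighted_model`.
#' @param include_summary Include discharge-summary text.
#' @return Matrix (episodes x dim) with episode ids as row names.
#' @export
collection_episode_matrix <- function(collection, wm,
                                      include_summary = TRUE) {
  ids <- vapply(collection, `[[`, character(1), "episode_id")
  M <- t(vapply(collection, function(ep)
    as.numeric(episode_vector(ep, wm, include_summary)),
    numeric(ncol(wm$vectors))))
  rownames(M) <- ids
  M
}

# --- TF-IDF vector-space baseline -----------------------------------------

#' TF-IDF vector-space retrieval baseline
#'
#' Exact sparse bag-of-words ranking: each episode's concatenated text
#' becomes a TF x IDF vector (IDF over clinical notes, as elsewhere in the
#' package) and candidates are ranked by cosine against the query vector.
#' This is the bespoke stand-in for a search-engine baseline; no random
#' projection is involved.
#'
#' @param collection A `care_corpus` used to fit the vocabulary and IDF.
#' @param include_summary Include summary text on the collection side.
#' @return A ranker object of class `tfidf_ranker` usable with
#'   [tfidf_baseline_rank()] and the experiment drivers.
#' @export
tfidf_ranker <- function(collection, include_summary = TRUE) {
  vocab <- build_vocabulary(collection)
  idf <- compute_idf(vocab)
  ids <- vapply(collection, `[[`, character(1), "episode_id")
  tf <- lapply(collection, function(ep)
    table(episode_tokens(ep, include_summary)))
  trip <- do.call(rbind, lapply(seq_along(tf), function(i) {
    w <- match(names(tf[[i]]), vocab$words)
    ok <- !is.na(w)
    cbind(i, w[ok], as.integer(tf[[i]])[ok])
  }))
  M <- Matrix::sparseMatrix(i = trip[, 1L], j = trip[, 2L], x = trip[, 3L],
                            dims = c(length(ids), length(vocab$words)))
  M <- M %*% Matrix::Diagonal(x = unname(idf[vocab$words]))
  structure(list(vocab = vocab, idf = idf, ids = ids, matrix = M,
                 norms = sqrt(Matrix::rowSums(M^2))),
            class = "tfidf_ranker")
}

tfidf_vector <- function(rk, tokens) {
  tf <- table(tokens)
  w <- match(names(tf), rk$vocab$words)
  ok <- !is.na(w)
  v <- numeric(length(rk$vocab$words))
  v[w[ok]] <- as.integer(tf)[ok] * unname(rk$idf[rk$vocab$words[w[ok]]])
  v
}

#' @rdname tfidf_ranker
#' @param rk A `tfidf_ranker`.
#' @param query Query `care_episode`.
#' @param limit Optional truncation.
#' @export
tfidf_baseline_rank <- function(rk, query, limit = NULL) {
  qv <- tfidf_vector(rk, episode_tokens(query))
  keep <- rk$ids != query$episode_id
  M <- rk$matrix[keep, , drop = FALSE]
  norms <- rk$norms[keep]
  nq <- sqrt(sum(qv^2))
  scores <- if (nq == 0) rep(0, sum(keep))
            else as.numeric(M %*% qv) / pmax(norms * nq, .Machine$double.eps)
  scores[norms == 0] <- 0
  rl <- new_ranked_list(query$episode_id, rk$ids[keep], scores, "tfidf")
  if (!is.null(limit) && nrow(rl) > limit) rl <- utils::head(rl, limit)
  rl
}

# --- random baseline ------------------------------------------------------

#' Random retrieval baseline
#'
#' Seeded uniform random permutation of the non-query episodes; a sanity
#' check lower bound for the evaluation protocols.
#'
#' @param query Query `care_episode`.
#' @param collection A `care_corpus`.
#' @param seed Integer seed.
#' @return A `ranked_list`.
#' @export
random_rank <- function(query, collection, seed = 1L) {
  ids <- vapply(collection, `[[`, character(1), "episode_id")
  ids <- ids[ids != query$episode_id]
  with_preserved_rng({
    set.seed(seed)
    perm <- sample.int(length(ids))
  })
  ord_ids <- ids[perm]
  scores <- if (length(ids)) rev(seq_along(ids)) / length(ids) else numeric(0)
  structure(data.frame(episode_id = ord_ids, score = scores,
                       stringsAsFactors = FALSE),
            query_id = query$episode_id, provenance = "random",
            class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, n = 10L, ...) {
  cat("<ranked_list> query=", attr(x, "query_id"), " (",
      attr(x, "provenance"), "), ", nrow(x), " episodes\n", sep = "")
  print.data.frame(utils::head(x, n))
  invisible(x)
}
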