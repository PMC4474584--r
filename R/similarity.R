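#' Cosine similarity
#'
#' Defined as 0 when either vector is zero.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Score in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Note and episode vectors
#'
#' A note vector is the sum of the weighted word vectors of all token
#' occurrences in the note (repeated words count repeatedly); an episode
#' vector is the sum over all its notes' tokens divided by the number of
#' contributing occurrences. Out-of-vocabulary tokens are skipped.
#'
#' @param note A `clinical_note`; `ep` a `care_episode`.
#' @param wm A `weighted_model`.
#' @return Numeric vector of the model dimensionality; attribute `n_tokens`
#'   holds the number of contributing token occurrences.
#' @export
note_vector <- function(note, wm) {
  pooled_vector(note_tokens(note), wm, mean = FALSE)
}

#' @rdname note_vector
#' @param include_summary Include the discharge summary's text (episode
#'   vectors for retrieval of full collection episodes) or not (query side).
#' @export
episode_vector <- function(ep, wm, include_summary = TRUE) {
  pooled_vector(episode_tokens(ep, include_summary), wm, mean = TRUE)
}

pooled_vector <- function(tokens, wm, mean = FALSE) {
  idx <- match(tokens, rownames(wm$vectors))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    out <- numeric(ncol(wm$vectors))
    attr(out, "n_tokens") <- 0L
    return(out)
  }
  out <- colSums(wm$vectors[idx, , drop = FALSE])
  if (mean) out <- out / length(idx)
  attr(out, "n_tokens") <- length(idx)
  out
}

# note-by-note cosine matrix between two episodes
note_cosine_matrix <- function(A, B, wm) {
  va <- lapply(A$notes, note_vector, wm = wm)
  vb <- lapply(B$notes, note_vector, wm = wm)
  S <- matrix(0, length(va), length(vb))
  for (i in seq_along(va)) for (j in seq_along(vb))
    S[i, j] <- cosine(va[[i]], vb[[j]])
  S
}

#' Episode similarity schemes
#'
#' Four ways of scoring the similarity of two care episodes from their
#' weighted word vectors:
#'
#' * `single_sim` — cosine between the two pooled episode vectors.
#' * `avg_sim` — mean cosine over all note pairs of the two episodes.
#' * `ha_sim` — optimal one-to-one note assignment (Hungarian algorithm)
#'   maximizing the summed note cosines; pairs with non-positive similarity
#'   are left unmatched. Score `2 * sum / (|A| + |B|)`, which penalizes
#'   length mismatch.
#' * `nw_sim` — order-preserving global note alignment (Needleman-Wunsch,
#'   gap contribution 0, match score = cosine); scored with the same
#'   `2 * sum / (|A| + |B|)` formula over the aligned pairs.
#'
#' `single_sim` returns `NA` (an undefined similarity, ranked last) when
#' either episode has no in-vocabulary token.
#'
#' @param A,B `care_episode` objects.
#' @param wm A `weighted_model`.
#' @return A similarity score; for `ha_sim`/`nw_sim` the attribute
#'   `pairing` holds the matched note index pairs.
#' @export
single_sim <- function(A, B, wm) {
  va <- episode_vector(A, wm); vb <- episode_vector(B, wm)
  if (attr(va, "n_tokens") == 0L || attr(vb, "n_tokens") == 0L)
    return(NA_real_)
  cosine(va, vb)
}

#' @rdname single_sim
#' @export
avg_sim <- function(A, B, wm) {
  mean(note_cosine_matrix(A, B, wm))
}

#' @rdname single_sim
#' @export
ha_sim <- function(A, B, wm) {
  ha_score(note_cosine_matrix(A, B, wm))
}

#' @rdname single_sim
#' @export
nw_sim <- function(A, B, wm) {
  nw_score(note_cosine_matrix(A, B, wm))
}

# Assignment score on a raw similarity matrix. Maximum-weight one-to-one
# matching; non-positive entries never pay, realizing the same "align with
# zero or one notes" semantics as the gap-0 alignment.
ha_score <- function(S) {
  n <- nrow(S); m <- ncol(S)
  Sp <- pmax(S, 0)
  transposed <- n > m
  M <- if (transposed) t(Sp) else Sp
  sol <- clue::solve_LSAP(M, maximum = TRUE)
  rows <- seq_len(nrow(M)); cols <- as.integer(sol)
  keep <- M[cbind(rows, cols)] > 0
  pairs <- cbind(rows[keep], cols[keep])
  if (transposed) pairs <- pairs[, 2:1, drop = FALSE]
  total <- sum(S[pairs])
  structure(2 * total / (n + m), pairing = pairs)
}

# Needleman-Wunsch alignment score with gap contribution 0: the best
# strictly order-preserving partial matching of the two note sequences.
nw_score <- function(S) {
  n <- nrow(S); m <- ncol(S)
  F <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    F[i + 1L, j + 1L] <- max(F[i, j] + S[i, j], F[i, j + 1L], F[i + 1L, j])
  }
  # traceback (informational pairing)
  pairs <- NULL
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (F[i + 1L, j + 1L] == F[i, j] + S[i, j] && S[i, j] > 0) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (F[i + 1L, j + 1L] == F[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  structure(2 * F[n + 1L, m + 1L] / (n + m), pairing = pairs)
}

episode_similarity <- function(A, B, scheme, wm) {
  switch(scheme,
         single = single_sim(A, B, wm),
         avg = avg_sim(A, B, wm),
         ha = as.numeric(ha_sim(A, B, wm)),
         nw = as.numeric(nw_sim(A, B, wm)),
         stop("unknown similarity scheme '", scheme, "'"))
}
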