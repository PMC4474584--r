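# Internal tokenized view of a corpus: one integer vector of word ids per
# sentence, plus per-note groupings. Word ids index vocab$words.
corpus_token_ids <- function(corpus, vocab) {
  sentences <- list()
  note_tok <- list()
  note_keys <- character(0)
  note_codes <- list()
  si <- 0L; ni <- 0L
  for (ep in corpus) for (nt in ep$notes) {
    ni <- ni + 1L
    ids_all <- integer(0)
    for (s in nt$sentences) {
      si <- si + 1L
      ids <- unname(vocab$id[s])
      sentences[[si]] <- ids
      ids_all <- c(ids_all, ids)
    }
    note_tok[[ni]] <- ids_all
    note_keys[ni] <- paste0(ep$episode_id, "|", nt$note_id)
    note_codes[[ni]] <- if (is.null(ep$primary_icd)) NA_character_
                        else ep$primary_icd
  }
  list(sentences = sentences, note_tok = note_tok, note_keys = note_keys,
       note_codes = unlist(note_codes, use.names = FALSE))
}

empty_model_matrix <- function(dim) {
  matrix(numeric(0), nrow = 0L, ncol = dim,
         dimnames = list(character(0), NULL))
}

train_ri_word <- function(corpus, cfg) {
  vocab <- build_vocabulary(corpus)
  V <- length(vocab$words)
  if (V == 0L) return(list(vectors = empty_model_matrix(cfg$dim),
                           vocab = vocab, skipped = list()))
  tk <- corpus_token_ids(corpus, vocab)
  toks <- unlist(tk$sentences, use.names = FALSE)
  sid <- rep(seq_along(tk$sentences), lengths(tk$sentences))
  I <- index_matrix(paste0("w|", vocab$words), cfg)
  IL <- if (cfg$use_direction_shift) rotate_columns(I, "left") else I
  IR <- if (cfg$use_direction_shift) rotate_columns(I, "right") else I
  C <- matrix(0, V, cfg$dim)
  n <- length(toks)
  for (d in seq_len(cfg$window)) {
    if (n <= d) break
    i <- seq_len(n - d)
    ok <- sid[i] == sid[i + d]
    if (!any(ok)) next
    a <- toks[i][ok]          # earlier token
    b <- toks[i + d][ok]      # later token, i.e. right neighbour of a
    w <- cfg$distance_weight_base ^ (1 - d)
    # focus a sees b on its right; focus b sees a on its left
    Pr <- Matrix::sparseMatrix(i = a, j = b, x = 1, dims = c(V, V))
    Pl <- Matrix::sparseMatrix(i = b, j = a, x = 1, dims = c(V, V))
    C <- C + w * as.matrix(Pr %*% IR) + w * as.matrix(Pl %*% IL)
  }
  rownames(C) <- vocab$words
  list(vectors = C, vocab = vocab, skipped = list())
}

train_ri_note <- function(corpus, cfg) {
  vocab <- build_vocabulary(corpus)
  V <- length(vocab$words)
  if (V == 0L) return(list(vectors = empty_model_matrix(cfg$dim),
                           vocab = vocab, skipped = list()))
  tk <- corpus_token_ids(corpus, vocab)
  counts <- note_word_counts(tk, V)
  Inote <- index_matrix(paste0("n|", tk$note_keys), cfg)
  C <- as.matrix(Matrix::crossprod(counts, Inote))
  rownames(C) <- vocab$words
  list(vectors = C, vocab = vocab, skipped = list())
}

train_ri_icd <- function(corpus, cfg) {
  vocab <- build_vocabulary(corpus)
  V <- length(vocab$words)
  tk <- corpus_token_ids(corpus, vocab)
  coded <- !is.na(tk$note_codes)
  if (!any(coded))
    stop("no episodes with a primary ICD-10 code; cannot train the ",
         "ICD-supervised random-indexing model")
  counts <- note_word_counts(tk, V)[coded, , drop = FALSE]
  codes <- tk$note_codes[coded]
  seg_tabs <- lapply(unique(codes), function(cd) segment_icd(cd)$segments)
  names(seg_tabs) <- unique(codes)
  segments <- sort(unique(unlist(lapply(seg_tabs, `[[`, "segment"))))
  Iseg <- index_matrix(paste0("c|", segments), cfg)
  # note x segment weight matrix, then composite code vectors per note
  trip <- do.call(rbind, lapply(seq_along(codes), function(ni) {
    st <- seg_tabs[[codes[ni]]]
    cbind(ni, match(st$segment, segments), st$weight)
  }))
  W <- Matrix::sparseMatrix(i = trip[, 1L], j = trip[, 2L], x = trip[, 3L],
                            dims = c(length(codes), length(segments)))
  C <- as.matrix(Matrix::crossprod(counts, W %*% Iseg))
  rownames(C) <- vocab$words
  list(vectors = C, vocab = vocab,
       skipped = list(uncoded_notes = sum(!coded)))
}

train_ri_index <- function(corpus, cfg) {
  vocab <- build_vocabulary(corpus)
  if (!length(vocab$words))
    return(list(vectors = empty_model_matrix(cfg$dim), vocab = vocab,
                skipped = list()))
  C <- as.matrix(index_matrix(paste0("w|", vocab$words), cfg))
  rownames(C) <- vocab$words
  list(vectors = C, vocab = vocab, skipped = list())
}

note_word_counts <- function(tk, V) {
  nid <- rep(seq_along(tk$note_tok), lengths(tk$note_tok))
  wid <- unlist(tk$note_tok, use.names = FALSE)
  Matrix::sparseMatrix(i = nid, j = wid, x = 1,
                       dims = c(length(tk$note_tok), V))
}
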