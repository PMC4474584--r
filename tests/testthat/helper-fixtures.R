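# Shared builders for tiny in-code corpora.

mk_note <- function(eid, pos, sentences, summary = FALSE)
  clinical_note(sprintf("%s-n%02d", eid, pos + 1L), eid, pos,
                sentences, is_summary = summary)

# episode from a list of sentence-lists; last note flagged summary on request
mk_ep <- function(id, notes_sentences, code = NULL, summary_last = FALSE) {
  n <- length(notes_sentences)
  notes <- lapply(seq_len(n), function(i)
    mk_note(id, i - 1L, notes_sentences[[i]],
            summary = summary_last && i == n))
  care_episode(id, notes, code)
}

mk_corpus <- function(...) {
  eps <- list(...)
  asNamespace("epiretrieve")$new_care_corpus(eps)
}

# one-sentence-per-note shorthand: each element a token vector
mk_ep1 <- function(id, note_tokens, code = NULL, summary_last = FALSE)
  mk_ep(id, lapply(note_tokens, list), code, summary_last)

fx_corpus <- generate_fixture_small()

fx_weighted <- function(method = "ri-index", dim = 200L, seed = 3L,
                        thesaurus = NULL) {
  cfg <- if (method %in% c("w2v", "w2v-icd"))
    w2v_config(dim = dim, seed = seed) else ri_config(dim = dim, seed = seed)
  m <- semantic_model(fx_corpus, method, config = cfg)
  idf <- compute_idf(build_vocabulary(fx_corpus))
  suppressWarnings(apply_weighting(m, idf, thesaurus))
}

# random similarity-like matrices with entries in [-1, 1]
random_sim_matrix <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1), nr, nc)
}

# small random episodes with dense random note vectors, via a fake weighted
# model whose vocabulary is one word per note
random_vector_episodes <- function(n_notes_a, n_notes_b, dim = 8L) {
  words <- paste0("t", seq_len(n_notes_a + n_notes_b))
  vecs <- matrix(stats::rnorm(length(words) * dim), ncol = dim,
                 dimnames = list(words, NULL))
  wm <- structure(list(vectors = vecs, method = "synthetic",
                       weighting = "idf", boost = 1),
                  class = "weighted_model")
  A <- mk_ep1("A", lapply(seq_len(n_notes_a), function(i) words[i]))
  B <- mk_ep1("B", lapply(seq_len(n_notes_b), function(i)
    words[n_notes_a + i]))
  list(A = A, B = B, wm = wm)
}
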