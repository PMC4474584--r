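# Initialization: input vectors uniform in (-0.5/dim, +0.5/dim), internal
# hierarchical-soft-max node weights zero.
init_syn0 <- function(dim, V, seed) {
  with_preserved_rng({
    set.seed(seed)
    matrix(stats::runif(dim * V, -0.5, 0.5) / dim, nrow = dim, ncol = V)
  })
}

train_w2v_cbow <- function(corpus, cfg) {
  vocab <- build_vocabulary(corpus)
  V <- length(vocab$words)
  if (V == 0L) stop("cannot train word2vec on an empty corpus")
  tk <- corpus_token_ids(corpus, vocab)
  tree <- build_huffman(stats::setNames(vocab$tf, vocab$words))
  stopifnot(identical(tree$leaves, vocab$words))
  syn0 <- init_syn0(cfg$dim, V, cfg$seed)
  syn1 <- matrix(0, cfg$dim, tree$n_internal)
  cpp_cbow_train(tk$sentences, unname(tree$codes), unname(tree$points),
                 syn0, syn1, cfg$window, cfg$epochs,
                 cfg$initial_lr, cfg$min_lr)
  vectors <- t(syn0)
  rownames(vectors) <- vocab$words
  list(vectors = vectors, vocab = vocab,
       skipped = list(),
       hs = list(tree = tree, syn1 = syn1, sentences = tk$sentences))
}

# Per-epoch CBOW training with the global linear learning-rate schedule,
# evaluating the mean path negative log-likelihood after each epoch.
cbow_train_epoch_losses <- function(corpus, cfg) {
  vocab <- build_vocabulary(corpus)
  tk <- corpus_token_ids(corpus, vocab)
  tree <- build_huffman(stats::setNames(vocab$tf, vocab$words))
  syn0 <- init_syn0(cfg$dim, length(vocab$words), cfg$seed)
  syn1 <- matrix(0, cfg$dim, tree$n_internal)
  n_tok <- sum(lengths(tk$sentences))
  total <- n_tok * cfg$epochs
  losses <- numeric(cfg$epochs + 1L)
  losses[1L] <- cpp_cbow_loss(tk$sentences, unname(tree$codes),
                              unname(tree$points), syn0, syn1, cfg$window)
  for (e in seq_len(cfg$epochs)) {
    cpp_cbow_train(tk$sentences, unname(tree$codes), unname(tree$points),
                   syn0, syn1, cfg$window, 1L, cfg$initial_lr, cfg$min_lr,
                   processed0 = (e - 1L) * n_tok, total_sched = total)
    losses[e + 1L] <- cpp_cbow_loss(tk$sentences, unname(tree$codes),
                                    unname(tree$points), syn0, syn1,
                                    cfg$window)
  }
  losses
}

# Training pairs for the ICD-segment-target variant: every token of a coded
# note is trained against every taxonomy segment of the note's primary code,
# the gradient scaled by the segment weight. Segment Huffman frequencies are
# token-weighted pair counts.
icd_training_data <- function(corpus, vocab) {
  tk <- corpus_token_ids(corpus, vocab)
  coded <- !is.na(tk$note_codes)
  if (!any(coded))
    stop("no episodes with a primary ICD-10 code; cannot train the ",
         "ICD-segment-target word2vec model")
  toks <- tk$note_tok[coded]
  codes <- tk$note_codes[coded]
  seg_tabs <- lapply(unique(codes), function(cd) segment_icd(cd)$segments)
  names(seg_tabs) <- unique(codes)
  segfreq <- list()
  for (i in seq_along(codes)) {
    st <- seg_tabs[[codes[i]]]
    n <- length(toks[[i]])
    for (s in st$segment)
      segfreq[[s]] <- (if (is.null(segfreq[[s]])) 0 else segfreq[[s]]) + n
  }
  list(note_tok = toks, codes = codes, seg_tabs = seg_tabs,
       segfreq = unlist(segfreq), n_uncoded = sum(!coded))
}

train_w2v_icd <- function(corpus, cfg) {
  vocab <- build_vocabulary(corpus)
  V <- length(vocab$words)
  if (V == 0L) stop("cannot train word2vec on an empty corpus")
  td <- icd_training_data(corpus, vocab)
  tree <- build_huffman(td$segfreq)
  note_segs <- lapply(td$codes, function(cd)
    match(td$seg_tabs[[cd]]$segment, tree$leaves))
  note_segw <- lapply(td$codes, function(cd) td$seg_tabs[[cd]]$weight)
  syn0 <- init_syn0(cfg$dim, V, cfg$seed)
  syn1 <- matrix(0, cfg$dim, tree$n_internal)
  cpp_icd_train(td$note_tok, note_segs, note_segw,
                unname(tree$codes), unname(tree$points),
                syn0, syn1, cfg$epochs, cfg$initial_lr, cfg$min_lr)
  vectors <- t(syn0)
  rownames(vectors) <- vocab$words
  list(vectors = vectors, vocab = vocab,
       skipped = list(uncoded_notes = td$n_uncoded),
       hs = list(tree = tree, syn1 = syn1))
}
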