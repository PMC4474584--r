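ns <- asNamespace("epiretrieve")

two_code_corpus <- function(seed, lambda = 0.8) {
  generate_corpus(synth_config(
    n_codes = 2, n_chapters = 2, episodes_per_code = 6, lambda = lambda,
    vocab_background = 80, topic_words_per_node = 10,
    active_topic_words = NULL, notes_per_episode = c(3, 5),
    tokens_per_note = c(15, 25), icd_mention_prob = 0, seed = seed))
}

mean_code_cosines <- function(model, gen) {
  V <- coef(model)
  lex <- lapply(gen$code_table$code, ns$node_lexicon,
                n = gen$config$topic_words_per_node)
  w1 <- intersect(lex[[1]], rownames(V))
  w2 <- intersect(lex[[2]], rownames(V))
  cosm <- function(a, b) {
    A <- V[a, , drop = FALSE] / sqrt(rowSums(V[a, , drop = FALSE]^2))
    B <- V[b, , drop = FALSE] / sqrt(rowSums(V[b, , drop = FALSE]^2))
    M <- A %*% t(B)
    if (identical(a, b)) mean(M[upper.tri(M)]) else mean(M)
  }
  c(within = (cosm(w1, w1) + cosm(w2, w2)) / 2, cross = cosm(w1, w2))
}

test_that("zero learning rate leaves the embeddings at initialization", {
  g <- two_code_corpus(1)
  m <- semantic_model(g$corpus, "w2v",
                      config = w2v_config(dim = 24, epochs = 2,
                                          initial_lr = 0, min_lr = 0,
                                          seed = 5))
  init <- t(ns$init_syn0(24, nrow(coef(m)), 5L))
  expect_equal(unname(coef(m)), unname(init))
})

test_that("training is bit-stable for a fixed seed", {
  g <- two_code_corpus(2)
  cfg <- w2v_config(dim = 24, epochs = 2, seed = 9)
  m1 <- semantic_model(g$corpus, "w2v", config = cfg)
  m2 <- semantic_model(g$corpus, "w2v", config = cfg)
  expect_identical(coef(m1), coef(m2))
  icfg <- w2v_config(dim = 24, epochs = 3, initial_lr = 0.04, seed = 9)
  i1 <- semantic_model(g$corpus, "w2v-icd", config = icfg)
  i2 <- semantic_model(g$corpus, "w2v-icd", config = icfg)
  expect_identical(coef(i1), coef(i2))
})

test_that("the CBOW objective is non-increasing across epochs", {
  g <- two_code_corpus(3)
  losses <- ns$cbow_train_epoch_losses(
    g$corpus, w2v_config(dim = 40, epochs = 5, initial_lr = 0.05, seed = 1))
  for (e in seq_len(length(losses) - 1L))
    expect_lte(losses[e + 1L], losses[e] * 1.05)
  expect_lt(losses[length(losses)], losses[1L])
})

test_that("CBOW separates the topics of a two-code corpus", {
  wins <- 0L
  for (s in 1:3) {
    g <- two_code_corpus(s)
    m <- semantic_model(g$corpus, "w2v",
                        config = w2v_config(dim = 60, epochs = 5,
                                            initial_lr = 0.05, seed = s))
    cc <- mean_code_cosines(m, g)
    if (cc["within"] > cc["cross"]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("ICD-target training uses the halving update scales", {
  g <- two_code_corpus(4)
  td <- ns$icd_training_data(g$corpus, build_vocabulary(g$corpus))
  for (cd in names(td$seg_tabs)) {
    w <- td$seg_tabs[[cd]]$weight
    expect_equal(w[length(w)], 1.0)
    expect_equal(rev(w), 0.5^(seq_along(w) - 1))
  }
})

test_that("zero-weight segments change no parameters", {
  dim <- 8L
  set.seed(3)
  syn0a <- matrix(stats::runif(dim * 3, -0.1, 0.1), dim, 3)
  syn1a <- matrix(stats::runif(dim * 1, -0.1, 0.1), dim, 1)
  syn0b <- syn0a + 0; syn1b <- syn1a + 0
  tree <- build_huffman(c(s1 = 5, s2 = 3))
  # one note, tokens {1,2}: segment s1 at weight 0 plus s2 at weight 1 ...
  ns$cpp_icd_train(list(1:2), list(1:2), list(c(0, 1)),
                   unname(tree$codes), unname(tree$points),
                   syn0a, syn1a, 2L, 0.05, 1e-4)
  # ... must equal training on s2 alone (the lr schedule counts pairs, so
  # feed the same pair count with weight 0 standing in)
  ns$cpp_icd_train(list(1:2), list(c(2L, 2L)), list(c(0, 1)),
                   unname(tree$codes), unname(tree$points),
                   syn0b, syn1b, 2L, 0.05, 1e-4)
  expect_identical(syn0a, syn0b)
  expect_identical(syn1a, syn1b)
})

test_that("ICD-target model separates codes and converges by profile", {
  wins <- 0L
  for (s in 1:3) {
    g <- two_code_corpus(s)
    m <- semantic_model(g$corpus, "w2v-icd",
                        config = w2v_config(dim = 60, epochs = 10,
                                            initial_lr = 0.04, seed = s))
    cc <- mean_code_cosines(m, g)
    if (cc["within"] > cc["cross"]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)

  # two words with identical code-occurrence profiles converge
  notes <- lapply(1:30, function(i)
    mk_note("e1", i - 1L, list(c("alpha", "beta"))))
  corp <- mk_corpus(care_episode("e1", notes, "J21.1"))
  m <- semantic_model(corp, "w2v-icd",
                      config = w2v_config(dim = 50, epochs = 10,
                                          initial_lr = 0.04, seed = 2))
  V <- coef(m)
  expect_gt(cosine(V["alpha", ], V["beta", ]), 0.95)
})

test_that("dimensionality and vocabulary are invariant under training", {
  g <- two_code_corpus(5)
  vocab <- build_vocabulary(g$corpus)
  for (meth in c("w2v", "w2v-icd")) {
    m <- semantic_model(g$corpus, meth,
                        config = w2v_config(dim = 32, epochs = 1, seed = 1))
    expect_equal(ncol(coef(m)), 32L)
    expect_identical(rownames(coef(m)), vocab$words)
  }
})
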