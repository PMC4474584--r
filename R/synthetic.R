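#' Synthetic care-episode corpus configuration
#'
#' Parameters of the seeded generator that emulates the structure of a
#' coded clinical corpus: episodes of sequential notes concluded by a
#' discharge summary, one primary ICD-10-style code per episode, and
#' code-specific topic lexicons mixed with a shared Zipf-distributed
#' background vocabulary so that code identity is statistically recoverable
#' from the text. Sibling codes share ancestor-level lexicons mixed in with
#' geometrically decreasing weight (1, 0.5, 0.25 for code, category,
#' chapter), mirroring the taxonomy halving used by the ICD-supervised
#' models.
#'
#' @param n_codes Number of distinct full codes.
#' @param n_chapters Number of chapters the codes are spread over.
#' @param episodes_per_code Episodes generated per code.
#' @param lambda Probability that a (non-stopword) token is drawn from the
#'   episode's code lexicon hierarchy rather than the background.
#' @param vocab_background Background vocabulary size.
#' @param topic_words_per_node Lexicon size per taxonomy node.
#' @param active_topic_words Number of lexicon words active per episode and
#'   node: each episode presents its own random subset of its code's
#'   lexicon, emulating patients showing different subsets of a diagnosis's
#'   symptom vocabulary, so same-code episodes overlap only partially in
#'   exact words and distributional similarity has work to do. `NULL`
#'   activates the whole lexicon.
#' @param notes_per_episode Inclusive range of notes per episode (the last
#'   one is the discharge summary); minimum 2.
#' @param tokens_per_note Inclusive range of tokens per note.
#' @param zipf_exponent Exponent of the background Zipf distribution.
#' @param stopword_rate Probability a token position emits a stopword.
#' @param n_stopwords Stopword vocabulary size.
#' @param icd_mention_prob Probability a clinical note gets an extra
#'   sentence mentioning the episode's code in free text.
#' @param summary_topic_share Probability a non-stopword summary token
#'   resamples one of the episode's earlier topic draws (else background).
#' @param ancestor_mixing Mix ancestor-node lexicons into the topic draws;
#'   `FALSE` restricts topic tokens to the full code's own lexicon.
#' @param thesaurus_fraction Share of topic words emitted to the
#'   metathesaurus term list.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_codes = 10L, n_chapters = 3L,
                         episodes_per_code = 20L, lambda = 0.7,
                         vocab_background = 2000L,
                         topic_words_per_node = 40L,
                         active_topic_words = 8L,
                         notes_per_episode = c(5L, 10L),
                         tokens_per_note = c(20L, 40L),
                         zipf_exponent = 1.1, stopword_rate = 0.15,
                         n_stopwords = 8L, icd_mention_prob = 0.15,
                         summary_topic_share = 0.8,
                         ancestor_mixing = TRUE,
                         thesaurus_fraction = 1.0, seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, n_codes >= 1L, n_chapters >= 1L,
            episodes_per_code >= 1L, notes_per_episode[1] >= 2L,
            tokens_per_note[1] >= 1L, thesaurus_fraction >= 0,
            thesaurus_fraction <= 1)
  structure(list(n_codes = as.integer(n_codes),
                 n_chapters = as.integer(n_chapters),
                 episodes_per_code = as.integer(episodes_per_code),
                 lambda = lambda,
                 vocab_background = as.integer(vocab_background),
                 topic_words_per_node = as.integer(topic_words_per_node),
                 active_topic_words = if (is.null(active_topic_words)) NULL
                                      else as.integer(active_topic_words),
                 notes_per_episode = as.integer(notes_per_episode),
                 tokens_per_note = as.integer(tokens_per_note),
                 zipf_exponent = zipf_exponent,
                 stopword_rate = stopword_rate,
                 n_stopwords = as.integer(n_stopwords),
                 icd_mention_prob = icd_mention_prob,
                 summary_topic_share = summary_topic_share,
                 ancestor_mixing = isTRUE(ancestor_mixing),
                 thesaurus_fraction = thesaurus_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_code_table <- function(cfg) {
  chapters <- LETTERS[seq_len(cfg$n_chapters)]
  chap <- chapters[(seq_len(cfg$n_codes) - 1L) %% cfg$n_chapters + 1L]
  within <- stats::ave(seq_len(cfg$n_codes), chap, FUN = seq_along)
  category <- sprintf("%s%02d", chap, (within - 1L) %/% 2L + 1L)
  sub <- (within - 1L) %% 2L + 1L
  data.frame(code = sprintf("%s.%d", category, sub),
             category = category, chapter = chap,
             stringsAsFactors = FALSE)
}

node_lexicon <- function(node, n) {
  sprintf("tw%sx%03d", tolower(gsub("[^A-Za-z0-9]", "", node)), seq_len(n))
}

#' Generate a synthetic care-episode corpus
#'
#' Deterministic for a fixed configuration (byte-identical corpus,
#' metathesaurus and stopword files per seed). See [synth_config()] for the
#' generative model.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional directory; when given, `corpus.jsonl`,
#'   `thesaurus.txt` and `stopwords.txt` are written there.
#' @return List with elements `corpus` (a `care_corpus`), `thesaurus`,
#'   `stopwords`, `code_table` and `config`.
#' @export
generate_corpus <- function(cfg = synth_config(), dir = NULL) {
  codes <- synth_code_table(cfg)
  lex_code <- lapply(codes$code, node_lexicon, n = cfg$topic_words_per_node)
  names(lex_code) <- codes$code
  lex_cat <- lapply(unique(codes$category), node_lexicon,
                    n = cfg$topic_words_per_node)
  names(lex_cat) <- unique(codes$category)
  lex_chap <- lapply(unique(codes$chapter), node_lexicon,
                     n = cfg$topic_words_per_node)
  names(lex_chap) <- unique(codes$chapter)
  background <- sprintf("bg%04d", seq_len(cfg$vocab_background))
  bg_prob <- seq_len(cfg$vocab_background) ^ (-cfg$zipf_exponent)
  bg_prob <- bg_prob / sum(bg_prob)
  stopwords <- sprintf("sw%02d", seq_len(cfg$n_stopwords))
  level_prob <- if (cfg$ancestor_mixing) c(1, 0.5, 0.25) / 1.75
                else c(1, 0, 0)

  episodes <- vector("list", cfg$n_codes * cfg$episodes_per_code)
  ei <- 0L
  with_preserved_rng({
    set.seed(cfg$seed)
    for (ci in seq_len(nrow(codes))) {
      lexs <- list(lex_code[[codes$code[ci]]],
                   lex_cat[[codes$category[ci]]],
                   lex_chap[[codes$chapter[ci]]])
      for (k in seq_len(cfg$episodes_per_code)) {
        ei <- ei + 1L
        eid <- sprintf("ep%04d", ei)
        active <- if (is.null(cfg$active_topic_words)) lexs
                  else lapply(lexs, function(lx)
                    sample(lx, min(cfg$active_topic_words, length(lx))))
        n_notes <- sample(cfg$notes_per_episode[1]:cfg$notes_per_episode[2],
                          1L)
        topic_draws <- character(0)
        notes <- vector("list", n_notes)
        for (nn in seq_len(n_notes - 1L)) {
          n_tok <- sample(cfg$tokens_per_note[1]:cfg$tokens_per_note[2], 1L)
          kind <- ifelse(stats::runif(n_tok) < cfg$stopword_rate, "s",
                         ifelse(stats::runif(n_tok) < cfg$lambda, "t", "b"))
          toks <- character(n_tok)
          n_t <- sum(kind == "t")
          if (n_t) {
            lv <- sample.int(3L, n_t, replace = TRUE, prob = level_prob)
            toks[kind == "t"] <- vapply(lv, function(l)
              sample(active[[l]], 1L), character(1))
            topic_draws <- c(topic_draws, toks[kind == "t"])
          }
          toks[kind == "s"] <- sample(stopwords, sum(kind == "s"),
                                      replace = TRUE)
          toks[kind == "b"] <- sample(background, sum(kind == "b"),
                                      replace = TRUE, prob = bg_prob)
          sents <- chunk_sentences(toks)
          if (stats::runif(1) < cfg$icd_mention_prob)
            sents <- c(sents, list(c("dg", tolower(codes$code[ci]))))
          notes[[nn]] <- clinical_note(sprintf("%s-n%02d", eid, nn), eid,
                                       nn - 1L, sents)
        }
        n_tok <- sample(cfg$tokens_per_note[1]:cfg$tokens_per_note[2], 1L)
        kind <- ifelse(stats::runif(n_tok) < cfg$stopword_rate, "s",
                       ifelse(stats::runif(n_tok) < cfg$summary_topic_share &
                                length(topic_draws) > 0, "t", "b"))
        toks <- character(n_tok)
        if (any(kind == "t"))
          toks[kind == "t"] <- sample(topic_draws, sum(kind == "t"),
                                      replace = TRUE)
        toks[kind == "s"] <- sample(stopwords, sum(kind == "s"),
                                    replace = TRUE)
        toks[kind == "b"] <- sample(background, sum(kind == "b"),
                                    replace = TRUE, prob = bg_prob)
        notes[[n_notes]] <- clinical_note(
          sprintf("%s-n%02d", eid, n_notes), eid, n_notes - 1L,
          chunk_sentences(toks), is_summary = TRUE)
        episodes[[ei]] <- care_episode(eid, notes, codes$code[ci])
      }
    }
    topic_words <- sort(unique(unlist(c(lex_code, lex_cat, lex_chap))))
    n_thes <- round(cfg$thesaurus_fraction * length(topic_words))
    thesaurus <- sort(sample(topic_words, n_thes))
  })
  out <- list(corpus = new_care_corpus(episodes), thesaurus = thesaurus,
              stopwords = stopwords, code_table = codes, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_corpus(out$corpus, file.path(dir, "corpus.jsonl"))
    writeLines(out$thesaurus, file.path(dir, "thesaurus.txt"))
    writeLines(out$stopwords, file.path(dir, "stopwords.txt"))
  }
  out
}

chunk_sentences <- function(tokens) {
  sents <- list()
  i <- 1L
  while (i <= length(tokens)) {
    len <- min(sample(4:8, 1L), length(tokens) - i + 1L)
    sents[[length(sents) + 1L]] <- tokens[i:(i + len - 1L)]
    i <- i + len
  }
  sents
}
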