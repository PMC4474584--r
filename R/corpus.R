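#' Clinical note constructor
#'
#' A clinical note is one free-text record of a care episode: an ordered list
#' of sentences, each a character vector of lowercase lemma tokens. The final
#' note of an episode may be flagged as its discharge summary.
#'
#' @param note_id Opaque note identifier, unique within the corpus.
#' @param episode_id Identifier of the episode the note belongs to.
#' @param position 0-based ordinal of the note within its episode.
#' @param sentences List of non-empty character vectors of tokens.
#' @param is_summary Logical; `TRUE` only for a discharge summary, which must
#'   be the last note of its episode.
#' @return An object of class `clinical_note`.
#' @export
clinical_note <- function(note_id, episode_id, position, sentences,
                          is_summary = FALSE) {
  stopifnot(is.character(note_id), length(note_id) == 1L,
            is.character(episode_id), length(episode_id) == 1L,
            is.numeric(position), position >= 0,
            is.list(sentences), is.logical(is_summary))
  structure(
    list(note_id = note_id, episode_id = episode_id,
         position = as.integer(position), is_summary = isTRUE(is_summary),
         sentences = lapply(sentences, as.character)),
    class = "clinical_note")
}

#' Care episode constructor
#'
#' A care episode is the ordered sequence of clinical notes documenting one
#' hospital stay, optionally concluded by a discharge summary and optionally
#' labelled with a single primary ICD-10 diagnosis code.
#'
#' @param episode_id Opaque episode identifier.
#' @param notes List of [clinical_note()] objects, ordered by position.
#' @param primary_icd Primary ICD-10 code string (e.g. `"J21.1"`) or `NULL`.
#' @return An object of class `care_episode`.
#' @export
care_episode <- function(episode_id, notes, primary_icd = NULL) {
  if (length(notes) < 1L) stop("care episode needs at least one note")
  pos <- vapply(notes, function(n) n$position, integer(1))
  if (!identical(pos, seq_along(notes) - 1L))
    stop("note positions must be consecutive from 0 in episode ", episode_id)
  summ <- vapply(notes, function(n) n$is_summary, logical(1))
  if (any(summ[-length(summ)]))
    stop("only the last note of episode ", episode_id,
         " may be a discharge summary")
  structure(list(episode_id = episode_id, notes = notes,
                 primary_icd = primary_icd),
            class = "care_episode")
}

#' @export
print.care_episode <- function(x, ...) {
  cat("<care_episode> ", x$episode_id, ": ", length(x$notes), " notes",
      if (any(vapply(x$notes, `[[`, logical(1), "is_summary")))
        " (incl. summary)" else "",
      if (!is.null(x$primary_icd)) paste0(", ICD-10 ", x$primary_icd) else "",
      "\n", sep = "")
  invisible(x)
}

new_care_corpus <- function(episodes) {
  ids <- vapply(episodes, `[[`, character(1), "episode_id")
  if (anyDuplicated(ids)) stop("duplicate episode_id in corpus")
  episodes <- episodes[order(ids)]
  names(episodes) <- sort(ids)
  structure(episodes, class = "care_corpus")
}

#' @export
print.care_corpus <- function(x, ...) {
  n_notes <- sum(vapply(x, function(e) length(e$notes), integer(1)))
  coded <- sum(vapply(x, function(e) !is.null(e$primary_icd), logical(1)))
  cat("<care_corpus> ", length(x), " episodes, ", n_notes, " notes, ",
      coded, " with a primary ICD-10 code\n", sep = "")
  invisible(x)
}

#' Preprocessing configuration
#'
#' @param stopwords Character vector of stopword lemmas (may be empty).
#' @param drop_numeric Drop tokens that are pure numbers.
#' @param lowercase Lowercase all tokens before filtering.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(stopwords = character(), drop_numeric = TRUE,
                              lowercase = TRUE) {
  structure(list(stopwords = as.character(stopwords),
                 drop_numeric = isTRUE(drop_numeric),
                 lowercase = isTRUE(lowercase)),
            class = "preprocess_config")
}

preprocess_tokens <- function(tokens, cfg) {
  if (cfg$lowercase) tokens <- tolower(tokens)
  keep <- rep(TRUE, length(tokens))
  if (cfg$drop_numeric) keep <- keep & !grepl("^[0-9]+([.,][0-9]+)?$", tokens)
  if (length(cfg$stopwords)) keep <- keep & !(tokens %in% cfg$stopwords)
  tokens[keep]
}

#' Apply preprocessing to an in-memory corpus
#'
#' Lowercases tokens, removes stopwords and purely numeric tokens, drops
#' sentences and notes that become empty, and renumbers note positions so the
#' episode invariants still hold. Episodes losing all notes are dropped.
#'
#' @param corpus A `care_corpus`.
#' @param cfg A [preprocess_config()].
#' @return A preprocessed `care_corpus`.
#' @export
preprocess_corpus <- function(corpus, cfg = preprocess_config()) {
  eps <- lapply(corpus, function(ep) {
    notes <- lapply(ep$notes, function(nt) {
      sents <- lapply(nt$sentences, preprocess_tokens, cfg = cfg)
      nt$sentences <- sents[lengths(sents) > 0L]
      nt
    })
    notes <- notes[vapply(notes, function(n) length(n$sentences) > 0L,
                          logical(1))]
    if (!length(notes)) return(NULL)
    for (i in seq_along(notes)) notes[[i]]$position <- i - 1L
    care_episode(ep$episode_id, notes, ep$primary_icd)
  })
  new_care_corpus(Filter(Negate(is.null), eps))
}

#' Read a care-episode corpus from a line-delimited JSON file
#'
#' Each line holds one note record with keys `episode_id`, `note_id`,
#' `position`, `is_summary`, `icd10` (string or null, identical on all notes
#' of an episode) and `sentences` (list of token lists). Notes of an episode
#' need not be adjacent lines. Episodes are returned ordered by id, notes by
#' position; preprocessing is applied and empty notes are dropped.
#'
#' @param path Path to a UTF-8 JSON-lines corpus file.
#' @param preprocess A [preprocess_config()], or `NULL` to keep tokens as-is.
#' @return A `care_corpus`.
#' @export
read_corpus <- function(path, preprocess = preprocess_config()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(new_care_corpus(list()))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop("malformed corpus record at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    for (key in c("episode_id", "note_id", "position", "is_summary",
                  "sentences"))
      if (is.null(rec[[key]]))
        stop("corpus record at line ", i, " lacks key '", key, "'",
             call. = FALSE)
    recs[[i]] <- rec
  }
  ep_ids <- vapply(recs, function(r) as.character(r$episode_id), character(1))
  keypair <- paste(ep_ids, vapply(recs, function(r) as.integer(r$position),
                                  integer(1)))
  if (anyDuplicated(keypair)) {
    d <- keypair[duplicated(keypair)][1L]
    stop("duplicate (episode_id, position): ", d, call. = FALSE)
  }
  episodes <- lapply(split(recs, ep_ids), function(rr) {
    pos <- vapply(rr, function(r) as.integer(r$position), integer(1))
    rr <- rr[order(pos)]
    icd <- unique(unlist(lapply(rr, function(r)
      if (is.null(r$icd10)) NA_character_ else as.character(r$icd10))))
    if (length(icd) > 1L)
      stop("inconsistent icd10 within episode ", rr[[1L]]$episode_id,
           call. = FALSE)
    notes <- lapply(seq_along(rr), function(i) {
      r <- rr[[i]]
      clinical_note(as.character(r$note_id), as.character(r$episode_id),
                    i - 1L,
                    lapply(r$sentences, function(s) unlist(s, use.names = FALSE)),
                    isTRUE(r$is_summary))
    })
    care_episode(rr[[1L]]$episode_id, notes,
                 if (is.na(icd)) NULL else icd)
  })
  corpus <- new_care_corpus(unname(episodes))
  if (!is.null(preprocess)) preprocess_corpus(corpus, preprocess) else corpus
}

#' Write a care-episode corpus as line-delimited JSON
#'
#' Inverse of [read_corpus()]: one note record per line, episodes ordered by
#' id and notes by position, so `read_corpus(write_corpus(x))` is the
#' identity on valid preprocessed corpora.
#'
#' @param corpus A `care_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (ep in corpus) {
    for (nt in ep$notes) {
      rec <- list(episode_id = ep$episode_id, note_id = nt$note_id,
                  position = nt$position, is_summary = nt$is_summary,
                  icd10 = if (is.null(ep$primary_icd)) NULL else ep$primary_icd,
                  sentences = lapply(nt$sentences, as.list))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
    }
  }
  invisible(path)
}

note_tokens <- function(note) unlist(note$sentences, use.names = FALSE)

episode_tokens <- function(ep, include_summary = TRUE) {
  notes <- ep$notes
  if (!include_summary)
    notes <- notes[!vapply(notes, `[[`, logical(1), "is_summary")]
  unlist(lapply(notes, note_tokens), use.names = FALSE)
}

episode_summary_note <- function(ep) {
  last <- ep$notes[[length(ep$notes)]]
  if (isTRUE(last$is_summary)) last else NULL
}

#' Build the corpus vocabulary
#'
#' Collects the word list with total token frequencies and note-level
#' document frequencies. Clinical notes are the document unit for IDF
#' weighting throughout the package.
#'
#' @param corpus A preprocessed `care_corpus`.
#' @return An object of class `vocabulary`: words, integer ids, token
#'   frequency `tf`, note-level document frequency `df`, note count `n_notes`.
#' @export
build_vocabulary <- function(corpus) {
  n_notes <- 0L
  tok_list <- list()
  df_list <- list()
  for (ep in corpus) for (nt in ep$notes) {
    n_notes <- n_notes + 1L
    toks <- note_tokens(nt)
    tok_list[[n_notes]] <- toks
    df_list[[n_notes]] <- unique(toks)
  }
  tf_tab <- table(unlist(tok_list, use.names = FALSE))
  df_tab <- table(unlist(df_list, use.names = FALSE))
  words <- sort(names(tf_tab))
  structure(list(words = words,
                 id = stats::setNames(seq_along(words), words),
                 tf = as.integer(tf_tab[words]),
                 df = stats::setNames(as.integer(df_tab[words]), words),
                 n_notes = n_notes),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x$words), " words over ", x$n_notes,
      " notes\n", sep = "")
  invisible(x)
}

#' Read a term list (metathesaurus or stopword file)
#'
#' One lowercase term per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of unique terms.
#' @export
read_term_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  unique(tolower(trimws(x[nzchar(trimws(x))])))
}
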