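#' Evaluation configuration
#'
#' @param k Cutoff for precision-at-k.
#' @param top_n Size of the discharge-summary-overlap relevance sets.
#' @param limit Number of episodes retrieved per query in the
#'   summary-overlap protocol.
#' @param min_notes Minimum number of clinical (non-summary) notes an
#'   episode needs to serve as a query.
#' @param n_queries Number of query episodes sampled, each with a distinct
#'   primary ICD-10 code.
#' @param seed Integer seed for query sampling and the random baseline.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(k = 10L, top_n = 100L, limit = 1000L,
                        min_notes = 6L, n_queries = 40L, seed = 1L) {
  stopifnot(k >= 1L, top_n >= 0L, limit >= 1L, min_notes >= 1L,
            n_queries >= 1L)
  structure(list(k = as.integer(k), top_n = as.integer(top_n),
                 limit = as.integer(limit), min_notes = as.integer(min_notes),
                 n_queries = as.integer(n_queries), seed = as.integer(seed)),
            class = "eval_config")
}

n_clinical_notes <- function(ep)
  sum(!vapply(ep$notes, `[[`, logical(1), "is_summary"))

#' Sample query episodes
#'
#' Queries are coded episodes with at least `min_notes` clinical notes, a
#' non-empty relevance set (some other episode shares the primary code), and
#' pairwise distinct primary ICD-10 codes. Sampling is seeded; an error
#' listing the eligible counts is raised when too few queries exist.
#'
#' @param corpus A `care_corpus`.
#' @param cfg An [eval_config()].
#' @param require_summary Additionally require a discharge summary (needed
#'   by the summary-overlap protocol).
#' @return Character vector of query episode ids.
#' @export
sample_queries <- function(corpus, cfg = eval_config(),
                           require_summary = FALSE) {
  codes <- vapply(corpus, function(e)
    if (is.null(e$primary_icd)) NA_character_ else e$primary_icd,
    character(1))
  code_count <- table(codes[!is.na(codes)])
  eligible <- vapply(seq_along(corpus), function(i) {
    ep <- corpus[[i]]
    !is.na(codes[i]) &&
      n_clinical_notes(ep) >= cfg$min_notes &&
      code_count[[codes[i]]] >= 2L &&
      (!require_summary || !is.null(episode_summary_note(ep)))
  }, logical(1))
  idx <- which(eligible)
  with_preserved_rng({
    set.seed(cfg$seed)
    idx <- idx[sample.int(length(idx))]
  })
  picked <- idx[!duplicated(codes[idx])]
  if (length(picked) < cfg$n_queries)
    stop("only ", length(picked), " eligible queries with distinct codes (",
         sum(eligible), " eligible episodes, ", length(code_count),
         " codes) but ", cfg$n_queries, " requested")
  ids <- vapply(corpus, `[[`, character(1), "episode_id")
  ids[picked[seq_len(cfg$n_queries)]]
}

# Polymorphic ranking over the supported ranker kinds.
rank_with <- function(ranker, query, collection, scheme, cfg, query_index,
                      cache = NULL, limit = NULL) {
  if (inherits(ranker, "weighted_model")) {
    rank_collection(query, collection, scheme, ranker, limit = limit,
                    episode_matrix = cache)
  } else if (inherits(ranker, "tfidf_ranker")) {
    tfidf_baseline_rank(ranker, query, limit = limit)
  } else if (inherits(ranker, "random_ranker")) {
    rl <- random_rank(query, collection, seed = ranker$seed + query_index)
    if (!is.null(limit)) utils::head(rl, limit) else rl
  } else stop("unsupported ranker")
}

#' Random-baseline ranker marker
#'
#' @param seed Base seed; each query uses `seed + query index`.
#' @return Object of class `random_ranker` for the experiment drivers.
#' @export
random_ranker <- function(seed = 1L) {
  structure(list(seed = as.integer(seed)), class = "random_ranker")
}

#' Code-identity retrieval evaluation
#'
#' The first evaluation protocol: a retrieved episode is relevant when its
#' primary ICD-10 code is identical to the query's. Query episodes are
#' stripped of their discharge summary and of ICD-mentioning sentences; the
#' whole collection is ranked for each query and MAP, precision-at-k and
#' R-precision are averaged over queries.
#'
#' @param corpus A preprocessed, coded `care_corpus`.
#' @param rankers Named list of `weighted_model`, [tfidf_ranker()] or
#'   [random_ranker()] objects.
#' @param schemes Episode-similarity schemes evaluated for each weighted
#'   model (baselines ignore this).
#' @param cfg An [eval_config()].
#' @return Named list of `eval_report` objects, one per ranker/scheme.
#' @export
run_experiment1 <- function(corpus, rankers, schemes = "single",
                            cfg = eval_config()) {
  qids <- sample_queries(corpus, cfg)
  ids <- vapply(corpus, `[[`, character(1), "episode_id")
  codes <- vapply(corpus, function(e)
    if (is.null(e$primary_icd)) NA_character_ else e$primary_icd,
    character(1))
  queries <- lapply(qids, function(q)
    build_query_episode(corpus[[match(q, ids)]]))
  usable <- vapply(queries, is_usable_query, logical(1))
  if (!all(usable)) stop("unusable query episode(s): ",
                         paste(qids[!usable], collapse = ", "))
  relevance <- lapply(qids, function(q)
    setdiff(ids[!is.na(codes) & codes == codes[match(q, ids)]], q))
  names(relevance) <- qids
  out <- list()
  for (rname in names(rankers)) {
    rk <- rankers[[rname]]
    sch_list <- if (inherits(rk, "weighted_model")) schemes else "-"
    for (scheme in sch_list) {
      cache <- if (inherits(rk, "weighted_model") && scheme == "single")
        collection_episode_matrix(corpus, rk) else NULL
      pq <- do.call(rbind, lapply(seq_along(queries), function(i) {
        rl <- rank_with(rk, queries[[i]], corpus, scheme, cfg, i, cache)
        as.data.frame(as.list(query_metrics(rl, relevance[[qids[i]]],
                                            cfg$k)))
      }))
      pq <- cbind(query_id = qids, pq)
      label <- if (identical(sch_list, "-")) rname
               else paste0(rname, ":", scheme)
      out[[label]] <- new_eval_report(pq, cfg, label)
    }
  }
  out
}

summary_only_episode <- function(ep) {
  s <- episode_summary_note(ep)
  if (is.null(s)) return(NULL)
  s$position <- 0L; s$is_summary <- FALSE
  care_episode(ep$episode_id, list(s), ep$primary_icd)
}

strip_summary <- function(ep) {
  notes <- ep$notes[!vapply(ep$notes, `[[`, logical(1), "is_summary")]
  if (!length(notes)) return(NULL)
  care_episode(ep$episode_id, notes, ep$primary_icd)
}

#' Discharge-summary-overlap relevance sets
#'
#' For each query, the `n` collection episodes whose discharge summary is
#' most similar to the query's summary under the given model are taken as
#' relevant. Weighted models use the cosine of pooled summary vectors; the
#' TF-IDF ranker uses its own scorer on summary text.
#'
#' @param model A `weighted_model` or `tfidf_ranker`.
#' @param query_ids Character vector of query episode ids.
#' @param collection A `care_corpus` in which every episode has a summary.
#' @param n Relevance-set size.
#' @return Named list: query id -> character vector of relevant ids.
#' @export
build_summary_gold <- function(model, query_ids, collection, n = 100L) {
  ids <- vapply(collection, `[[`, character(1), "episode_id")
  summaries <- lapply(collection, summary_only_episode)
  if (any(vapply(summaries, is.null, logical(1))))
    stop("summary-overlap relevance needs a discharge summary per episode")
  if (inherits(model, "tfidf_ranker")) {
    vecs <- lapply(summaries, function(s)
      tfidf_vector(model, episode_tokens(s)))
    score_fun <- function(i, j) cosine(vecs[[i]], vecs[[j]])
  } else {
    vecs <- lapply(summaries, function(s) episode_vector(s, model))
    score_fun <- function(i, j) cosine(vecs[[i]], vecs[[j]])
  }
  gold <- lapply(query_ids, function(q) {
    qi <- match(q, ids)
    cand <- setdiff(seq_along(ids), qi)
    sc <- vapply(cand, function(j) score_fun(qi, j), numeric(1))
    ord <- order(-sc, ids[cand])
    ids[cand][utils::head(ord, n)]
  })
  stats::setNames(gold, query_ids)
}

#' Cross-model summary-overlap evaluation
#'
#' The second evaluation protocol: every ranker is evaluated against the
#' relevance sets constructed by every model (a full cross design, 7x7 in
#' the original setting). Discharge summaries are excluded from both query
#' and retrieval-side text and only define relevance. For each cell the
#' retrieved-relevant count (summed and per-query mean), MAP and
#' precision-at-k over the top `limit` retrieved episodes are reported,
#' together with per-ranker row means and ranks.
#'
#' @param corpus A preprocessed `care_corpus` where episodes end in a
#'   discharge summary.
#' @param rankers Named list of `weighted_model` / [tfidf_ranker()] objects
#'   (the TF-IDF ranker must be fitted on the summary-free collection).
#' @param gold_models Named list of models used to build relevance sets;
#'   defaults to `rankers`.
#' @param scheme Episode-similarity scheme for weighted-model rankers.
#' @param cfg An [eval_config()].
#' @return Object of class `experiment2_report` holding matrices
#'   `map`, `p_at_k`, `count_total`, `count_mean` (rankers x gold models),
#'   `row_means` and `ranks`.
#' @export
run_experiment2 <- function(corpus, rankers, gold_models = rankers,
                            scheme = "single", cfg = eval_config()) {
  qids <- sample_queries(corpus, cfg, require_summary = TRUE)
  ids <- vapply(corpus, `[[`, character(1), "episode_id")
  retrieval_side <- new_care_corpus(
    Filter(Negate(is.null), lapply(corpus, strip_summary)))
  queries <- lapply(qids, function(q)
    build_query_episode(corpus[[match(q, ids)]]))
  # ranked lists once per ranker, reused across relevance constructions
  ranked <- lapply(rankers, function(rk) {
    cache <- if (inherits(rk, "weighted_model") && scheme == "single")
      collection_episode_matrix(retrieval_side, rk) else NULL
    lapply(seq_along(queries), function(i)
      rank_with(rk, queries[[i]], retrieval_side, scheme, cfg, i,
                cache, limit = cfg$limit))
  })
  gold <- lapply(gold_models, function(g)
    build_summary_gold(g, qids, corpus, cfg$top_n))
  dims <- list(ranker = names(rankers), gold = names(gold_models))
  mk <- function() matrix(NA_real_, length(rankers), length(gold_models),
                          dimnames = dims)
  map <- p_at_k <- count_total <- count_mean <- mk()
  for (r in names(rankers)) for (g in names(gold_models)) {
    m <- vapply(seq_along(qids), function(i)
      query_metrics(ranked[[r]][[i]], gold[[g]][[qids[i]]], cfg$k),
      c(ap = 0, p_at_k = 0, rprec = 0, retrieved_relevant = 0))
    map[r, g] <- mean(m["ap", ])
    p_at_k[r, g] <- mean(m["p_at_k", ])
    count_total[r, g] <- sum(m["retrieved_relevant", ])
    count_mean[r, g] <- mean(m["retrieved_relevant", ])
  }
  row_means <- cbind(map = rowMeans(map), p_at_k = rowMeans(p_at_k),
                     count_total = rowMeans(count_total))
  structure(list(map = map, p_at_k = p_at_k, count_total = count_total,
                 count_mean = count_mean, row_means = row_means,
                 ranks = rank(-row_means[, "map"], ties.method = "min"),
                 queries = qids, config = cfg),
            class = "experiment2_report")
}

#' @export
print.experiment2_report <- function(x, ...) {
  cat("<experiment2_report> ", nrow(x$map), " rankers x ", ncol(x$map),
      " relevance constructions, ", length(x$queries), " queries\n",
      sep = "")
  cat("MAP matrix:\n")
  print(round(x$map, 4))
  cat("Row means (MAP) and ranks:\n")
  print(cbind(map = round(x$row_means[, "map"], 4), rank = x$ranks))
  invisible(x)
}

#' Write per-query metrics and the run manifest
#'
#' Tab-separated export of an `eval_report` (per-query metrics plus a
#' summary row) with a JSON manifest of the configuration alongside.
#'
#' @param report An `eval_report`.
#' @param path Output TSV path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report$per_query, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(label = report$label,
                            means = as.list(report$means),
                            config = unclass(report$config)),
                       paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}
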