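test_that("rank-based metrics reproduce hand-evaluated cases", {
  # ranking [rel, non, rel] with two relevant items
  expect_equal(average_precision(c("r1", "n1", "r2"), c("r1", "r2")), 5 / 6)
  expect_equal(average_precision(c("r1", "r2", "n1"), c("r1", "r2")), 1)
  expect_equal(average_precision(c("n1", "n2"), c("r1")), 0)
  expect_equal(precision_at_k(c("r1", "n1", "r2", "n2", "r3",
                                paste0("n", 3:7)),
                              c("r1", "r2", "r3"), 10), 0.3)
  expect_equal(precision_at_k(c("r1"), c("r1"), 10), 0.1)
  expect_equal(r_precision(c("r1", "n1"), c("r1", "r2")), 0.5)
  expect_equal(r_precision(c("r1", "n1", "r2", "n2"),
                           c("r1", "r2", "r3", "r4")), 0.5)
})

test_that("metrics agree with an independent reference implementation", {
  set.seed(59)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    ids <- paste0("e", sample(1000, n))
    relevant <- sample(ids, sample(1:min(8, n), 1))
    if (stats::runif(1) < 0.3) # sometimes unretrieved relevant items
      relevant <- c(relevant, paste0("x", i))
    k <- sample(c(3L, 10L), 1)
    expect_equal(average_precision(ids, relevant), oracle_ap(ids, relevant))
    expect_equal(precision_at_k(ids, relevant, k),
                 oracle_p_at_k(ids, relevant, k))
    expect_equal(r_precision(ids, relevant), oracle_rprec(ids, relevant))
  }
})

test_that("metrics are invariant to id relabeling and irrelevant tails", {
  ids <- c("a", "b", "c", "d", "e")
  rel <- c("b", "d")
  relabel <- stats::setNames(paste0("z", 1:5), ids)
  expect_equal(average_precision(unname(relabel[ids]), relabel[rel]),
               average_precision(ids, rel))
  longer <- c(ids, paste0("tail", 1:20))
  expect_equal(average_precision(longer, rel), average_precision(ids, rel))
  expect_equal(precision_at_k(longer, rel, 5), precision_at_k(ids, rel, 5))
  expect_equal(r_precision(longer, rel), r_precision(ids, rel))
})

test_that("a verbatim copy of the query ranks first", {
  wm <- fx_weighted("ri-index")
  q <- build_query_episode(fx_corpus[["fx02"]])
  copy <- care_episode("copy", q$notes, NULL)
  coll <- mk_corpus(copy, fx_corpus[["fx05"]], fx_corpus[["fx09"]],
                    fx_corpus[["fx02"]])
  rl <- rank_collection(q, coll, "single", wm)
  expect_identical(rl$episode_id[1], "copy")
  expect_equal(rl$score[1], 1, tolerance = 1e-9)
  expect_false("fx02" %in% rl$episode_id) # query never ranks itself

  rk <- tfidf_ranker(coll)
  expect_identical(tfidf_baseline_rank(rk, q)$episode_id[1], "copy")
})

test_that("ranking is deterministic under collection permutation", {
  wm <- fx_weighted("ri-note")
  q <- build_query_episode(fx_corpus[["fx01"]])
  perm <- mk_corpus(fx_corpus[["fx09"]], fx_corpus[["fx02"]],
                    fx_corpus[["fx05"]])
  perm2 <- mk_corpus(fx_corpus[["fx02"]], fx_corpus[["fx05"]],
                     fx_corpus[["fx09"]])
  expect_equal(as.data.frame(rank_collection(q, perm, "avg", wm)),
               as.data.frame(rank_collection(q, perm2, "avg", wm)))
  expect_length(rank_collection(q, mk_corpus(), "single", wm)$episode_id,
                0L)
})

test_that("undefined similarities sink to the bottom of the ranking", {
  wm <- fx_weighted("ri-index")
  q <- build_query_episode(fx_corpus[["fx02"]])
  oov <- mk_ep1("zz-oov", list(c("xyzzy", "plugh")))
  coll <- mk_corpus(oov, fx_corpus[["fx05"]], fx_corpus[["fx01"]])
  rl <- rank_collection(q, coll, "single", wm)
  expect_identical(rl$episode_id[nrow(rl)], "zz-oov")
  expect_true(is.na(rl$score[nrow(rl)]))
})

test_that("TF-IDF baseline scores disjoint episodes at zero", {
  coll <- mk_corpus(mk_ep1("e1", list(c("kipu", "rinta"))),
                    mk_ep1("e2", list(c("nekroosi", "resektio"))))
  rk <- tfidf_ranker(coll)
  q <- mk_ep1("q", list(c("kipu", "kipu")))
  rl <- tfidf_baseline_rank(rk, q)
  expect_equal(rl$score[rl$episode_id == "e2"], 0)
  expect_gt(rl$score[rl$episode_id == "e1"], 0)
})

test_that("fast-path episode-matrix ranking equals the direct path", {
  wm <- fx_weighted("ri-word")
  q <- build_query_episode(fx_corpus[["fx06"]])
  E <- collection_episode_matrix(fx_corpus, wm)
  a <- rank_collection(q, fx_corpus, "single", wm, episode_matrix = E)
  b <- rank_collection(q, fx_corpus, "single", wm)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})

test_that("random baseline is a seeded complete permutation", {
  r1 <- random_rank(fx_corpus[[1]], fx_corpus, seed = 7)
  r2 <- random_rank(fx_corpus[[1]], fx_corpus, seed = 7)
  expect_identical(r1$episode_id, r2$episode_id)
  expect_setequal(r1$episode_id, setdiff(names(fx_corpus), "fx01"))
  r3 <- random_rank(fx_corpus[[1]], fx_corpus, seed = 8)
  expect_false(identical(r1$episode_id, r3$episode_id))
})

test_that("random baseline precision matches the binomial expectation", {
  rel <- c("fx02", "fx03", "fx04")
  p10 <- vapply(1:1000, function(s)
    precision_at_k(random_rank(fx_corpus[[1]], fx_corpus, s), rel, 10),
    numeric(1))
  prevalence <- length(rel) / 11
  se <- stats::sd(p10) / sqrt(length(p10))
  expect_lt(abs(mean(p10) - prevalence), 3 * se)
})

test_that("index-vector episode cosines track exact TF-IDF cosines", {
  g <- generate_corpus(synth_config(n_codes = 6, episodes_per_code = 6,
                                    lambda = 0.9, active_topic_words = NULL,
                                    vocab_background = 300, seed = 9))
  corp <- g$corpus
  idf <- compute_idf(build_vocabulary(corp))
  wm <- suppressWarnings(apply_weighting(
    semantic_model(corp, "ri-index", config = ri_config(seed = 9)), idf))
  E <- collection_episode_matrix(corp, wm)
  En <- E / sqrt(rowSums(E^2))
  ri_cos <- En %*% t(En)
  rk <- tfidf_ranker(corp)
  TV <- as.matrix(rk$matrix / pmax(rk$norms, 1e-12))
  tf_cos <- TV %*% t(TV)
  ut <- upper.tri(ri_cos)
  expect_gt(stats::cor(ri_cos[ut], tf_cos[ut]), 0.9)
  # per-query rank agreement is strongly positive
  sp <- vapply(corp[1:4], function(ep) {
    q <- build_query_episode(ep)
    a <- rank_collection(q, corp, "single", wm, episode_matrix = E)
    b <- tfidf_baseline_rank(rk, q)
    m <- merge(as.data.frame(a), as.data.frame(b), by = "episode_id")
    stats::cor(m$score.x, m$score.y, method = "spearman")
  }, numeric(1))
  expect_true(all(sp > 0.6))
})
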