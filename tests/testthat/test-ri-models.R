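ns <- asNamespace("epiretrieve")

dense_iv <- function(key, cfg, dir = NULL) {
  v <- make_index_vector(key, cfg)
  if (!is.null(dir)) v <- shift_vector(v, dir)
  ns$as_dense(v)
}

test_that("word-context training matches the hand-computed window sum", {
  cfg <- ri_config(dim = 64, window = 2, seed = 7)
  corp <- mk_corpus(mk_ep1("e1", list(paste0("w", 1:5))))
  m <- semantic_model(corp, "ri-word", config = cfg)
  expected_w3 <-
    dense_iv("w|w2", cfg, "left") + 0.5 * dense_iv("w|w1", cfg, "left") +
    dense_iv("w|w4", cfg, "right") + 0.5 * dense_iv("w|w5", cfg, "right")
  expect_equal(unname(coef(m)["w3", ]), expected_w3)
  # boundary word: only right context exists
  expected_w1 <-
    dense_iv("w|w2", cfg, "right") + 0.5 * dense_iv("w|w3", cfg, "right")
  expect_equal(unname(coef(m)["w1", ]), expected_w1)
})

test_that("windows do not cross sentence boundaries", {
  cfg <- ri_config(dim = 64, window = 3, seed = 7)
  one_sent <- mk_corpus(mk_ep("e1", list(list(c("a", "b", "c", "d")))))
  two_sent <- mk_corpus(mk_ep("e1", list(list(c("a", "b"), c("c", "d")))))
  m1 <- semantic_model(one_sent, "ri-word", config = cfg)
  m2 <- semantic_model(two_sent, "ri-word", config = cfg)
  expect_false(isTRUE(all.equal(coef(m1)["a", ], coef(m2)["a", ])))
  expect_equal(unname(coef(m2)["a", ]), dense_iv("w|b", cfg, "right"))
})

test_that("note-context training sums note index vectors with multiplicity", {
  cfg <- ri_config(dim = 64, seed = 11)
  corp <- mk_corpus(
    mk_ep("e1", list(list(c("twice", "twice", "solo")),
                     list(c("both", "x")))),
    mk_ep("e2", list(list(c("both", "y")))))
  m <- semantic_model(corp, "ri-note", config = cfg)
  iv <- function(eid, nid) dense_iv(paste0("n|", eid, "|", nid), cfg)
  expect_equal(unname(coef(m)["twice", ]), 2 * iv("e1", "e1-n01"))
  expect_equal(unname(coef(m)["solo", ]), iv("e1", "e1-n01"))
  expect_equal(unname(coef(m)["both", ]),
               iv("e1", "e1-n02") + iv("e2", "e2-n01"))
  # words sharing their single note have identical directions
  expect_equal(cosine(coef(m)["twice", ], coef(m)["solo", ]), 1)
})

test_that("ICD-supervised training adds the weighted segment chain", {
  cfg <- ri_config(dim = 64, seed = 13)
  corp <- mk_corpus(
    mk_ep1("e1", list(c("word1")), code = "J21.1"),
    mk_ep1("e2", list(c("word2")), code = "J21.1"))
  m <- semantic_model(corp, "ri-icd", config = cfg)
  expected <- 1.0 * dense_iv("c|J21.1", cfg) + 0.5 * dense_iv("c|J21", cfg) +
    0.25 * dense_iv("c|J2", cfg) + 0.125 * dense_iv("c|J", cfg)
  expect_equal(unname(coef(m)["word1", ]), expected)
  # same-code words in different notes coincide
  expect_equal(unname(coef(m)["word2", ]), unname(coef(m)["word1", ]))
  expect_equal(cosine(coef(m)["word1", ], coef(m)["word2", ]), 1)
})

test_that("uncoded corpora are rejected for ICD-supervised training", {
  corp <- mk_corpus(mk_ep1("e1", list(c("a"))))
  expect_error(semantic_model(corp, "ri-icd",
                              config = ri_config(dim = 32)), "ICD-10")
})

test_that("taxonomy gradient: sibling codes closer than cross-chapter", {
  sib <- numeric(100); cross <- numeric(100)
  for (s in 1:100) {
    cfg <- ri_config(dim = 200, seed = s)
    comp <- function(code) {
      st <- segment_icd(code)$segments
      v <- numeric(cfg$dim)
      for (i in seq_len(nrow(st)))
        v <- v + st$weight[i] * dense_iv(paste0("c|", st$segment[i]), cfg)
      v
    }
    sib[s] <- cosine(comp("J21.1"), comp("J21.2"))
    cross[s] <- cosine(comp("J21.1"), comp("K55.0"))
  }
  expect_gt(mean(sib), mean(cross))
  expect_gt(mean(sib), 0.15)
  expect_lt(abs(mean(cross)), 0.1)
})

test_that("plain index-vector model returns the index vectors themselves", {
  cfg <- ri_config(dim = 64, seed = 17)
  corp <- mk_corpus(mk_ep1("e1", list(c("a", "b"))))
  m <- semantic_model(corp, "ri-index", config = cfg)
  expect_setequal(rownames(coef(m)), c("a", "b"))
  expect_equal(unname(coef(m)["a", ]), dense_iv("w|a", cfg))
})

test_that("trainers are order-independent and incremental", {
  cfg <- ri_config(dim = 64, window = 2, seed = 19)
  A <- mk_corpus(
    mk_ep1("a1", list(c("x", "y", "z"), c("y", "q")), code = "J21.1"),
    mk_ep1("a2", list(c("z", "x")), code = "K55.0"))
  B <- mk_corpus(
    mk_ep1("b1", list(c("x", "q", "q"), c("z", "y", "x")), code = "J21.2"))
  AB <- mk_corpus(A[[1]], A[[2]], B[[1]])
  BA <- mk_corpus(B[[1]], A[[2]], A[[1]])
  for (method in c("ri-word", "ri-note", "ri-icd")) {
    mA <- coef(semantic_model(A, method, config = cfg))
    mB <- coef(semantic_model(B, method, config = cfg))
    mAB <- coef(semantic_model(AB, method, config = cfg))
    mBA <- coef(semantic_model(BA, method, config = cfg))
    expect_equal(mAB, mBA, info = method) # order independence
    summed <- matrix(0, nrow(mAB), ncol(mAB),
                     dimnames = dimnames(mAB))
    summed[rownames(mA), ] <- summed[rownames(mA), ] + mA
    summed[rownames(mB), ] <- summed[rownames(mB), ] + mB
    expect_equal(mAB, summed, tolerance = 1e-9, info = method)
  }
  # the untrained variant is incremental in the degenerate sense: vectors
  # are unchanged under corpus extension
  mA <- coef(semantic_model(A, "ri-index", config = cfg))
  mAB <- coef(semantic_model(AB, "ri-index", config = cfg))
  expect_equal(mAB[rownames(mA), ], mA)
})

test_that("empty corpora give empty models", {
  empty <- mk_corpus()
  for (method in c("ri-word", "ri-note", "ri-index")) {
    m <- semantic_model(empty, method, config = ri_config(dim = 16))
    expect_equal(nrow(coef(m)), 0L)
    expect_equal(ncol(coef(m)), 16L)
  }
})

test_that("doubling the corpus doubles accumulated context vectors", {
  cfg <- ri_config(dim = 32, window = 2, seed = 23)
  ep <- mk_ep1("e1", list(c("a", "b", "c")), code = "J21.1")
  one <- mk_corpus(ep)
  for (method in c("ri-word", "ri-icd")) {
    m1 <- coef(semantic_model(one, method, config = cfg))
    corp2 <- mk_corpus(ep, mk_ep1("e2", list(c("a", "b", "c")),
                                  code = "J21.1"))
    m2 <- coef(semantic_model(corp2, method, config = cfg))
    expect_equal(m2, 2 * m1, tolerance = 1e-12, info = method)
  }
})
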