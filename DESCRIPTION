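Package: epiretrieve
Title: Semantic Retrieval of Clinical Care Episodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distributional semantic models of clinical vocabulary for
    content-based retrieval of hospital care episodes. Implements four
    random-indexing variants (word context, note context, ICD-10-hierarchy
    supervised, and plain index vectors), a CBOW word2vec baseline with
    hierarchical soft-max, and a word2vec variant trained to predict the
    weighted ICD-10 code segments of the note containing each word. Episode
    similarity is computed from IDF-weighted word vectors via pooled episode
    vectors, exhaustive note-pair averaging, optimal note assignment
    (Hungarian algorithm) or order-preserving note alignment
    (Needleman-Wunsch). Includes TF-IDF and random retrieval baselines,
    mean-average-precision evaluation against ICD-code-identity and
    discharge-summary-overlap relevance proxies, and a seeded synthetic
    care-episode corpus generator with hierarchical diagnosis-specific
    lexical signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    clue,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
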