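#' Build a Huffman-coded hierarchical soft-max tree
#'
#' The hierarchical soft-max output layer organizes the prediction targets
#' (words, or ICD-10 code segments) as the leaves of a Huffman tree built on
#' their frequencies, so that predicting a target only touches the
#' `O(log V)` internal nodes on its root path. Ties in frequency are broken
#' by lexicographic leaf order, then by node creation order, making the tree
#' deterministic.
#'
#' @param freqs Named numeric vector of positive leaf counts.
#' @return An object of class `hs_tree`: per-leaf binary `codes` and
#'   internal-node `points` (1-based, root first), `n_internal`, and the leaf
#'   `counts` used.
#' @export
build_huffman <- function(freqs) {
  if (!length(freqs)) stop("empty frequency table")
  if (any(freqs <= 0)) stop("leaf counts must be positive")
  leaves <- sort(names(freqs))
  cnt <- as.numeric(freqs[leaves])
  V <- length(leaves)
  if (V == 1L) {
    # degenerate tree: single leaf, one internal root with a forced branch
    return(structure(list(
      leaves = leaves,
      codes = stats::setNames(list(0L), leaves),
      points = stats::setNames(list(1L), leaves),
      n_internal = 1L, counts = stats::setNames(cnt, leaves)),
      class = "hs_tree"))
  }
  n_nodes <- 2L * V - 1L
  count <- c(cnt, rep(NA_real_, V - 1L))
  parent <- integer(n_nodes)
  branch <- integer(n_nodes)      # 0 = left child, 1 = right child
  active <- seq_len(V)            # leaf ids in lexicographic order
  nxt <- V
  while (length(active) > 1L) {
    ord <- order(count[active], active)   # smallest count, oldest id first
    a <- active[ord[1L]]; b <- active[ord[2L]]
    nxt <- nxt + 1L
    count[nxt] <- count[a] + count[b]
    parent[c(a, b)] <- nxt
    branch[a] <- 0L; branch[b] <- 1L
    active <- c(active[-ord[1:2]], nxt)
  }
  root <- nxt
  codes <- vector("list", V)
  points <- vector("list", V)
  for (leaf in seq_len(V)) {
    cd <- integer(0); pt <- integer(0)
    node <- leaf
    while (node != root) {
      cd <- c(branch[node], cd)
      pt <- c(parent[node] - V, pt)     # internal ids 1..V-1
      node <- parent[node]
    }
    codes[[leaf]] <- cd
    points[[leaf]] <- pt
  }
  structure(list(leaves = leaves,
                 codes = stats::setNames(codes, leaves),
                 points = stats::setNames(points, leaves),
                 n_internal = V - 1L,
                 counts = stats::setNames(cnt, leaves)),
            class = "hs_tree")
}

#' @export
print.hs_tree <- function(x, ...) {
  cl <- lengths(x$codes)
  cat("<hs_tree> ", length(x$leaves), " leaves, code lengths ",
      min(cl), "-", max(cl), "\n", sep = "")
  invisible(x)
}

#' Word2vec training configuration
#'
#' @param dim Embedding dimensionality.
#' @param window One-sided context width (CBOW only).
#' @param epochs Passes over the training data (5 for the CBOW baseline; the
#'   ICD-segment-target variant uses 10).
#' @param initial_lr Starting learning rate (0.025 CBOW, 0.04 ICD variant).
#' @param min_lr Floor of the linear learning-rate decay.
#' @param seed Integer seed for the embedding initialization.
#' @return An object of class `w2v_config`.
#' @export
w2v_config <- function(dim = 800L, window = 5L, epochs = 5L,
                       initial_lr = 0.025, min_lr = 1e-4, seed = 1L) {
  stopifnot(epochs >= 1L, min_lr >= 0, min_lr <= initial_lr, window >= 1L)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), initial_lr = initial_lr,
                 min_lr = min_lr, seed = as.integer(seed)),
            class = "w2v_config")
}
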